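test_that("three-taxon tree follows the closed-form branch lengths", {
    d <- symMatrix(c("A", "B", "C"),
                   list(list("A", "B", .2), list("A", "C", .3),
                        list("B", "C", .4)))
    tr <- njTree(d)
    bl <- stats::setNames(tr$edge.length,
                          tr$tip.label[tr$edge[, 2]])
    expect_equal(bl[["A"]], 0.05)
    expect_equal(bl[["B"]], 0.15)
    expect_equal(bl[["C"]], 0.25)
})

test_that("NJ is exact on additive matrices (topology and path lengths)", {
    set.seed(31)
    for (rep in 1:25) {
        case <- randomAdditiveCase(sample(5:8, 1))
        tr <- njTree(case$d)
        ids <- rownames(case$d)
        expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                               ape::unroot(case$tree))), 0)
        expect_equal(ape::cophenetic.phylo(tr)[ids, ids],
                     case$d[ids, ids], tolerance = 1e-10)
    }
})

test_that("equidistant four taxa resolve by the lexicographic tie-break", {
    d <- matrix(0.2, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
    diag(d) <- 0
    tr <- njTree(d)
    ## all Q values tie; the smallest id pair (A, B) is joined first,
    ## internal branch collapses to 0
    expect_identical(ape::write.tree(tr),
                     "((A:0.1,B:0.1):0,C:0.1,D:0.1);")
})

test_that("NJ is invariant to input row permutation", {
    set.seed(17)
    case <- randomAdditiveCase(7)
    ids <- rownames(case$d)
    perm <- sample(ids)
    t1 <- njTree(case$d)
    t2 <- njTree(case$d[perm, perm])
    expect_equal(ape::cophenetic.phylo(t2)[ids, ids],
                 ape::cophenetic.phylo(t1)[ids, ids], tolerance = 1e-12)
})

test_that("NJ agrees with ape's implementation on generic matrices", {
    set.seed(23)
    for (rep in 1:10) {
        n <- sample(5:9, 1)
        ids <- sprintf("t%02d", seq_len(n))
        ## additive plus mild noise keeps the NJ choice unambiguous
        case <- randomAdditiveCase(n)
        d <- case$d + matrix(stats::runif(n * n, 0, 1e-3), n, n)
        d <- (d + t(d)) / 2; diag(d) <- 0
        dimnames(d) <- list(ids, ids)
        mine <- njTree(d)
        theirs <- ape::nj(stats::as.dist(d))
        expect_equal(as.numeric(ape::dist.topo(ape::unroot(mine),
                                               ape::unroot(theirs))), 0)
    }
})

test_that("NJ rejects incomplete or too-small matrices", {
    d <- symMatrix(c("A", "B", "C"),
                   list(list("A", "B", .1), list("A", "C", NA_real_),
                        list("B", "C", .1)))
    expect_error(njTree(d), "A.*C")
    expect_error(njTree(d[1:2, 1:2]), "at least 3")
})

test_that("newick output round-trips topology and branch lengths", {
    set.seed(7)
    case <- randomAdditiveCase(6)
    tr <- njTree(case$d)
    tf <- withr::local_tempfile(fileext = ".nwk")
    ape::write.tree(tr, tf)
    back <- ape::read.tree(tf)
    ids <- tr$tip.label
    expect_equal(ape::cophenetic.phylo(back)[ids, ids],
                 ape::cophenetic.phylo(tr)[ids, ids], tolerance = 1e-8)
})

test_that("midpoint root splits the diameter path in half", {
    ## symmetric quartet: root lands at the center of the internal edge
    q <- ape::read.tree(text = "(A:1,B:1,(C:1,D:1):2);")
    rt <- midpointRoot(q)
    D <- ape::dist.nodes(rt)
    root <- length(rt$tip.label) + 1L
    depths <- D[root, seq_along(rt$tip.label)]
    expect_equal(max(depths), 2)          # diameter 4, half on each side
    ## caterpillar with one long terminal branch: root on that branch
    ct <- ape::unroot(ape::read.tree(
        text = "(((A:1,B:1):1,C:1):1,D:10);"))
    rt2 <- midpointRoot(ct)
    D2 <- ape::dist.nodes(rt2)
    root2 <- length(rt2$tip.label) + 1L
    expect_equal(max(D2[root2, 1:4]), 6.5)
    expect_equal(D2[root2, which(rt2$tip.label == "D")], 6.5)
    ## two-leaf tree roots at the edge midpoint
    two <- ape::read.tree(text = "(A:1,B:3);")
    rt3 <- midpointRoot(two)
    D3 <- ape::dist.nodes(rt3)
    root3 <- 3L
    expect_equal(unname(D3[root3, 1:2]), c(2, 2))
})

test_that("midpoint rooting matches phangorn on random trees", {
    skip_if_not_installed("phangorn")
    set.seed(13)
    for (rep in 1:10) {
        tr <- ape::rtree(sample(5:12, 1), rooted = FALSE)
        mine <- midpointRoot(tr)
        ref <- phangorn::midpoint(tr)
        Dm <- ape::dist.nodes(mine)
        Dr <- ape::dist.nodes(ref)
        n <- length(tr$tip.label)
        o <- order(mine$tip.label); o2 <- order(ref$tip.label)
        expect_equal(unname(Dm[n + 1L, seq_len(n)][o]),
                     unname(Dr[n + 1L, seq_len(n)][o2]),
                     tolerance = 1e-8)
    }
})

test_that("degenerate all-zero trees still root deterministically", {
    z <- ape::read.tree(text = "(B:0,A:0,C:0);")
    rt <- midpointRoot(z)
    expect_true(ape::is.rooted(rt))
})
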