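## Independent closed form for the expected values frozen below:
## d = -log(1 - 2P - Q)/2 - log(1 - 2Q)/4.
k2pClosedForm <- function(P, Q) -0.5 * log(1 - 2 * P - Q) -
    0.25 * log(1 - 2 * Q)

## Build a pair of sequences with an exact (nTs, nTv) difference
## composition over nSites comparable sites.
pairWithComposition <- function(nSites, nTs, nTv) {
    a <- strrep("A", nSites)
    b <- a
    if (nTs > 0) for (i in seq_len(nTs)) substr(b, i, i) <- "G"
    if (nTv > 0) for (i in seq_len(nTv))
        substr(b, nTs + i, nTs + i) <- "C"
    list(a = a, b = b)
}

test_that("identical sequences give P = Q = d = 0", {
    a <- cleanBase(600)
    k <- k2pDistance(a, a)
    expect_identical(k$n, 600L)
    expect_identical(k$P, 0)
    expect_identical(k$Q, 0)
    expect_identical(k$d, 0)
})

test_that("one difference in 658 sites is ~0.15% for transition and transversion", {
    a <- cleanBase(658)
    ts <- mutateAt(a, 500, "C")   # T -> C transition at site 500
    tv <- mutateAt(a, 500, "A")   # T -> A transversion
    dts <- k2pDistance(a, ts)$d
    dtv <- k2pDistance(a, tv)$d
    expect_equal(round(100 * dts, 2), 0.15)
    expect_equal(round(100 * dtv, 2), 0.15)
    expect_equal(dts, k2pClosedForm(1 / 658, 0), tolerance = 1e-12)
})

test_that("constructed P/Q compositions match the closed form to 1e-12", {
    p <- pairWithComposition(100, 10, 5)
    k <- k2pDistance(p$a, p$b)
    expect_equal(k$P, 0.10)
    expect_equal(k$Q, 0.05)
    expect_equal(k$d, 0.1701812, tolerance = 1e-6)  # frozen from closed form
    for (case in list(c(200, 0, 0), c(200, 10, 0), c(200, 0, 10),
                      c(400, 40, 30), c(658, 100, 80))) {
        p <- pairWithComposition(case[1], case[2], case[3])
        k <- k2pDistance(p$a, p$b)
        expect_equal(k$d, k2pClosedForm(case[2] / case[1],
                                        case[3] / case[1]),
                     tolerance = 1e-12)
    }
})

test_that("distances saturate to undefined rather than erroring", {
    ## 2P + Q >= 1: log argument non-positive
    p <- pairWithComposition(100, 49, 10)
    expect_true(is.na(k2pDistance(p$a, p$b)$d))
    ## overlap below the minimum
    a <- cleanBase(50)
    expect_true(is.na(k2pDistance(a, a, minOverlap = 100)$d))
    expect_false(is.na(k2pDistance(a, a, minOverlap = 50)$d))
})

test_that("pairwise deletion removes exactly the masked site", {
    a <- cleanBase(600)
    b <- mutateAt(a, c(10, 20), c("C", "A"))
    k0 <- k2pDistance(a, b)
    bN <- mutateAt(b, 300, "N")
    k1 <- k2pDistance(a, bN)
    expect_identical(k1$n, k0$n - 1L)
    expect_identical(round(k1$P * k1$n), round(k0$P * k0$n))
    expect_identical(round(k1$Q * k1$n), round(k0$Q * k0$n))
    ## masking a differing site removes that (transversion) difference
    bN2 <- mutateAt(b, 10, "N")
    k2 <- k2pDistance(a, bN2)
    expect_identical(round(k2$Q * k2$n), round(k0$Q * k0$n) - 1)
    expect_identical(round(k2$P * k2$n), round(k0$P * k0$n))
})

test_that("adding substitutions at fresh sites never decreases the distance", {
    set.seed(42)
    a <- cleanBase(600)
    b <- a
    bases <- c("A", "C", "G", "T")
    sites <- sample.int(600)          # each site mutated at most once
    last <- 0
    saturated <- FALSE
    for (pos in sites) {
        b <- mutateAt(b, pos, sample(setdiff(bases, substr(a, pos, pos)), 1))
        k <- k2pDistance(a, b)
        if (is.na(k$d)) { saturated <- TRUE; break }
        expect_gte(k$d, last)
        last <- k$d
    }
    expect_true(saturated)   # a long enough walk saturates the model
    expect_gt(last, 0.5)
})

test_that("matrix construction matches the pair operation and ape's K80", {
    sim <- simulateReferenceLibrary(simulationConfig(
        seed = 5, n_genera = 1, species_per_genus = 2,
        specimens_per_species = 5, fragment_fraction = 0,
        misid_count = 0L))
    lib <- sim$library
    dm <- k2pDistanceMatrix(lib)
    d <- distances(dm)
    expect_identical(d, t(d))
    expect_true(all(diag(d) == 0))
    ids <- rownames(d)
    ## spot-check entries against the scalar operation
    for (pair in list(c(1, 2), c(3, 7), c(2, 10))) {
        k <- k2pDistance(
            as.character(barcodeSequences(lib)[[ids[pair[1]]]]),
            as.character(barcodeSequences(lib)[[ids[pair[2]]]]))
        expect_equal(d[pair[1], pair[2]], k$d)
    }
    ## independent oracle: ape's K80 with pairwise deletion
    bin <- ape::as.DNAbin(Biostrings::DNAStringSet(
        as.character(barcodeSequences(lib))))
    dape <- as.matrix(ape::dist.dna(bin, model = "K80",
                                    pairwise.deletion = TRUE))
    expect_equal(d[ids, ids], dape[ids, ids], tolerance = 1e-10)
})

test_that("undefined entries and long format behave as documented", {
    seqs <- c(A = cleanBase(658), B = cleanBase(658),
              C = cleanBase(50))   # C overlaps everything at only 50 sites
    dm <- k2pDistanceMatrix(seqs, minOverlap = 100)
    d <- distances(dm)
    expect_true(is.na(d["A", "C"]) && is.na(d["B", "C"]))
    expect_identical(d["A", "B"], 0)
    lf <- k2pLongFormat(dm)
    expect_identical(nrow(lf), 3L)
    expect_identical(lf$id1, c("A", "A", "B"))
    ## square export writes NA for undefined entries
    tf <- withr::local_tempfile(fileext = ".tsv")
    writeDistanceMatrix(dm, tf)
    back <- utils::read.delim(tf, row.names = 1)
    expect_true(is.na(back["A", "C"]))
    expect_error(k2pDistanceMatrix(seqs[1]), "at least 2")
})
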