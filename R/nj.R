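.quoteNewickLabel <- function(x) {
    needs <- grepl("[ ():,;'\\[\\]]", x)
    x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
    x
}

.fmtBranch <- function(b) sprintf("%.17g", b)

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining using the Studier-Keppler criterion
#' \eqn{Q(i,j) = (r-2) d(i,j) - R(i) - R(j)}, where \eqn{R} is the row sum
#' over the current working matrix. Ties in \eqn{Q} are broken by the
#' lexicographically smallest pair of cluster ids (each cluster is
#' identified by its smallest leaf label), so the result is
#' bit-reproducible. Branch lengths follow the standard NJ formulas and
#' are retained even when negative. NJ is exact on additive matrices: the
#' path length between any two leaves equals the input entry.
#'
#' @param x a \code{K2PDistanceMatrix} or symmetric numeric matrix with id
#'   dimnames; all entries must be defined and at least 3 ids present.
#' @return an unrooted \code{phylo} tree (trifurcating root node), leaves
#'   labeled by specimen id.
#' @examples
#' d <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' njTree(d)
#' @export
njTree <- function(x) {
    D <- if (is(x, "K2PDistanceMatrix")) distances(x) else x
    ids <- rownames(D)
    if (is.null(ids) || !identical(ids, colnames(D)))
        stop("distance matrix must have identical row/col ids")
    r <- nrow(D)
    if (r < 3L)
        stop("neighbor joining needs at least 3 taxa (n = 2 is a single edge)")
    na <- which(is.na(D) & upper.tri(D), arr.ind = TRUE)
    if (nrow(na))
        stop("undefined distance between ", ids[na[1L, 1L]], " and ",
             ids[na[1L, 2L]], "; neighbor joining needs a complete matrix")
    frag <- .quoteNewickLabel(ids)   # newick fragment per active cluster
    repr <- ids                      # smallest leaf label per cluster
    W <- D
    while (r > 3L) {
        R <- rowSums(W)
        Qm <- (r - 2) * W - outer(R, R, `+`)
        diag(Qm) <- Inf
        qmin <- min(Qm)
        cand <- which(Qm == qmin & upper.tri(Qm), arr.ind = TRUE)
        key1 <- pmin(repr[cand[, 1L]], repr[cand[, 2L]])
        key2 <- pmax(repr[cand[, 1L]], repr[cand[, 2L]])
        pick <- order(key1, key2)[1L]
        i <- cand[pick, 1L]; j <- cand[pick, 2L]
        bi <- 0.5 * W[i, j] + (R[i] - R[j]) / (2 * (r - 2))
        bj <- W[i, j] - bi
        ## order the two children by cluster id for a deterministic string
        ch <- if (repr[i] <= repr[j])
            c(paste0(frag[i], ":", .fmtBranch(bi)),
              paste0(frag[j], ":", .fmtBranch(bj)))
        else
            c(paste0(frag[j], ":", .fmtBranch(bj)),
              paste0(frag[i], ":", .fmtBranch(bi)))
        newFrag <- paste0("(", ch[1L], ",", ch[2L], ")")
        dnew <- 0.5 * (W[i, ] + W[j, ] - W[i, j])
        keep <- setdiff(seq_len(r), c(i, j))
        W2 <- rbind(cbind(W[keep, keep, drop = FALSE], dnew[keep]),
                    c(dnew[keep], 0))
        frag <- c(frag[keep], newFrag)
        repr <- c(repr[keep], min(repr[i], repr[j]))
        rownames(W2) <- colnames(W2) <- NULL
        W <- W2
        r <- r - 1L
    }
    v1 <- (W[1, 2] + W[1, 3] - W[2, 3]) / 2
    v2 <- (W[1, 2] + W[2, 3] - W[1, 3]) / 2
    v3 <- (W[1, 3] + W[2, 3] - W[1, 2]) / 2
    o <- order(repr)
    b <- c(v1, v2, v3)[o]
    nwk <- paste0("(", paste0(frag[o], ":", .fmtBranch(b),
                              collapse = ","), ");")
    ape::read.tree(text = nwk)
}

#' Midpoint rooting
#'
#' Roots an unrooted tree at the midpoint of the longest leaf-to-leaf
#' path. Ties among equally long paths are broken by the lexicographically
#' smallest (sorted) pair of leaf labels; a degenerate all-zero-length
#' tree is rooted on the edge adjacent to the lexicographically first
#' leaf.
#'
#' @param tree a \code{phylo} tree with branch lengths.
#' @return a rooted \code{phylo} tree.
#' @export
midpointRoot <- function(tree) {
    stopifnot(inherits(tree, "phylo"))
    n <- length(tree$tip.label)
    if (n < 2L) stop("need at least 2 leaves to root")
    D <- ape::dist.nodes(tree)
    DL <- D[seq_len(n), seq_len(n), drop = FALSE]
    diam <- max(DL)
    if (diam <= 0) {
        leaf <- order(tree$tip.label)[1L]
        return(phytools::reroot(tree, leaf, position = 0))
    }
    cand <- which(DL == diam & upper.tri(DL), arr.ind = TRUE)
    lab1 <- pmin(tree$tip.label[cand[, 1L]], tree$tip.label[cand[, 2L]])
    lab2 <- pmax(tree$tip.label[cand[, 1L]], tree$tip.label[cand[, 2L]])
    pick <- order(lab1, lab2)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]
    ## walk from the lexicographically smaller endpoint towards the other
    if (tree$tip.label[i] > tree$tip.label[j]) { t <- i; i <- j; j <- t }
    path <- ape::nodepath(tree, i, j)
    half <- diam / 2
    cum <- 0
    for (k in seq_len(length(path) - 1L)) {
        elen <- D[path[k], path[k + 1L]]
        if (cum + elen >= half) {
            a <- path[k]; b <- path[k + 1L]
            offA <- half - cum          # midpoint distance from node a
            ## reroot() measures position from the parent end of the edge
            er <- which(tree$edge[, 1L] == a & tree$edge[, 2L] == b)
            if (length(er)) {           # b is the child, a the parent
                return(phytools::reroot(tree, b, position = offA))
            }
            return(phytools::reroot(tree, a, position = elen - offA))
        }
        cum <- cum + elen
    }
    stop("internal error: midpoint not located")   # nocov
}
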