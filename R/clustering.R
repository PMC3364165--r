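#' Single-linkage clusters at a divergence cutoff
#'
#' Partitions specimens into haplotype clusters: two specimens fall in the
#' same cluster iff they are connected by a chain of pairs each with
#' distance strictly below \code{cutoff}. Distinct clusters are therefore
#' separated by at least \code{cutoff}. Clusters are labeled by their
#' smallest member id, so the partition is deterministic.
#'
#' @param x a \code{K2PDistanceMatrix} (or plain symmetric numeric matrix
#'   with id dimnames).
#' @param ids subset of specimen ids to cluster (default: all).
#' @param cutoff divergence cutoff (proportion); linkage uses strict
#'   \code{d < cutoff}.
#' @return named character vector mapping each id to its cluster label.
#' @export
singleLinkageClusters <- function(x, ids = NULL, cutoff) {
    d <- if (is(x, "K2PDistanceMatrix")) distances(x) else x
    if (is.null(ids)) ids <- rownames(d)
    miss <- setdiff(ids, rownames(d))
    if (length(miss))
        stop("ids absent from distance matrix: ",
             paste(miss, collapse = ", "))
    d <- d[ids, ids, drop = FALSE]
    if (length(ids) == 1L)
        return(stats::setNames(ids, ids))
    na <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    if (nrow(na))
        stop("undefined distance between ", ids[na[1L, 1L]], " and ",
             ids[na[1L, 2L]], "; cannot cluster")
    ## connected components of the strict-threshold graph
    comp <- seq_along(ids)
    adj <- d < cutoff
    repeat {
        changed <- FALSE
        for (i in seq_along(ids)) {
            nb <- which(adj[i, ])
            newc <- min(comp[c(i, nb)])
            if (any(comp[c(i, nb)] != newc)) {
                comp[c(i, nb)] <- newc
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    labels <- vapply(split(ids, comp), min, character(1))
    stats::setNames(unname(labels[as.character(comp)]), ids)
}

#' Cross-species shared haplotypes
#'
#' Reports pairs of specimens with a K2P distance of exactly zero whose
#' species labels differ — identical barcodes shared across nominal
#' species. Pairs are sorted by (id1, id2).
#'
#' @param x a \code{K2PDistanceMatrix}.
#' @param species named character vector mapping specimen id to species
#'   label; must cover the matrix ids.
#' @return \code{DataFrame} with columns \code{id1}, \code{id2},
#'   \code{species1}, \code{species2}; zero rows when no haplotypes are
#'   shared across species.
#' @export
detectSharedHaplotypes <- function(x, species) {
    stopifnot(is(x, "K2PDistanceMatrix"))
    ids <- rownames(distances(x))
    miss <- setdiff(ids, names(species))
    if (length(miss))
        stop("species map missing ids: ", paste(miss, collapse = ", "))
    d <- distances(x)
    hit <- which(upper.tri(d) & !is.na(d) & d == 0, arr.ind = TRUE)
    if (nrow(hit)) {
        s1 <- unname(species[ids[hit[, 1L]]])
        s2 <- unname(species[ids[hit[, 2L]]])
        keep <- s1 != s2
        hit <- hit[keep, , drop = FALSE]
        s1 <- s1[keep]; s2 <- s2[keep]
        id1 <- pmin(ids[hit[, 1L]], ids[hit[, 2L]])
        id2 <- pmax(ids[hit[, 1L]], ids[hit[, 2L]])
        swap <- id1 != ids[hit[, 1L]]
        tmp <- s1[swap]; s1[swap] <- s2[swap]; s2[swap] <- tmp
        o <- order(id1, id2)
        DataFrame(id1 = id1[o], id2 = id2[o],
                  species1 = s1[o], species2 = s2[o])
    } else {
        DataFrame(id1 = character(), id2 = character(),
                  species1 = character(), species2 = character())
    }
}
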