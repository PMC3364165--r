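## Integer encoding of concrete bases on the barcode frame: purines A=1,
## G=2; pyrimidines C=3, T=4; everything else (ambiguity codes, N, gaps,
## uncovered sites) is NA and excluded by pairwise deletion.
.BASE_CODE <- c(A = 1L, G = 2L, C = 3L, T = 4L)

.encodeFrame <- function(sequences, startPos, frameLength) {
    m <- matrix(NA_integer_, nrow = length(sequences), ncol = frameLength,
                dimnames = list(names(sequences), NULL))
    s <- as.character(sequences)
    for (i in seq_along(s)) {
        ch <- strsplit(s[i], "")[[1]]
        idx <- seq.int(startPos[i], length.out = length(ch))
        m[i, idx] <- .BASE_CODE[ch]
    }
    m
}

## Frame-encoded matrix for a library (QC-passing specimens only unless
## onlyPass = FALSE).
.libraryFrameMatrix <- function(lib, onlyPass = TRUE) {
    keep <- if (onlyPass) qcReport(lib)$qc_status == "pass"
            else rep(TRUE, length(lib))
    .encodeFrame(barcodeSequences(lib)[keep], frameStart(lib)[keep],
                 barcodeFrameLength(lib))
}

## Core K2P computation on two encoded site vectors.
.k2pPair <- function(x, y, minOverlap) {
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n == 0L)
        return(list(n = 0L, P = NA_real_, Q = NA_real_, d = NA_real_))
    xs <- x[ok]; ys <- y[ok]
    differ <- xs != ys
    ts <- differ & ((xs <= 2L) == (ys <= 2L))   # A<->G, C<->T
    P <- sum(ts) / n
    Q <- (sum(differ) - sum(ts)) / n
    a1 <- 1 - 2 * P - Q
    a2 <- 1 - 2 * Q
    d <- if (n < minOverlap || a1 <= 0 || a2 <= 0) NA_real_
         else -0.5 * log(a1) - 0.25 * log(a2)
    list(n = n, P = P, Q = Q, d = d)
}

#' Kimura 2-parameter distance between two sequences (pairwise deletion)
#'
#' Compares only sites where both sequences carry a concrete base
#' (A, C, G or T); ambiguity codes, N, gaps and uncovered frame positions
#' are excluded (pairwise deletion). With transition proportion P and
#' transversion proportion Q over the n compared sites,
#' \deqn{d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q).}
#' The distance is undefined (\code{NA}) when fewer than \code{minOverlap}
#' sites are compared or when a logarithm argument is non-positive
#' (saturation).
#'
#' @param a,b nucleotide strings (or \code{DNAString}s) anchored on a
#'   common coordinate frame.
#' @param startA,startB 1-based frame anchors of \code{a} and \code{b}.
#' @param minOverlap minimum compared sites for a defined distance
#'   (default 100).
#' @param frameLength frame size (default 658).
#' @return list with \code{n} (compared sites), \code{P}, \code{Q} and
#'   \code{d} (substitutions/site; \code{NA} when undefined).
#' @examples
#' a <- strrep("ACGT", 25)
#' b <- paste0("G", substring(a, 2))   # one transition at site 1
#' k2pDistance(a, b, minOverlap = 50)
#' @export
k2pDistance <- function(a, b, startA = 1L, startB = 1L, minOverlap = 100L,
                        frameLength = 658L) {
    seqs <- c(as.character(a), as.character(b))
    enc <- .encodeFrame(stats::setNames(seqs, c("a", "b")),
                        as.integer(c(startA, startB)), frameLength)
    .k2pPair(enc[1L, ], enc[2L, ], minOverlap)
}

#' Pairwise K2P distance matrix for a barcode library
#'
#' Computes all pairwise K2P distances (pairwise deletion) among the
#' QC-passing specimens of a library, or among an arbitrary set of
#' frame-anchored sequences. Undefined entries (overlap below
#' \code{minOverlap}, or saturated) are stored as \code{NA}.
#'
#' @param x a \code{BarcodeLibrary}, or a named \code{DNAStringSet} /
#'   character vector of sequences anchored at \code{startPos}.
#' @param minOverlap minimum compared sites (default 100).
#' @param onlyPass for a library, restrict to QC-passing specimens
#'   (default TRUE).
#' @param startPos,frameLength anchoring, for non-library input.
#' @return a \code{\link{K2PDistanceMatrix-class}} object.
#' @export
k2pDistanceMatrix <- function(x, minOverlap = 100L, onlyPass = TRUE,
                              startPos = 1L, frameLength = 658L) {
    enc <- if (is(x, "BarcodeLibrary")) {
        .libraryFrameMatrix(x, onlyPass)
    } else {
        if (is.null(names(x)))
            stop("sequences must be named by specimen id")
        sq <- stats::setNames(as.character(x), names(x))
        .encodeFrame(sq, as.integer(rep_len(startPos, length(x))),
                     frameLength)
    }
    m <- nrow(enc)
    if (m < 2L)
        stop("need at least 2 sequences to build a distance matrix")
    ids <- rownames(enc)
    d <- matrix(NA_real_, m, m, dimnames = list(ids, ids))
    n <- matrix(0L, m, m, dimnames = list(ids, ids))
    P <- matrix(NA_real_, m, m, dimnames = list(ids, ids))
    Q <- matrix(NA_real_, m, m, dimnames = list(ids, ids))
    notNA <- !is.na(enc)
    for (i in seq_len(m)) {
        n[i, i] <- sum(notNA[i, ])
        P[i, i] <- 0; Q[i, i] <- 0
        if (i == m) break
        for (j in (i + 1L):m) {
            k <- .k2pPair(enc[i, ], enc[j, ], minOverlap)
            d[i, j] <- d[j, i] <- k$d
            n[i, j] <- n[j, i] <- k$n
            P[i, j] <- P[j, i] <- k$P
            Q[i, j] <- Q[j, i] <- k$Q
        }
    }
    diag(d) <- 0
    new("K2PDistanceMatrix", d = d, n = n, P = P, Q = Q,
        minOverlap = as.integer(minOverlap))
}

#' @describeIn K2PDistanceMatrix-class distance matrix (\code{NA} =
#'   undefined).
#' @param x a \code{K2PDistanceMatrix}.
#' @export
setMethod("distances", "K2PDistanceMatrix", function(x) x@d)

#' @describeIn K2PDistanceMatrix-class matrix of compared-site counts.
#' @export
setMethod("comparedSites", "K2PDistanceMatrix", function(x) x@n)

#' @describeIn K2PDistanceMatrix-class specimen ids.
#' @export
setMethod("specimenIds", "K2PDistanceMatrix", function(x) rownames(x@d))

#' @export
setMethod("dim", "K2PDistanceMatrix", function(x) dim(x@d))

#' @export
#' @param ... ignored.
setMethod("as.matrix", "K2PDistanceMatrix", function(x, ...) x@d)

setMethod("show", "K2PDistanceMatrix", function(object) {
    m <- nrow(object@d)
    off <- object@d[upper.tri(object@d)]
    cat("K2PDistanceMatrix over", m, "specimens;",
        sum(is.na(off)), "of", length(off), "pairs undefined\n")
    if (any(!is.na(off)))
        cat(sprintf("  defined distances: %.4f - %.4f (mean %.4f)\n",
                    min(off, na.rm = TRUE), max(off, na.rm = TRUE),
                    mean(off, na.rm = TRUE)))
})

#' Long-format pair table of a K2P distance matrix
#'
#' @param x a \code{K2PDistanceMatrix}.
#' @return \code{DataFrame} with one row per unordered pair (id1 < id2):
#'   \code{id1}, \code{id2}, \code{n}, \code{P}, \code{Q}, \code{d}.
#' @export
k2pLongFormat <- function(x) {
    stopifnot(is(x, "K2PDistanceMatrix"))
    ids <- rownames(x@d)
    ut <- which(upper.tri(x@d), arr.ind = TRUE)
    ut <- ut[order(ut[, 1L], ut[, 2L]), , drop = FALSE]
    DataFrame(id1 = ids[ut[, 1L]], id2 = ids[ut[, 2L]],
              n = x@n[ut], P = x@P[ut], Q = x@Q[ut], d = x@d[ut])
}

#' Write a distance matrix as square TSV
#'
#' Square tab-separated matrix with a header row and leading id column;
#' undefined entries are written as \code{NA}.
#'
#' @param x a \code{K2PDistanceMatrix}.
#' @param path output file.
#' @export
writeDistanceMatrix <- function(x, path) {
    stopifnot(is(x, "K2PDistanceMatrix"))
    df <- data.frame(specimen_id = rownames(x@d), x@d,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA",
                       fileEncoding = "UTF-8")
    invisible(path)
}
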