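#' Fixed diagnostic nucleotide positions
#'
#' A (position, state) pair is diagnostic for a species within a
#' comparison set iff every member of that species with a concrete base
#' (A/C/G/T) at the position shows the state, and no member of any other
#' species in the set with a concrete base there shows it. Positions are
#' 1-based on the 658-site barcode frame. Positions where fewer than
#' \code{minCoverage} members of the species carry data are skipped.
#'
#' @param lib a \code{BarcodeLibrary} (QC-passing specimens are used).
#' @param speciesSet character vector of at least two species labels to
#'   compare.
#' @param minCoverage minimum members of the focal species with data at a
#'   position (default 1).
#' @param onlyPass restrict to QC-passing specimens (default TRUE).
#' @return \code{DataFrame} with columns \code{species_label},
#'   \code{position}, \code{state}, sorted by species then position.
#' @export
findDiagnosticPositions <- function(lib, speciesSet, minCoverage = 1L,
                                    onlyPass = TRUE) {
    stopifnot(is(lib, "BarcodeLibrary"))
    if (length(speciesSet) < 2L)
        stop("need at least 2 species to compare")
    enc <- .libraryFrameMatrix(lib, onlyPass)
    sp <- speciesLabels(lib)[rownames(enc)]
    zero <- speciesSet[!speciesSet %in% sp]
    if (length(zero))
        stop("species with zero usable sequences: ",
             paste(zero, collapse = ", "))
    enc <- enc[sp %in% speciesSet, , drop = FALSE]
    sp <- sp[rownames(enc)]
    baseLetters <- names(.BASE_CODE)
    res <- list()
    for (s in sort(speciesSet)) {
        own <- enc[sp == s, , drop = FALSE]
        oth <- enc[sp != s, , drop = FALSE]
        for (pos in seq_len(ncol(enc))) {
            v <- own[, pos]
            v <- v[!is.na(v)]
            if (length(v) < minCoverage || length(v) == 0L) next
            if (length(unique(v)) != 1L) next         # not fixed in s
            w <- oth[, pos]
            if (any(!is.na(w) & w == v[1L])) next     # state seen elsewhere
            res[[length(res) + 1L]] <-
                list(s, pos, baseLetters[v[1L]])
        }
    }
    if (!length(res))
        return(DataFrame(species_label = character(),
                         position = integer(), state = character()))
    DataFrame(species_label = vapply(res, `[[`, character(1), 1L),
              position = vapply(res, `[[`, integer(1), 2L),
              state = vapply(res, `[[`, character(1), 3L))
}
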