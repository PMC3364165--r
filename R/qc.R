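## Stop codons under the invertebrate mitochondrial genetic code
## (translation table 5): TAA and TAG; TGA encodes Trp.
.stopCodons <- function() {
    gc5 <- Biostrings::getGeneticCode("5")
    names(gc5)[gc5 == "*"]
}

.allowedAlphabet <- function() {
    c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
      "V", "H", "D", "B", "N", "-")
}

## In-frame stop codon starts (local 1-based) for one sequence string at a
## given reading offset; codons containing ambiguity codes or gaps are
## never counted as stops.
.stopStarts <- function(s, offset) {
    n <- nchar(s)
    if (n < offset + 3L) return(integer())
    starts <- seq.int(1L + offset, n - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    starts[codons %in% .stopCodons()]
}

## Reading-frame offset in {0,1,2} minimizing in-frame stops; ties broken
## by the smallest offset.
.bestFrameOffset <- function(s) {
    counts <- vapply(0:2, function(o) length(.stopStarts(s, o)), integer(1))
    which.min(counts) - 1L
}

#' Anchor a sequence to the barcode coordinate frame
#'
#' Places nucleotide strings on the standard 658-site barcode frame.
#' Full-length sequences and 5' fragments are anchored at site 1 unless an
#' explicit \code{start} is given; the reading-frame offset is chosen as
#' the offset in \{0, 1, 2\} minimizing in-frame stop codons under the
#' invertebrate mitochondrial genetic code (ties to the smallest offset).
#' Sequences shorter than \code{minLen} are marked \code{too_short}.
#'
#' @param bases character vector of nucleotide strings (A/C/G/T, IUPAC
#'   ambiguity codes, N; a gap character is tolerated here and flagged by
#'   \code{\link{qcSequence}}).
#' @param start 1-based anchor position(s) on the frame (recycled).
#' @param minLen minimum retained length in sites (default 300).
#' @param frameLength frame size (default 658).
#' @return \code{DataFrame} with columns \code{bases}, \code{start},
#'   \code{length}, \code{frame_offset} and \code{qc_status}
#'   (\code{"pending"} or \code{"too_short"}).
#' @export
anchorToBarcodeFrame <- function(bases, start = 1L, minLen = 300L,
                                 frameLength = 658L) {
    bases <- toupper(as.character(bases))
    bad <- vapply(strsplit(bases, ""), function(ch)
        any(!ch %in% .allowedAlphabet()), logical(1))
    if (any(bad))
        stop("non-nucleotide characters in sequence(s) ",
             paste(which(bad), collapse = ", "))
    start <- as.integer(rep_len(start, length(bases)))
    len <- nchar(bases)
    if (any(start < 1L) || any(start + len - 1L > frameLength))
        stop("sequence does not fit the ", frameLength, "-site frame")
    DataFrame(
        bases = bases,
        start = start,
        length = len,
        frame_offset = vapply(bases, .bestFrameOffset, integer(1),
                              USE.NAMES = FALSE),
        qc_status = ifelse(len < minLen, "too_short", "pending")
    )
}

#' Quality-screen anchored barcode sequences
#'
#' Screens sequences for in-frame stop codons (invertebrate mitochondrial
#' code, reading frame chosen by \code{\link{anchorToBarcodeFrame}}),
#' internal gap characters (indels) and minimum length. All outcomes are
#' report states, never errors.
#'
#' Decision: \code{indel} if a gap character is present, else
#' \code{stop_codon} if any in-frame stop occurs, else \code{too_short} if
#' the sequence is shorter than \code{minLen}, else \code{pass}.
#'
#' @param sequences \code{DNAStringSet} or character vector.
#' @param start 1-based frame anchor(s), recycled.
#' @param minLen minimum retained length (default 300).
#' @param frameLength frame size (default 658).
#' @return \code{DataFrame} with columns \code{frame_offset},
#'   \code{stop_positions} (comma-separated 1-based codon start positions
#'   on the frame; \code{""} if none), \code{n_stops}, \code{has_indel},
#'   \code{length}, \code{qc_status}.
#' @examples
#' qcSequence(c(ok = "ATGATTGGA", stop = "ATGTAAGGA"), minLen = 3)
#' @export
qcSequence <- function(sequences, start = 1L, minLen = 300L,
                       frameLength = 658L) {
    nms <- names(sequences)
    s <- toupper(as.character(sequences))
    start <- as.integer(rep_len(start, length(s)))
    len <- nchar(s)
    offs <- integer(length(s))
    stopsGlobal <- character(length(s))
    nStops <- integer(length(s))
    for (i in seq_along(s)) {
        offs[i] <- .bestFrameOffset(s[i])
        st <- .stopStarts(s[i], offs[i])
        nStops[i] <- length(st)
        stopsGlobal[i] <- paste(st + start[i] - 1L, collapse = ",")
    }
    hasIndel <- grepl("-", s, fixed = TRUE)
    status <- rep("pass", length(s))
    status[len < minLen] <- "too_short"
    status[nStops > 0L] <- "stop_codon"
    status[hasIndel] <- "indel"
    DataFrame(frame_offset = offs, stop_positions = stopsGlobal,
              n_stops = nStops, has_indel = hasIndel, length = len,
              qc_status = status, row.names = nms)
}

## Specimens whose sequences passed QC.
.qcPassIds <- function(lib) {
    specimenIds(lib)[qcReport(lib)$qc_status == "pass"]
}
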