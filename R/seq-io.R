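#' Read barcode sequences from a FASTA file
#'
#' Reads nucleotide barcode sequences, taking the header token before the
#' first whitespace as the specimen id, upper-casing the sequence and
#' mapping U to T. IUPAC ambiguity codes, N and the gap character are
#' retained.
#'
#' @param path path to a FASTA file.
#' @return a named \code{DNAStringSet}, one element per FASTA entry.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">X123 Baetis sp.", "acgtu"), tf)
#' readBarcodeFasta(tf)
#' @export
readBarcodeFasta <- function(path) {
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L)
        stop("empty FASTA file: ", path)
    ids <- sub("\\s.*$", "", names(raw))
    if (anyDuplicated(ids))
        stop("duplicate specimen ids in FASTA: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    seqs <- chartr("u", "T", chartr("U", "T", toupper(as.character(raw))))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- ids
    out
}

#' Write barcode sequences to FASTA
#'
#' @param x a \code{BarcodeLibrary} or named \code{DNAStringSet}.
#' @param path output file.
#' @export
writeBarcodeFasta <- function(x, path) {
    if (is(x, "BarcodeLibrary")) x <- barcodeSequences(x)
    Biostrings::writeXStringSet(x, path, width = 70L)
    invisible(path)
}

## Provisional-name pattern: genus, " sp." (optional space), taxonomist
## initials, serial integer -- e.g. "Heptagenia sp.LJ1", "Acerpenna sp. CHU1".
.provisionalPattern <- "^(\\S+) sp\\. ?([A-Za-z]+)([0-9]+)$"

#' Is a species label a provisional name?
#'
#' Provisional names follow the pattern genus + " sp." + taxonomist
#' initials + serial number, e.g. \code{"Heptagenia sp.LJ1"}.
#'
#' @param label character vector of species labels.
#' @return logical vector.
#' @export
isProvisionalName <- function(label) {
    !is.na(label) & grepl(.provisionalPattern, label)
}

.requiredSpecimenCols <- c("specimen_id", "family", "genus", "species_label",
                           "id_confidence")
.optionalSpecimenCols <- c("life_stage", "country", "state_province",
                           "latitude", "longitude")

#' Read a specimen metadata table
#'
#' Reads a tab-separated specimen table (BOLD-export-like). Required
#' columns: \code{specimen_id}, \code{family}, \code{genus},
#' \code{species_label}, \code{id_confidence}. Optional columns
#' (\code{life_stage}, \code{country}, \code{state_province},
#' \code{latitude}, \code{longitude}) are filled with \code{NA} when
#' absent. \code{is_provisional} is derived from the species label.
#'
#' @param path path to a TSV file with a header row.
#' @return a \code{DataFrame} with row names set to \code{specimen_id}.
#' @export
readSpecimenTable <- function(path) {
    if (!file.exists(path))
        stop("specimen table not found: ", path)
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            colClasses = "character",
                            na.strings = c("", "NA"), check.names = FALSE,
                            fileEncoding = "UTF-8")
    missing <- setdiff(.requiredSpecimenCols, colnames(df))
    if (length(missing))
        stop("specimen table is missing required column(s): ",
             paste(missing, collapse = ", "))
    for (col in .optionalSpecimenCols)
        if (!col %in% colnames(df)) df[[col]] <- NA_character_
    df$latitude <- suppressWarnings(as.numeric(df$latitude))
    df$longitude <- suppressWarnings(as.numeric(df$longitude))
    if (anyDuplicated(df$specimen_id))
        stop("duplicate specimen ids in table: ",
             paste(unique(df$specimen_id[duplicated(df$specimen_id)]),
                   collapse = ", "))
    bad <- !df$id_confidence %in% c("expert", "propagated", "unidentified")
    if (any(bad))
        stop("invalid id_confidence values: ",
             paste(unique(df$id_confidence[bad]), collapse = ", "))
    df$is_provisional <- isProvisionalName(df$species_label)
    out <- DataFrame(df[setdiff(colnames(df), "specimen_id")],
                     row.names = df$specimen_id, check.names = FALSE)
    cols <- c(setdiff(.requiredSpecimenCols, "specimen_id"),
              "is_provisional", .optionalSpecimenCols)
    out[, c(cols, setdiff(colnames(out), cols)), drop = FALSE]
}

#' Write a specimen metadata table
#'
#' Writes the metadata of a library (or a specimen \code{DataFrame}) as a
#' UTF-8 tab-separated file with a deterministic column order, suitable
#' for re-reading with \code{\link{readSpecimenTable}}.
#'
#' @param x a \code{BarcodeLibrary} or specimen \code{DataFrame}.
#' @param path output file.
#' @export
writeSpecimenTable <- function(x, path) {
    if (is(x, "BarcodeLibrary")) x <- specimenData(x)
    df <- as.data.frame(x)
    df <- cbind(specimen_id = rownames(df), df, stringsAsFactors = FALSE)
    rownames(df) <- NULL
    cols <- c(.requiredSpecimenCols, "is_provisional", .optionalSpecimenCols)
    df <- df[, c(intersect(cols, colnames(df)),
                 setdiff(colnames(df), cols)), drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Assemble a barcode library
#'
#' Combines anchored sequences with specimen metadata and runs the
#' stop-codon / indel / length quality screen on every sequence.
#' Specimens present in the metadata but lacking a sequence are dropped
#' with a message; sequences lacking metadata are an error.
#'
#' @param sequences named \code{DNAStringSet} (see
#'   \code{\link{readBarcodeFasta}}).
#' @param specimens specimen \code{DataFrame} or data.frame with specimen
#'   ids as row names (see \code{\link{readSpecimenTable}}).
#' @param startPos 1-based anchor position(s) on the barcode frame;
#'   recycled. Sequences shorter than the frame are 5'-anchored by default.
#' @param frameLength sites in the barcode frame (default 658).
#' @param minLen minimum retained length; shorter sequences get QC status
#'   \code{too_short} (default 300).
#' @return a \code{BarcodeLibrary}.
#' @export
BarcodeLibrary <- function(sequences, specimens, startPos = 1L,
                           frameLength = 658L, minLen = 300L) {
    if (!is(sequences, "DNAStringSet"))
        sequences <- Biostrings::DNAStringSet(sequences)
    ids <- names(sequences)
    if (is.null(ids))
        stop("sequences must be named by specimen id")
    if (is.data.frame(specimens))
        specimens <- DataFrame(specimens, row.names = rownames(specimens))
    orphanMeta <- setdiff(rownames(specimens), ids)
    if (length(orphanMeta)) {
        message(length(orphanMeta),
                " specimen(s) in the table have no sequence and are dropped: ",
                paste(utils::head(orphanMeta, 5L), collapse = ", "),
                if (length(orphanMeta) > 5L) ", ...")
    }
    noMeta <- setdiff(ids, rownames(specimens))
    if (length(noMeta))
        stop("sequences without specimen metadata: ",
             paste(utils::head(noMeta, 5L), collapse = ", "))
    specimens <- specimens[ids, , drop = FALSE]
    if (is.null(specimens[["is_provisional"]]))
        specimens$is_provisional <- isProvisionalName(
            specimens[["species_label"]])
    startPos <- as.integer(rep_len(startPos, length(sequences)))
    qc <- qcSequence(sequences, start = startPos, minLen = minLen,
                     frameLength = frameLength)
    new("BarcodeLibrary", sequences = sequences, startPos = startPos,
        frameLength = as.integer(frameLength), specimens = specimens,
        qc = qc)
}

#' @describeIn BarcodeLibrary specimen ids, in library order.
#' @param x a \code{BarcodeLibrary}.
#' @export
setMethod("specimenIds", "BarcodeLibrary",
    function(x) names(x@sequences))

#' @describeIn BarcodeLibrary specimen metadata \code{DataFrame}.
#' @export
setMethod("specimenData", "BarcodeLibrary", function(x) x@specimens)

#' @describeIn BarcodeLibrary the sequences as a \code{DNAStringSet}.
#' @export
setMethod("barcodeSequences", "BarcodeLibrary", function(x) x@sequences)

#' @describeIn BarcodeLibrary 1-based frame anchor of each sequence.
#' @export
setMethod("frameStart", "BarcodeLibrary",
    function(x) stats::setNames(x@startPos, names(x@sequences)))

#' @describeIn BarcodeLibrary the frame length (658 for COI barcodes).
#' @export
setMethod("barcodeFrameLength", "BarcodeLibrary", function(x) x@frameLength)

#' @describeIn BarcodeLibrary per-sequence QC report \code{DataFrame}.
#' @export
setMethod("qcReport", "BarcodeLibrary", function(x) x@qc)

#' @describeIn BarcodeLibrary species label of each specimen (named).
#' @export
setMethod("speciesLabels", "BarcodeLibrary",
    function(x) stats::setNames(as.character(x@specimens$species_label),
                                names(x@sequences)))

#' @describeIn BarcodeLibrary number of specimens.
#' @export
setMethod("length", "BarcodeLibrary", function(x) length(x@sequences))

#' Subset a barcode library by specimen id or index
#'
#' @param x a \code{BarcodeLibrary}.
#' @param i character ids or numeric/logical index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "BarcodeLibrary", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) {
        miss <- setdiff(i, names(x@sequences))
        if (length(miss))
            stop("unknown specimen id(s): ", paste(miss, collapse = ", "))
        i <- match(i, names(x@sequences))
    }
    new("BarcodeLibrary", sequences = x@sequences[i],
        startPos = x@startPos[i], frameLength = x@frameLength,
        specimens = x@specimens[i, , drop = FALSE],
        qc = x@qc[i, , drop = FALSE])
})

setMethod("show", "BarcodeLibrary", function(object) {
    sp <- unique(as.character(object@specimens$species_label))
    cat("BarcodeLibrary with", length(object@sequences), "specimens,",
        length(sp[!is.na(sp)]), "species labels\n")
    cat("  frame: ", object@frameLength, " sites; sequence lengths ",
        if (length(object@sequences))
            paste0(min(Biostrings::width(object@sequences)), "-",
                   max(Biostrings::width(object@sequences)))
        else "-", "\n", sep = "")
    if (nrow(object@qc)) {
        tab <- table(object@qc$qc_status)
        cat("  QC: ", paste(names(tab), as.integer(tab), sep = "=",
                            collapse = ", "), "\n", sep = "")
    }
})
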