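#' Assign a query specimen to a reference species
#'
#' Computes K2P distances from a query barcode to every expert-identified
#' reference specimen and applies the divergence-threshold rule: with S
#' the set of species holding a reference strictly closer than
#' \code{t_assign}, the query is assigned that species' name (confidence
#' "propagated") when |S| = 1, is \code{ambiguous} when several species
#' qualify, and \code{unassigned} (a candidate for a provisional name)
#' when none does.
#'
#' @param query nucleotide string (or \code{DNAString}) of the query
#'   barcode.
#' @param reference a \code{BarcodeLibrary}; only QC-passing specimens
#'   with \code{id_confidence = "expert"} serve as references.
#' @param config an \code{\link{auditConfig}} (uses \code{t_assign},
#'   \code{min_overlap}, \code{min_len}).
#' @param queryStart 1-based frame anchor of the query (default 1).
#' @param exclude reference specimen ids to leave out (e.g. the query
#'   itself when re-identifying a library member).
#' @return list with \code{status} ("assigned", "ambiguous",
#'   "unassigned"), \code{species_label} (\code{NA} unless assigned),
#'   \code{id_confidence} ("propagated" when assigned) and
#'   \code{candidates}, a \code{DataFrame} of per-species minimum
#'   distances (species below threshold only; full nearest-reference
#'   detail in \code{nearest}).
#' @export
assignSpecimen <- function(query, reference, config = auditConfig(),
                           queryStart = 1L, exclude = NULL) {
    stopifnot(is(reference, "BarcodeLibrary"))
    qqc <- qcSequence(as.character(query), start = queryStart,
                      minLen = config@min_len,
                      frameLength = barcodeFrameLength(reference))
    if (qqc$qc_status != "pass")
        stop("query fails QC (", qqc$qc_status, "); cannot assign")
    ok <- qcReport(reference)$qc_status == "pass" &
        as.character(specimenData(reference)$id_confidence) == "expert"
    ids <- setdiff(specimenIds(reference)[ok], exclude)
    if (!length(ids))
        stop("reference library has no expert-identified specimens")
    ref <- reference[ids]
    enc <- .encodeFrame(
        c(barcodeSequences(ref),
          stats::setNames(Biostrings::DNAStringSet(as.character(query)),
                          ".query")),
        c(frameStart(ref), as.integer(queryStart)),
        barcodeFrameLength(reference))
    q <- enc[nrow(enc), ]
    dd <- vapply(seq_len(nrow(enc) - 1L), function(i)
        .k2pPair(enc[i, ], q, config@min_overlap)$d, numeric(1))
    sp <- speciesLabels(ref)
    perSpecies <- vapply(split(dd, unname(sp)), function(v)
        if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE), numeric(1))
    hit <- perSpecies[!is.na(perSpecies) & perSpecies < config@t_assign]
    hit <- hit[order(names(hit))]
    status <- if (length(hit) == 1L) "assigned"
        else if (length(hit) > 1L) "ambiguous" else "unassigned"
    nearestIdx <- if (all(is.na(dd))) NA_integer_ else which.min(dd)
    list(
        status = status,
        species_label = if (status == "assigned") names(hit)
                        else NA_character_,
        id_confidence = if (status == "assigned") "propagated"
                        else NA_character_,
        candidates = DataFrame(species_label = names(hit),
                               min_d = unname(hit)),
        nearest = if (is.na(nearestIdx)) NULL else
            list(specimen_id = ids[nearestIdx],
                 species_label = unname(sp[nearestIdx]),
                 d = dd[nearestIdx])
    )
}

#' Provisional-name registry
#'
#' A mutable registry of provisional species names in use, used to issue
#' non-colliding serial numbers per genus and taxonomist. Previously
#' published provisional names (possibly with a space after "sp.", e.g.
#' \code{"Acerpenna sp. CHU1"}) can be preloaded as reserved.
#'
#' @param reserved character vector of names to reserve.
#' @return an object of class \code{ProvisionalNameRegistry}.
#' @seealso \code{\link{makeProvisionalName}}
#' @export
provisionalNameRegistry <- function(reserved = character()) {
    env <- new.env(parent = emptyenv())
    env$names <- character()
    reg <- structure(list(env = env), class = "ProvisionalNameRegistry")
    for (nm in reserved) .reserveProvisionalName(reg, nm)
    reg
}

.reserveProvisionalName <- function(registry, name) {
    m <- regmatches(name, regexec(.provisionalPattern, name))[[1L]]
    if (length(m) != 4L)
        stop("not a provisional name: ", name)
    registry$env$names <- union(registry$env$names,
                                paste0(m[2L], "|", m[3L], "|",
                                       as.integer(m[4L])))
    invisible(registry)
}

#' @export
print.ProvisionalNameRegistry <- function(x, ...) {
    cat("ProvisionalNameRegistry with", length(x$env$names),
        "reserved name(s)\n")
    invisible(x)
}

#' Mint a provisional species name
#'
#' Provisional names have the form genus + " sp." + taxonomist initials +
#' serial, e.g. \code{"Heptagenia sp.LJ1"}. The smallest positive serial
#' not colliding with the registry (for that genus and set of initials) is
#' used, and the registry is updated in place.
#'
#' @param genus genus name (non-empty).
#' @param initials taxonomist initials (letters).
#' @param registry a \code{\link{provisionalNameRegistry}}.
#' @return the new provisional name (character).
#' @examples
#' reg <- provisionalNameRegistry()
#' makeProvisionalName("Heptagenia", "LJ", reg)  # "Heptagenia sp.LJ1"
#' makeProvisionalName("Heptagenia", "LJ", reg)  # "Heptagenia sp.LJ2"
#' @export
makeProvisionalName <- function(genus, initials, registry) {
    stopifnot(nzchar(genus), grepl("^[A-Za-z]+$", initials),
              inherits(registry, "ProvisionalNameRegistry"))
    taken <- registry$env$names
    prefix <- paste0(genus, "|", initials, "|")
    used <- as.integer(sub(prefix, "", taken[startsWith(taken, prefix)],
                           fixed = TRUE))
    serial <- 1L
    while (serial %in% used) serial <- serial + 1L
    name <- paste0(genus, " sp.", initials, serial)
    .reserveProvisionalName(registry, name)
    name
}
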