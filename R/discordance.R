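#' Flag specimens discordant with their species label
#'
#' Screens the library for likely misidentifications: a specimen is
#' flagged iff its nearest neighbor (over all other specimens in the
#' matrix, ties to the smallest id) lies strictly closer than
#' \code{t_assign} and carries a different species label, AND its minimum
#' distance to the other specimens of its own species exceeds
#' \code{t_split} (vacuously satisfied for singletons). Undefined
#' distances are treated as absent neighbors.
#'
#' @param dmat a \code{K2PDistanceMatrix}.
#' @param specimens specimen \code{DataFrame} (row names = ids) with
#'   \code{species_label}; or a \code{BarcodeLibrary}.
#' @param config an \code{\link{auditConfig}}.
#' @return \code{DataFrame} of flagged specimens, ordered by id, with
#'   columns \code{specimen_id}, \code{species_label}, \code{nn_id},
#'   \code{nn_species}, \code{nn_d}, \code{own_min_d} (\code{NA} for
#'   singletons).
#' @export
flagDiscordantSpecimens <- function(dmat, specimens,
                                    config = auditConfig()) {
    if (is(specimens, "BarcodeLibrary")) specimens <- specimenData(specimens)
    ids <- intersect(rownames(distances(dmat)), rownames(specimens))
    sp <- stats::setNames(as.character(specimens[ids, "species_label"]), ids)
    d <- distances(dmat)[ids, ids, drop = FALSE]
    flagged <- list()
    for (i in seq_along(ids)) {
        di <- d[i, ]; di[i] <- NA
        if (all(is.na(di))) next
        nnIdx <- which(di == min(di, na.rm = TRUE))
        nnIdx <- nnIdx[order(ids[nnIdx])][1L]
        nnD <- di[nnIdx]
        conspecific <- which(sp == sp[i])
        conspecific <- setdiff(conspecific, i)
        ownMin <- if (length(conspecific)) {
            v <- di[conspecific]
            if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
        } else NA_real_
        ownFar <- length(conspecific) == 0L ||
            (!is.na(ownMin) && ownMin > config@t_split)
        if (nnD < config@t_assign && sp[nnIdx] != sp[i] && ownFar)
            flagged[[length(flagged) + 1L]] <-
                list(ids[i], unname(sp[i]), ids[nnIdx],
                     unname(sp[nnIdx]), unname(nnD), ownMin)
    }
    if (!length(flagged))
        return(DataFrame(specimen_id = character(),
                         species_label = character(),
                         nn_id = character(), nn_species = character(),
                         nn_d = numeric(), own_min_d = numeric()))
    out <- DataFrame(
        specimen_id = vapply(flagged, `[[`, character(1), 1L),
        species_label = vapply(flagged, `[[`, character(1), 2L),
        nn_id = vapply(flagged, `[[`, character(1), 3L),
        nn_species = vapply(flagged, `[[`, character(1), 4L),
        nn_d = vapply(flagged, `[[`, numeric(1), 5L),
        own_min_d = vapply(flagged, `[[`, numeric(1), 6L)
    )
    out[order(out$specimen_id), , drop = FALSE]
}
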