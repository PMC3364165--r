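#' Create an audit configuration
#'
#' @param t_deep deep-divergence threshold on MXID (default 0.022 = 2.2\%;
#'   flag uses strict \code{>}).
#' @param t_split single-linkage cutoff delimiting deep haplotype clusters
#'   (default 0.050).
#' @param t_assign name-assignment divergence threshold (default 0.020).
#' @param mnid_scope where the nearest non-conspecific is sought:
#'   \code{"genus"} (default), \code{"family"} or \code{"all"}.
#' @param min_overlap minimum compared sites for a defined K2P distance
#'   (default 100).
#' @param min_len minimum retained sequence length (default 300).
#' @return an \code{AuditConfig} object.
#' @export
auditConfig <- function(t_deep = 0.022, t_split = 0.050, t_assign = 0.020,
                        mnid_scope = c("genus", "family", "all"),
                        min_overlap = 100L, min_len = 300L) {
    new("AuditConfig", t_deep = t_deep, t_split = t_split,
        t_assign = t_assign, mnid_scope = match.arg(mnid_scope),
        min_overlap = as.integer(min_overlap),
        min_len = as.integer(min_len))
}

setMethod("show", "AuditConfig", function(object) {
    cat(sprintf(paste0("AuditConfig: t_deep=%.3f t_split=%.3f ",
                       "t_assign=%.3f scope=%s min_overlap=%d min_len=%d\n"),
                object@t_deep, object@t_split, object@t_assign,
                object@mnid_scope, object@min_overlap, object@min_len))
})

## Audit-eligible specimens: present in the matrix, not 'unidentified'.
.auditSpecimens <- function(dmat, specimens) {
    ids <- intersect(rownames(distances(dmat)), rownames(specimens))
    conf <- as.character(specimens[ids, "id_confidence"])
    ids[is.na(conf) | conf != "unidentified"]
}

#' Deep haplotype clusters within a species
#'
#' Single-linkage clusters of one species' specimens at the deep-split
#' cutoff; a count of 2 or more marks a putative cryptic complex.
#'
#' @param dmat a \code{K2PDistanceMatrix}.
#' @param ids specimen ids of the species' members.
#' @param t_split divergence cutoff (default 0.05).
#' @return list with \code{count} and the cluster assignment vector.
#' @export
countDeepClusters <- function(dmat, ids, t_split = 0.05) {
    cl <- singleLinkageClusters(dmat, ids, cutoff = t_split)
    list(count = length(unique(cl)), clusters = cl)
}

#' Per-species divergence summary (barcode-gap audit)
#'
#' Computes, for every species in the library, the maximum and mean
#' intraspecific K2P distance (MXID, mean_intra), the minimum distance to
#' any specimen of another species within the configured scope (MNID) and
#' that nearest neighbor's label, the number of single-linkage haplotype
#' clusters at the deep-split cutoff, and the audit flags. Specimens with
#' \code{id_confidence = "unidentified"} are excluded. Statistics over
#' pairs whose distance is undefined (short overlap or saturation) exclude
#' those pairs with a warning; MXID and mean_intra are \code{NA} for
#' singletons, MNID is \code{NA} when no other species occurs in scope.
#'
#' Flags (all strict inequalities):
#' \describe{
#'   \item{deep_divergence}{MXID > \code{t_deep} (default 2.2\%).}
#'   \item{multi_cluster}{at least 2 haplotype clusters at
#'     \code{t_split}.}
#'   \item{gap_overlap}{MXID > MNID, both defined — the local barcode gap
#'     fails.}
#' }
#'
#' @param dmat a \code{K2PDistanceMatrix} covering the specimens.
#' @param specimens specimen \code{DataFrame} (row names = ids) with
#'   \code{species_label}, \code{genus}, \code{family},
#'   \code{id_confidence}, \code{is_provisional}.
#' @param config an \code{\link{auditConfig}}.
#' @param tree optional rooted \code{phylo} over (a superset of) the
#'   specimens; adds a \code{monophyly} column.
#' @return \code{DataFrame} ordered by \code{species_label}.
#' @export
speciesAuditSummary <- function(dmat, specimens, config = auditConfig(),
                                tree = NULL) {
    if (is(specimens, "BarcodeLibrary")) specimens <- specimenData(specimens)
    ids <- .auditSpecimens(dmat, specimens)
    if (length(ids) == 0L) stop("no audit-eligible specimens in matrix")
    sp <- stats::setNames(as.character(specimens[ids, "species_label"]), ids)
    absent <- setdiff(rownames(specimens)[
        as.character(specimens$id_confidence) != "unidentified"],
        rownames(distances(dmat)))
    if (length(absent))
        warning(length(absent), " identified specimen(s) absent from the ",
                "distance matrix are ignored: ",
                paste(utils::head(absent, 5L), collapse = ", "))
    d <- distances(dmat)[ids, ids, drop = FALSE]
    if (anyNA(d[upper.tri(d)]))
        warning("undefined distances excluded from MXID/MNID summaries")
    genus <- stats::setNames(as.character(specimens[ids, "genus"]), ids)
    family <- stats::setNames(as.character(specimens[ids, "family"]), ids)
    mono <- NULL
    if (!is.null(tree)) {
        keep <- intersect(tree$tip.label, ids)
        tr <- if (length(keep) < length(tree$tip.label))
            ape::keep.tip(tree, keep) else tree
        mono <- classifyMonophyly(tr, sp[keep])
    }
    labels <- sort(unique(unname(sp)))
    rows <- lapply(labels, function(s) {
        mem <- ids[sp == s]
        g <- genus[mem[1L]]; f <- family[mem[1L]]
        intra <- if (length(mem) >= 2L) {
            dd <- d[mem, mem, drop = FALSE]
            dd[upper.tri(dd)]
        } else numeric()
        mxid <- if (length(intra) && any(!is.na(intra)))
            max(intra, na.rm = TRUE) else NA_real_
        meanIntra <- if (length(intra) && any(!is.na(intra)))
            mean(intra, na.rm = TRUE) else NA_real_
        scopeIds <- switch(config@mnid_scope,
            genus = ids[genus == g], family = ids[family == f], all = ids)
        other <- scopeIds[sp[scopeIds] != s]
        mnid <- NA_real_; nn <- NA_character_
        if (length(other)) {
            dOther <- d[mem, other, drop = FALSE]
            if (any(!is.na(dOther))) {
                k <- which(dOther == min(dOther, na.rm = TRUE),
                           arr.ind = TRUE)[1L, ]
                mnid <- dOther[k[1L], k[2L]]
                nn <- unname(sp[other[k[2L]]])
            }
        }
        nClust <- countDeepClusters(dmat, mem, config@t_split)$count
        list(s, f, g, length(mem), mxid, meanIntra, mnid, nn, nClust)
    })
    out <- DataFrame(
        species_label = labels,
        family = vapply(rows, `[[`, character(1), 2L),
        genus = vapply(rows, `[[`, character(1), 3L),
        n_specimens = vapply(rows, `[[`, integer(1), 4L),
        MXID = vapply(rows, `[[`, numeric(1), 5L),
        mean_intra = vapply(rows, `[[`, numeric(1), 6L),
        MNID = vapply(rows, `[[`, numeric(1), 7L),
        nearest_neighbor_species = vapply(rows, `[[`, character(1), 8L),
        n_clusters_at_split = vapply(rows, `[[`, integer(1), 9L),
        is_provisional = isProvisionalName(labels)
    )
    if (!is.null(mono))
        out$monophyly <- mono$status[match(out$species_label,
                                           mono$species_label)]
    flagSpecies(out, config)
}

#' Set audit flags on a species summary
#'
#' Recomputes the three audit flags from the summary statistics, with
#' strict inequalities: \code{deep_divergence} iff MXID > \code{t_deep},
#' \code{multi_cluster} iff the species splits into 2+ haplotype clusters
#' at \code{t_split}, \code{gap_overlap} iff MXID and MNID are both
#' defined and MXID > MNID.
#'
#' @param summary a species summary \code{DataFrame} (see
#'   \code{\link{speciesAuditSummary}}).
#' @param config an \code{\link{auditConfig}}.
#' @return the summary with logical columns \code{deep_divergence},
#'   \code{multi_cluster}, \code{gap_overlap}.
#' @export
flagSpecies <- function(summary, config = auditConfig()) {
    summary$deep_divergence <- !is.na(summary$MXID) &
        summary$MXID > config@t_deep
    summary$multi_cluster <- summary$n_clusters_at_split >= 2L
    summary$gap_overlap <- !is.na(summary$MXID) & !is.na(summary$MNID) &
        summary$MXID > summary$MNID
    summary
}

.meanOrNA <- function(x) if (any(!is.na(x))) mean(x, na.rm = TRUE) else NA_real_

#' Family rollup and library-wide statistics
#'
#' Aggregates a per-species audit summary into one row per family
#' (optionally joined against a checklist of known species counts) and a
#' set of library-wide statistics.
#'
#' @param summary output of \code{\link{speciesAuditSummary}}.
#' @param checklist optional data.frame with columns \code{family} and
#'   \code{n_known_species}; families in the checklist but not barcoded
#'   get zero-count rows, barcoded families missing from the checklist get
#'   \code{NA} known counts (with a message).
#' @param config an \code{\link{auditConfig}} (thresholds for the global
#'   percentages).
#' @return list with \code{families} (\code{DataFrame}: family, known /
#'   barcoded / provisional / deep-divergence species counts, mean MXID,
#'   mean MNID) and \code{global} (named list: specimens per species
#'   mean/max, mean MXID, mean of all intraspecific distances, MNID
#'   min/mean/max, percent of species with MXID above \code{t_deep} and
#'   above \code{t_split}, percent with gap overlap).
#' @export
summarizeLibrary <- function(summary, checklist = NULL,
                             config = auditConfig()) {
    fams <- sort(unique(as.character(summary$family)))
    if (!is.null(checklist)) {
        stopifnot(all(c("family", "n_known_species") %in%
                      colnames(checklist)))
        unmatched <- setdiff(fams, checklist$family)
        if (length(unmatched))
            message("families not in checklist: ",
                    paste(unmatched, collapse = ", "))
        fams <- sort(unique(c(fams, as.character(checklist$family))))
    }
    rows <- lapply(fams, function(f) {
        s <- summary[as.character(summary$family) == f, , drop = FALSE]
        known <- if (is.null(checklist)) NA_integer_ else {
            k <- checklist$n_known_species[checklist$family == f]
            if (length(k)) as.integer(k[1L]) else NA_integer_
        }
        list(f, known, nrow(s), sum(s$is_provisional),
             sum(s$deep_divergence), .meanOrNA(s$MXID), .meanOrNA(s$MNID))
    })
    families <- DataFrame(
        family = fams,
        n_known_species = vapply(rows, `[[`, integer(1), 2L),
        n_barcoded_species = vapply(rows, `[[`, integer(1), 3L),
        n_provisional_species = vapply(rows, `[[`, integer(1), 4L),
        n_deep_divergence = vapply(rows, `[[`, integer(1), 5L),
        mean_MXID = vapply(rows, `[[`, numeric(1), 6L),
        mean_MNID = vapply(rows, `[[`, numeric(1), 7L)
    )
    multi <- summary[summary$n_specimens > 1L, , drop = FALSE]
    global <- list(
        n_species = nrow(summary),
        n_specimens = sum(summary$n_specimens),
        mean_specimens_per_species = mean(summary$n_specimens),
        max_specimens_per_species = max(summary$n_specimens),
        mean_MXID = .meanOrNA(summary$MXID),
        mean_intra = .meanOrNA(summary$mean_intra),
        min_MNID = if (any(!is.na(summary$MNID)))
            min(summary$MNID, na.rm = TRUE) else NA_real_,
        mean_MNID = .meanOrNA(summary$MNID),
        max_MNID = if (any(!is.na(summary$MNID)))
            max(summary$MNID, na.rm = TRUE) else NA_real_,
        pct_deep = 100 * mean(multi$MXID > config@t_deep, na.rm = TRUE),
        pct_split = 100 * mean(multi$MXID > config@t_split, na.rm = TRUE),
        pct_gap_overlap = 100 * mean(summary$gap_overlap[
            !is.na(summary$MXID) & !is.na(summary$MNID)])
    )
    list(families = families, global = global)
}

## Report rendering: distances as percent with one decimal, undefined as
## an en dash (Table-style output).
.fmtPct <- function(x, digits = 1L) {
    ifelse(is.na(x), "–", formatC(100 * x, format = "f",
                                       digits = digits))
}

#' Write audit report tables
#'
#' Writes the per-species summary and the family rollup as UTF-8
#' tab-separated files with distances rendered as percent (one decimal)
#' and undefined values as an en dash.
#'
#' @param summary per-species summary \code{DataFrame}.
#' @param rollup output of \code{\link{summarizeLibrary}} (or NULL to skip).
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeAuditTables <- function(summary, rollup = NULL, dir = ".") {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    spPath <- file.path(dir, "species_summary.tsv")
    df <- as.data.frame(summary)
    for (col in c("MXID", "mean_intra", "MNID")) df[[col]] <- .fmtPct(df[[col]])
    df$nearest_neighbor_species[is.na(df$nearest_neighbor_species)] <- "–"
    utils::write.table(df, spPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    paths <- spPath
    if (!is.null(rollup)) {
        famPath <- file.path(dir, "family_summary.tsv")
        fam <- as.data.frame(rollup$families)
        fam$mean_MXID <- .fmtPct(fam$mean_MXID)
        fam$mean_MNID <- .fmtPct(fam$mean_MNID)
        fam$n_known_species[is.na(fam$n_known_species)] <- "–"
        utils::write.table(fam, famPath, sep = "\t", quote = FALSE,
                           row.names = FALSE, fileEncoding = "UTF-8")
        paths <- c(paths, famPath)
    }
    invisible(paths)
}

#' Run the full library audit pipeline
#'
#' Convenience wrapper chaining the audit stages: pairwise K2P distances
#' over QC-passing specimens, the misidentification (discordance) screen,
#' optional label correction of flagged specimens to their nearest
#' neighbor's species (emulating re-examination of discordant vouchers),
#' per-family neighbor-joining trees with midpoint rooting and monophyly
#' classification, the per-species barcode-gap summary and the family
#' rollup.
#'
#' @param lib a \code{BarcodeLibrary}.
#' @param config an \code{\link{auditConfig}}.
#' @param checklist optional known-species checklist (see
#'   \code{\link{summarizeLibrary}}).
#' @param treeScope \code{"family"} (default): one NJ tree per family
#'   with at least 3 QC-passing specimens; \code{"all"}: a single tree
#'   over the whole library (requires every distance defined);
#'   \code{"none"}: skip trees (and monophyly).
#' @param correctDiscordant relabel discordant specimens to their nearest
#'   neighbor's species before the species summary (default FALSE).
#' @return list with \code{distance} (\code{K2PDistanceMatrix}),
#'   \code{discordant}, \code{corrections} (ids relabeled), \code{trees}
#'   (named list of rooted \code{phylo}), \code{monophyly},
#'   \code{summary}, \code{rollup}, \code{shared_haplotypes}.
#' @export
auditLibrary <- function(lib, config = auditConfig(), checklist = NULL,
                         treeScope = c("family", "all", "none"),
                         correctDiscordant = FALSE) {
    stopifnot(is(lib, "BarcodeLibrary"))
    treeScope <- match.arg(treeScope)
    dm <- k2pDistanceMatrix(lib, minOverlap = config@min_overlap)
    disc <- flagDiscordantSpecimens(dm, lib, config)
    specimens <- specimenData(lib)
    corrections <- character()
    if (correctDiscordant && nrow(disc)) {
        specimens[disc$specimen_id, "species_label"] <- disc$nn_species
        corrections <- disc$specimen_id
    }
    ids <- rownames(distances(dm))
    sp <- stats::setNames(as.character(specimens[ids, "species_label"]),
                          ids)
    trees <- list()
    mono <- NULL
    if (treeScope == "all") {
        trees$all <- midpointRoot(njTree(dm))
        mono <- classifyMonophyly(trees$all, sp)
    } else if (treeScope == "family") {
        fam <- as.character(specimens[ids, "family"])
        monoList <- list()
        for (f in sort(unique(fam))) {
            fids <- ids[fam == f]
            if (length(fids) < 3L) next
            sub <- distances(dm)[fids, fids]
            if (anyNA(sub[upper.tri(sub)])) {
                warning("undefined distances within family ", f,
                        "; tree skipped")
                next
            }
            trees[[f]] <- midpointRoot(njTree(sub))
            monoList[[f]] <- classifyMonophyly(trees[[f]], sp[fids])
        }
        if (length(monoList)) mono <- do.call(rbind, monoList)
    }
    summary <- speciesAuditSummary(dm, specimens, config)
    if (!is.null(mono))
        summary$monophyly <- mono$status[match(summary$species_label,
                                               mono$species_label)]
    rollup <- summarizeLibrary(summary, checklist, config)
    list(distance = dm, discordant = disc, corrections = corrections,
         trees = trees, monophyly = mono, summary = summary,
         rollup = rollup,
         shared_haplotypes = detectSharedHaplotypes(dm, sp))
}
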