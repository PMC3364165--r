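## Tip sets (integer tip indices, sorted) for every node of a rooted tree,
## computed by a single postorder sweep over the edge matrix.
.nodeTipSets <- function(tree) {
    n <- length(tree$tip.label)
    M <- n + tree$Nnode
    tr <- ape::reorder.phylo(tree, "postorder")
    tips <- vector("list", M)
    tips[seq_len(n)] <- as.list(seq_len(n))
    for (e in seq_len(nrow(tr$edge))) {
        p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
        tips[[p]] <- c(tips[[p]], tips[[ch]])
    }
    lapply(tips, sort)
}

#' Classify species monophyly on a rooted tree
#'
#' For each species with leaf set L: \emph{monophyletic} if some clade's
#' leaf set equals L; otherwise, with I the leaves under the most recent
#' common ancestor of L that are not in L, \emph{paraphyletic} if I itself
#' forms exactly one clade and \emph{polyphyletic} otherwise. Species with
#' a single specimen are \emph{singleton}.
#'
#' @param tree a rooted \code{phylo} tree (see \code{\link{midpointRoot}};
#'   the para/poly distinction depends on the root).
#' @param species named character vector mapping every tip label to a
#'   species label.
#' @return \code{DataFrame} ordered by species label with columns
#'   \code{species_label}, \code{n_specimens}, \code{status}
#'   (monophyletic / paraphyletic / polyphyletic / singleton) and
#'   \code{intruding_ids} (comma-separated; empty for
#'   monophyletic/singleton).
#' @export
classifyMonophyly <- function(tree, species) {
    stopifnot(inherits(tree, "phylo"))
    if (!ape::is.rooted(tree))
        stop("tree must be rooted (see midpointRoot) to distinguish ",
             "para- from polyphyly")
    miss <- setdiff(tree$tip.label, names(species))
    if (length(miss))
        stop("species map missing tips: ", paste(miss, collapse = ", "))
    tipSets <- .nodeTipSets(tree)
    keys <- vapply(tipSets, paste, character(1), collapse = ",")
    spec <- unname(species[tree$tip.label])
    out <- lapply(sort(unique(spec)), function(s) {
        L <- which(spec == s)
        if (length(L) == 1L)
            return(list(s, 1L, "singleton", ""))
        ## MRCA clade = smallest tip set containing L
        containing <- which(vapply(tipSets, function(ts)
            all(L %in% ts), logical(1)))
        mrca <- containing[which.min(lengths(tipSets)[containing])]
        I <- setdiff(tipSets[[mrca]], L)
        status <- if (length(I) == 0L) "monophyletic"
            else if (paste(I, collapse = ",") %in% keys) "paraphyletic"
            else "polyphyletic"
        list(s, length(L), status,
             paste(sort(tree$tip.label[I]), collapse = ","))
    })
    DataFrame(
        species_label = vapply(out, `[[`, character(1), 1L),
        n_specimens = vapply(out, `[[`, integer(1), 2L),
        status = vapply(out, `[[`, character(1), 3L),
        intruding_ids = vapply(out, `[[`, character(1), 4L)
    )
}
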