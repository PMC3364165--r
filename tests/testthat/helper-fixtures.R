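## Shared fixtures, all built in code.

## A stop-free 658-site sequence: ATT repeated (Ile in the invertebrate
## mitochondrial code; no offset yields TAA/TAG) plus one trailing base.
cleanBase <- function(len = 658L) {
    substr(strrep("ATT", ceiling(len / 3)), 1L, len)
}

mutateAt <- function(s, pos, base) {
    for (k in seq_along(pos)) substr(s, pos[k], pos[k]) <- base[k]
    s
}

## Wrap a plain symmetric distance matrix as a K2PDistanceMatrix so the
## audit operations can be exercised on hand-set distances.
fakeDistanceMatrix <- function(d, n = 600L) {
    z <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
    new("K2PDistanceMatrix", d = d, n = matrix(as.integer(n), nrow(d),
        ncol(d), dimnames = dimnames(d)), P = z, Q = z,
        minOverlap = 100L)
}

symMatrix <- function(ids, entries) {
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (e in entries) m[e[[1]], e[[2]]] <- m[e[[2]], e[[1]]] <- e[[3]]
    m
}

specimenFrame <- function(ids, species, genus = NULL, family = NULL,
                          confidence = "expert") {
    if (is.null(genus)) genus <- sub(" .*$", "", species)
    if (is.null(family)) family <- "Famidae"
    S4Vectors::DataFrame(
        family = rep_len(family, length(ids)),
        genus = rep_len(genus, length(ids)),
        species_label = species,
        id_confidence = rep_len(confidence, length(ids)),
        is_provisional = barcodeAudit::isProvisionalName(species),
        row.names = ids)
}

## A small hand-built library: three congeneric species, three specimens
## each, with planted fixed differences against a clean backbone.
tinyLibrary <- function() {
    base <- cleanBase()
    seqs <- c(
        A1 = base,
        A2 = mutateAt(base, 10, "C"),
        A3 = base,
        B1 = mutateAt(base, c(100, 200), c("G", "C")),
        B2 = mutateAt(base, c(100, 200, 301), c("G", "C", "C")),
        B3 = mutateAt(base, c(100, 200), c("G", "C")),
        C1 = mutateAt(base, c(400, 500, 600), c("G", "G", "G")),
        C2 = mutateAt(base, c(400, 500, 600, 7), c("G", "G", "G", "C")),
        C3 = mutateAt(base, c(400, 500, 600), c("G", "G", "G"))
    )
    sp <- rep(c("Genua alpha", "Genua beta", "Genua gamma"), each = 3)
    BarcodeLibrary(Biostrings::DNAStringSet(seqs),
                   specimenFrame(names(seqs), sp, genus = "Genua"))
}

## Random additive distance matrix from a random tree; returns both.
randomAdditiveCase <- function(ntaxa) {
    tr <- ape::rtree(ntaxa, rooted = FALSE,
                     br = function(n) stats::runif(n, 0.05, 1))
    tr$tip.label <- sprintf("t%02d", seq_len(ntaxa))
    list(tree = tr, d = ape::cophenetic.phylo(tr))
}
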