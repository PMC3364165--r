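## Independent brute-force oracles shared by unit and acceptance tests.

## Brute-force oracle: enumerate every clade's tip set via phangorn and
## apply the definition directly.
bruteMonophyly <- function(tree, species) {
    n <- length(tree$tip.label)
    desc <- phangorn::Descendants(tree, seq_len(n + tree$Nnode), "tips")
    keys <- vapply(desc, function(x) paste(sort(x), collapse = ","),
                   character(1))
    spec <- unname(species[tree$tip.label])
    out <- character()
    for (s in sort(unique(spec))) {
        L <- which(spec == s)
        if (length(L) == 1L) { out[s] <- "singleton"; next }
        Lkey <- paste(sort(L), collapse = ",")
        if (Lkey %in% keys) { out[s] <- "monophyletic"; next }
        mrca <- ape::getMRCA(tree, L)
        I <- sort(setdiff(desc[[mrca]], L))
        out[s] <- if (paste(I, collapse = ",") %in% keys)
            "paraphyletic" else "polyphyletic"
    }
    out
}

## Brute-force oracle over the encoded alignment.
bruteDiagnostics <- function(lib, speciesSet) {
    seqs <- as.character(barcodeSequences(lib))
    sp <- speciesLabels(lib)
    keep <- sp %in% speciesSet & qcReport(lib)$qc_status == "pass"
    seqs <- seqs[keep]; sp <- sp[keep]
    fl <- barcodeFrameLength(lib)
    starts <- frameStart(lib)[names(seqs)]
    state <- function(id, pos) {
        loc <- pos - starts[id] + 1L
        if (loc < 1L || loc > nchar(seqs[id])) return(NA_character_)
        ch <- substr(seqs[id], loc, loc)
        if (ch %in% c("A", "C", "G", "T")) ch else NA_character_
    }
    hits <- list()
    for (s in sort(speciesSet)) for (pos in seq_len(fl)) {
        own <- stats::na.omit(vapply(names(seqs)[sp == s], state,
                                     character(1), pos = pos))
        if (length(own) == 0L || length(unique(own)) != 1L) next
        oth <- stats::na.omit(vapply(names(seqs)[sp != s], state,
                                     character(1), pos = pos))
        if (any(oth == own[1L])) next
        hits[[length(hits) + 1L]] <- c(s, pos, own[1L])
    }
    if (!length(hits)) return(data.frame(species_label = character(),
                                         position = integer(),
                                         state = character()))
    m <- do.call(rbind, hits)
    data.frame(species_label = m[, 1], position = as.integer(m[, 2]),
               state = m[, 3], stringsAsFactors = FALSE)
}
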