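#' Create a simulation configuration
#'
#' See \code{\link{SimulationConfig-class}} for the meaning and defaults
#' of every parameter. Divergence depths are expected pairwise K2P
#' distances; the generator radiates tips from a common ancestor at half
#' the stated depth, so the expected pairwise distance between two tips
#' equals the stated depth.
#'
#' @param seed integer RNG seed.
#' @param ... any \code{SimulationConfig} slot to override.
#' @return a \code{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L, ...) {
    args <- list(...)
    intSlots <- c("n_genera", "species_per_genus", "specimens_per_species",
                  "seq_length", "fragment_length", "misid_count")
    for (s in intersect(names(args), intSlots))
        args[[s]] <- as.integer(args[[s]])
    do.call(new, c(list("SimulationConfig", seed = as.integer(seed)), args))
}

## K2P substitution probabilities after branch length d (expected
## substitutions/site) with transition/transversion rate ratio kappa:
## P(transition) and Q(total transversion). Inverting the K2P distance
## formula on these expectations returns d exactly.
.k2pSubstProbs <- function(d, kappa) {
    E1 <- exp(-4 * d / (kappa + 2))
    E2 <- exp(-2 * d * (kappa + 1) / (kappa + 2))
    list(P = 0.25 + 0.25 * E1 - 0.5 * E2, Q = 0.5 - 0.5 * E1)
}

.TS_PARTNER <- c(2L, 1L, 4L, 3L)   # A<->G, C<->T
.TV_PARTNER1 <- c(3L, 3L, 1L, 1L)
.TV_PARTNER2 <- c(4L, 4L, 2L, 2L)

#' Evolve a sequence under the K2P substitution process
#'
#' Applies an i.i.d. per-site continuous-time Kimura 2-parameter process
#' with transition/transversion rate ratio \code{kappa}, scaled so the
#' expected number of substitutions per site equals \code{t}. Sites with
#' non-concrete bases (ambiguity codes, N, gaps) are left unchanged.
#' Randomness is drawn from R's global RNG; seed it for reproducibility.
#'
#' @param parent nucleotide string.
#' @param t branch length in expected substitutions/site (>= 0).
#' @param kappa transition/transversion rate ratio (default 3).
#' @return the child nucleotide string.
#' @export
evolveSequence <- function(parent, t, kappa = 3) {
    stopifnot(t >= 0)
    if (t == 0) return(parent)
    ch <- strsplit(toupper(as.character(parent)), "")[[1L]]
    code <- .BASE_CODE[ch]
    idx <- which(!is.na(code))
    if (!length(idx)) return(parent)
    pr <- .k2pSubstProbs(t, kappa)
    u <- stats::runif(length(idx))
    from <- code[idx]
    to <- from
    to[u < pr$P] <- .TS_PARTNER[from[u < pr$P]]
    tv1 <- u >= pr$P & u < pr$P + pr$Q / 2
    tv2 <- u >= pr$P + pr$Q / 2 & u < pr$P + pr$Q
    to[tv1] <- .TV_PARTNER1[from[tv1]]
    to[tv2] <- .TV_PARTNER2[from[tv2]]
    ch[idx] <- names(.BASE_CODE)[to]
    paste(ch, collapse = "")
}

## Evolve under K2P but reject in-frame stop codons (purifying
## selection): any codon that ends up as a stop is redrawn from its
## (non-stop) parent codon until clean. Reading frame is codon 1 at
## site 1, matching the codon-wise ancestor. Marginal per-site dynamics
## are K2P conditioned on no stop, a negligible perturbation at the
## depths used here.
.evolveNoStops <- function(parent, t, kappa) {
    child <- evolveSequence(parent, t, kappa)
    ncod <- nchar(child) %/% 3L
    if (ncod == 0L) return(child)
    starts <- seq.int(1L, by = 3L, length.out = ncod)
    stops <- .stopCodons()
    repeat {
        codons <- substring(child, starts, starts + 2L)
        bad <- which(codons %in% stops)
        if (!length(bad)) return(child)
        for (b in bad) {
            s <- starts[b]
            repeat {
                newc <- evolveSequence(substr(parent, s, s + 2L), t, kappa)
                if (!newc %in% stops) break
            }
            substr(child, s, s + 2L) <- newc
        }
    }
}

## Random ancestor: codon-wise draw from the 62 non-stop codons of the
## invertebrate mitochondrial code, plus random bases for a trailing
## partial codon.
.randomAncestor <- function(len) {
    bases <- names(.BASE_CODE)
    codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
    codons <- setdiff(codons, .stopCodons())
    ncod <- len %/% 3L
    rem <- len - 3L * ncod
    paste0(paste(sample(codons, ncod, replace = TRUE), collapse = ""),
           paste(sample(bases, rem, replace = TRUE), collapse = ""))
}

#' Simulate a barcode reference library with known truth
#'
#' Generates a multi-genus, multi-species COI barcode library whose
#' statistical structure is controlled by star radiations: a random
#' stop-free codon-wise ancestor per family, genus ancestors radiating
#' from it, species ancestors radiating from their genus ancestor, and
#' specimens radiating from their species (or cryptic-cluster) ancestor.
#' Radiation depths telescope so that the \emph{expected pairwise} K2P
#' distance between two specimens equals \code{intra_depth} within a
#' species (or cluster), \code{split_depth} across cryptic clusters,
#' \code{inter_depth} across congeneric species and
#' \code{between_genus_depth} across genera of a family. Substitutions
#' that would create an in-frame stop codon are rejected and redrawn
#' (purifying selection), so every emitted full-length sequence passes
#' the QC screen. A configured fraction of species is built as cryptic
#' complexes of 2-3 clusters; a fraction of sequences is truncated to 5'
#' fragments; ambiguities can be masked in at a per-site rate; and a
#' number of specimens get their metadata label swapped to a random
#' congeneric species (sequence untouched). The same seed yields
#' byte-identical output.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with elements \code{library} (a \code{BarcodeLibrary})
#'   and \code{truth} (list: \code{specimens} \code{DataFrame} with
#'   \code{specimen_id}, \code{true_species}, \code{cluster},
#'   \code{is_fragment}, \code{is_misidentified};
#'   \code{cryptic_species}; \code{misidentified} \code{DataFrame};
#'   \code{config}).
#' @export
simulateReferenceLibrary <- function(config = simulationConfig()) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    set.seed(config@seed)
    nGen <- config@n_genera
    nSpG <- config@species_per_genus
    nSpc <- config@specimens_per_species
    nSpecies <- nGen * nSpG
    nCryptic <- floor(config@cryptic_fraction * nSpecies)
    crypticIdx <- if (nCryptic > 0L) sort(sample.int(nSpecies, nCryptic))
                  else integer()
    seqs <- character(); ids <- character()
    meta <- list(); truthRows <- list()
    spCounter <- 0L; spmCounter <- 0L
    speciesLabelsAll <- character(nSpecies)
    ## telescoping branch depths: a pair of tips radiating from a common
    ## ancestor at depth t/2 each sits at expected pairwise distance t,
    ## so each level contributes (level depth - depth already accounted
    ## for below it) / 2 per branch
    bGenus <- (config@between_genus_depth - config@inter_depth) / 2
    bSpecies <- (config@inter_depth - config@intra_depth) / 2
    bCluster <- (config@split_depth - config@intra_depth) / 2
    bTip <- config@intra_depth / 2
    famAnc <- character()
    for (g in seq_len(nGen)) {
        genusName <- sprintf("Genus%02d", g)
        familyName <- sprintf("Family%02d", ceiling(g / 2))
        if (!familyName %in% names(famAnc))
            famAnc[familyName] <- .randomAncestor(config@seq_length)
        genAnc <- .evolveNoStops(famAnc[[familyName]], bGenus,
                                 config@kappa)
        for (s in seq_len(nSpG)) {
            spCounter <- spCounter + 1L
            spLabel <- sprintf("%s taxon%02d", genusName, s)
            speciesLabelsAll[spCounter] <- spLabel
            spAnc <- .evolveNoStops(genAnc, bSpecies, config@kappa)
            isCryptic <- spCounter %in% crypticIdx
            if (isCryptic) {
                k <- sample(2:3, 1L)
                clAnc <- vapply(seq_len(k), function(i)
                    .evolveNoStops(spAnc, bCluster, config@kappa),
                    character(1))
                membership <- rep(seq_len(k), length.out = nSpc)
            } else {
                clAnc <- spAnc
                membership <- rep(1L, nSpc)
            }
            for (m in seq_len(nSpc)) {
                spmCounter <- spmCounter + 1L
                id <- sprintf("SPM%04d", spmCounter)
                seqs[id] <- .evolveNoStops(clAnc[membership[m]], bTip,
                                           config@kappa)
                ids <- c(ids, id)
                meta[[id]] <- list(family = familyName, genus = genusName,
                                   species_label = spLabel)
                truthRows[[id]] <- list(id, spLabel, membership[m])
            }
        }
    }
    n <- length(ids)
    ## 5' fragments
    nFrag <- floor(config@fragment_fraction * n)
    fragIds <- if (nFrag > 0L) sort(ids[sample.int(n, nFrag)])
               else character()
    for (id in fragIds)
        seqs[id] <- substr(seqs[id], 1L, config@fragment_length)
    ## ambiguity masking
    ambIds <- character()
    if (config@ambiguity_rate > 0) {
        for (id in ids) {
            hits <- which(stats::runif(nchar(seqs[id])) <
                          config@ambiguity_rate)
            if (length(hits)) {
                ch <- strsplit(seqs[id], "")[[1L]]
                ch[hits] <- "N"
                seqs[id] <- paste(ch, collapse = "")
                ambIds <- c(ambIds, id)
            }
        }
    }
    ## metadata label swaps (sequences untouched)
    assigned <- vapply(meta, `[[`, character(1), "species_label")
    genusOf <- vapply(meta, `[[`, character(1), "genus")
    misid <- DataFrame(specimen_id = character(),
                       true_species = character(),
                       assigned_label = character())
    if (config@misid_count > 0L) {
        bySpGenus <- split(speciesLabelsAll,
                           sub(" .*$", "", speciesLabelsAll))
        eligible <- ids[lengths(bySpGenus[genusOf[ids]]) >= 2L]
        if (length(eligible) < config@misid_count)
            stop("not enough eligible specimens for misid_count")
        swapIds <- sort(eligible[sample.int(length(eligible),
                                            config@misid_count)])
        newLab <- character(length(swapIds))
        for (i in seq_along(swapIds)) {
            id <- swapIds[i]
            others <- setdiff(bySpGenus[[genusOf[id]]], assigned[id])
            newLab[i] <- others[sample.int(length(others), 1L)]
        }
        misid <- DataFrame(specimen_id = swapIds,
                           true_species = unname(assigned[swapIds]),
                           assigned_label = newLab)
        assigned[swapIds] <- newLab
    }
    specimens <- DataFrame(
        family = unname(genusToFamily <- vapply(meta, `[[`, character(1),
                                                "family")),
        genus = unname(genusOf),
        species_label = unname(assigned),
        id_confidence = "expert",
        life_stage = sample(c("larva", "imago", "subimago"), n,
                            replace = TRUE),
        country = "Canada",
        state_province = sample(c("ON", "MB", "NB", "SK"), n,
                                replace = TRUE),
        latitude = round(stats::runif(n, 42, 58), 4),
        longitude = round(stats::runif(n, -110, -60), 4),
        row.names = ids
    )
    ## configured 5' fragments are genuine records: keep the length
    ## screen at or below the fragment length
    lib <- BarcodeLibrary(Biostrings::DNAStringSet(seqs), specimens,
                          frameLength = config@seq_length,
                          minLen = min(300L, config@fragment_length))
    truth <- list(
        specimens = DataFrame(
            specimen_id = ids,
            true_species = vapply(truthRows, `[[`, character(1), 2L),
            cluster = vapply(truthRows, `[[`, integer(1), 3L),
            is_fragment = ids %in% fragIds,
            is_misidentified = ids %in% misid$specimen_id
        ),
        cryptic_species = speciesLabelsAll[crypticIdx],
        misidentified = misid,
        modified_ids = list(fragment = fragIds, ambiguity = ambIds),
        config = config
    )
    list(library = lib, truth = truth)
}

#' Plant fixed diagnostic states into a species
#'
#' Sets every member of a species to the given base at the given frame
#' positions, so the (position, state) pairs become candidate diagnostic
#' characters. Errors (without modifying anything) if a planted state
#' would create an in-frame stop codon in any member.
#'
#' @param lib a \code{BarcodeLibrary}.
#' @param species_label the target species.
#' @param positions integer vector of 1-based frame positions.
#' @param states character vector of bases in A/C/G/T, parallel to
#'   \code{positions}.
#' @param minLen minimum-length threshold used when re-screening the
#'   modified sequences (default 300).
#' @return list with \code{library} (modified) and \code{planted}
#'   (\code{DataFrame} of species, position, state).
#' @export
plantDiagnostics <- function(lib, species_label, positions, states,
                             minLen = 300L) {
    stopifnot(is(lib, "BarcodeLibrary"),
              length(positions) == length(states),
              all(states %in% names(.BASE_CODE)))
    fl <- barcodeFrameLength(lib)
    if (any(positions < 1L) || any(positions > fl))
        stop("positions must lie within the ", fl, "-site frame")
    members <- specimenIds(lib)[speciesLabels(lib) == species_label]
    if (!length(members)) stop("no members of species ", species_label)
    seqs <- as.character(barcodeSequences(lib))
    starts <- frameStart(lib)
    qc <- qcReport(lib)
    for (id in members) {
        s <- seqs[id]
        for (k in seq_along(positions)) {
            loc <- positions[k] - starts[id] + 1L
            if (loc < 1L || loc > nchar(s)) next
            substr(s, loc, loc) <- states[k]
        }
        newStops <- .stopStarts(s, qc[id, "frame_offset"])
        oldStops <- .stopStarts(seqs[id], qc[id, "frame_offset"])
        if (length(setdiff(newStops, oldStops)))
            stop("planting would create an in-frame stop codon in ", id)
        seqs[id] <- s
    }
    out <- BarcodeLibrary(Biostrings::DNAStringSet(seqs),
                          specimenData(lib), startPos = starts,
                          frameLength = fl, minLen = minLen)
    list(library = out,
         planted = DataFrame(species_label = species_label,
                             position = as.integer(positions),
                             state = states))
}

#' Export a simulated library to disk
#'
#' Writes the FASTA, the specimen table and a specimen-level truth table
#' as UTF-8 tab-separated text. Output is byte-identical for a given
#' simulation seed.
#'
#' @param sim output of \code{\link{simulateReferenceLibrary}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
exportLibrary <- function(sim, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa <- file.path(dir, "library.fasta")
    tsv <- file.path(dir, "specimens.tsv")
    tru <- file.path(dir, "truth.tsv")
    writeBarcodeFasta(sim$library, fa)
    writeSpecimenTable(sim$library, tsv)
    utils::write.table(as.data.frame(sim$truth$specimens), tru,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    invisible(c(fa, tsv, tru))
}
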