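test_that("FASTA reading tokenizes headers, normalizes case and U/T", {
    tf <- withr::local_tempfile(fileext = ".fasta")
    writeLines(c(">X123 Baetis sp.", "acgu", ">Y1", "ACGT"), tf)
    seqs <- readBarcodeFasta(tf)
    expect_identical(names(seqs), c("X123", "Y1"))
    expect_identical(as.character(seqs[["X123"]]), "ACGT")
})

test_that("FASTA reading rejects duplicates and empty files", {
    tf <- withr::local_tempfile(fileext = ".fasta")
    writeLines(c(">A", "ACGT", ">A", "ACGT"), tf)
    expect_error(readBarcodeFasta(tf), "duplicate.*A")
    tf2 <- withr::local_tempfile(fileext = ".fasta")
    writeLines(character(), tf2)
    expect_error(readBarcodeFasta(tf2), "empty")
})

test_that("FASTA and specimen tables round-trip field-for-field", {
    sim <- simulateReferenceLibrary(simulationConfig(
        seed = 2, n_genera = 2, species_per_genus = 2,
        specimens_per_species = 3, misid_count = 0L))
    lib <- sim$library
    fa <- withr::local_tempfile(fileext = ".fasta")
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeBarcodeFasta(lib, fa)
    writeSpecimenTable(lib, tsv)
    seqs2 <- readBarcodeFasta(fa)
    expect_identical(as.character(seqs2),
                     as.character(barcodeSequences(lib)))
    spd2 <- readSpecimenTable(tsv)
    spd1 <- specimenData(lib)
    expect_identical(rownames(spd2), rownames(spd1))
    for (col in c("family", "genus", "species_label", "id_confidence",
                  "life_stage", "country", "state_province"))
        expect_identical(as.character(spd2[[col]]),
                         as.character(spd1[[col]]))
    expect_equal(spd2$latitude, spd1$latitude)
    expect_equal(spd2$longitude, spd1$longitude)
})

test_that("specimen table parsing flags provisional names and tolerates missing coordinates", {
    tf <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c(
        paste("specimen_id", "family", "genus", "species_label",
              "id_confidence", "latitude", sep = "\t"),
        paste("S1", "Heptageniidae", "Heptagenia", "Heptagenia sp.LJ1",
              "expert", "45.1", sep = "\t"),
        paste("S2", "Ephemeridae", "Ephemera", "Ephemera simulans",
              "expert", "", sep = "\t")), tf)
    df <- readSpecimenTable(tf)
    expect_true(df["S1", "is_provisional"])
    expect_false(df["S2", "is_provisional"])
    expect_true(is.na(df["S2", "latitude"]))
    expect_true(is.na(df["S2", "longitude"]))  # absent column filled
})

test_that("specimen table with a missing required column names it", {
    tf <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("specimen_id\tfamily\tgenus", "S1\tF\tG"), tf)
    expect_error(readSpecimenTable(tf), "species_label")
})

test_that("anchoring places sequences on the 658-site frame", {
    full <- anchorToBarcodeFrame(cleanBase(658))
    expect_identical(full$start, 1L)
    expect_identical(full$length, 658L)
    expect_identical(full$qc_status, "pending")
    frag <- anchorToBarcodeFrame(cleanBase(325))
    expect_identical(frag$start, 1L)
    expect_identical(frag$length, 325L)
    short <- anchorToBarcodeFrame(cleanBase(250), minLen = 300)
    expect_identical(short$qc_status, "too_short")
    expect_error(anchorToBarcodeFrame("ACGX"), "non-nucleotide")
    expect_error(anchorToBarcodeFrame(cleanBase(658), start = 2),
                 "frame")
})

test_that("QC detects planted stop codons with their frame position", {
    ## a random-codon sequence pins the reading frame (the two shifted
    ## frames carry incidental stops), so a planted TAA is seen
    sim <- simulateReferenceLibrary(simulationConfig(
        seed = 6, n_genera = 1, species_per_genus = 1,
        specimens_per_species = 1, fragment_fraction = 0,
        misid_count = 0L))
    s <- as.character(barcodeSequences(sim$library)[[1]])
    expect_identical(qcSequence(s)$qc_status, "pass")
    s2 <- mutateAt(s, 100:102, c("T", "A", "A"))
    qc <- qcSequence(s2)
    expect_identical(qc$qc_status, "stop_codon")
    expect_match(qc$stop_positions, "\\b100\\b")
})

test_that("QC flags internal gaps as indels and short sequences as too_short", {
    s <- mutateAt(cleanBase(658), 50, "-")
    qc <- qcSequence(s)
    expect_true(qc$has_indel)
    expect_identical(qc$qc_status, "indel")
    expect_identical(qcSequence(cleanBase(250))$qc_status, "too_short")
})

test_that("frame choice is invariant to 3' truncation by multiples of 3", {
    set.seed(11)
    sim <- simulateReferenceLibrary(simulationConfig(
        seed = 11, n_genera = 1, species_per_genus = 2,
        specimens_per_species = 2, fragment_fraction = 0,
        misid_count = 0L))
    s <- as.character(barcodeSequences(sim$library)[[1]])
    off0 <- qcSequence(s)$frame_offset
    for (cut in c(3, 33, 333)) {
        trunc <- substr(s, 1, nchar(s) - cut)
        expect_identical(qcSequence(trunc, minLen = 100)$frame_offset, off0)
    }
})

test_that("simulator output with no injected artifacts passes QC at 100%", {
    sim <- simulateReferenceLibrary(simulationConfig(
        seed = 3, n_genera = 2, species_per_genus = 3,
        specimens_per_species = 4, ambiguity_rate = 0,
        misid_count = 0L))
    expect_true(all(qcReport(sim$library)$qc_status == "pass"))
})

test_that("library construction enforces id agreement", {
    seqs <- Biostrings::DNAStringSet(c(A = cleanBase(), B = cleanBase()))
    spd <- specimenFrame(c("A", "B", "C"), rep("Genua alpha", 3))
    expect_message(lib <- BarcodeLibrary(seqs, spd), "no sequence")
    expect_identical(specimenIds(lib), c("A", "B"))
    expect_error(BarcodeLibrary(seqs, spd[1, , drop = FALSE]),
                 "without specimen metadata")
})
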