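test_that("hand-set distances yield the expected MXID and MNID", {
    ids <- c("a1", "a2", "b1", "b2")
    d <- symMatrix(ids, list(
        list("a1", "a2", 0.03), list("b1", "b2", 0.01),
        list("a1", "b1", 0.08), list("a1", "b2", 0.09),
        list("a2", "b1", 0.10), list("a2", "b2", 0.12)))
    dm <- fakeDistanceMatrix(d)
    spd <- specimenFrame(ids, c("Genua alpha", "Genua alpha",
                                "Genua beta", "Genua beta"),
                         genus = "Genua")
    s <- speciesAuditSummary(dm, spd)
    a <- s[s$species_label == "Genua alpha", ]
    expect_equal(a$MXID, 0.03)
    expect_equal(a$MNID, 0.08)
    expect_identical(a$nearest_neighbor_species, "Genua beta")
    b <- s[s$species_label == "Genua beta", ]
    expect_equal(b$MXID, 0.01)
    expect_equal(b$mean_intra, 0.01)
})

test_that("singletons and out-of-scope species get undefined statistics", {
    ids <- c("a1", "b1", "c1")
    d <- symMatrix(ids, list(list("a1", "b1", 0.08),
                             list("a1", "c1", 0.20),
                             list("b1", "c1", 0.21)))
    dm <- fakeDistanceMatrix(d)
    ## a and b congeneric; c alone in its genus (and family)
    spd <- S4Vectors::DataFrame(
        family = c("Famidae", "Famidae", "Solidae"),
        genus = c("Genua", "Genua", "Sola"),
        species_label = c("Genua alpha", "Genua beta", "Sola una"),
        id_confidence = "expert",
        is_provisional = FALSE,
        row.names = ids)
    s <- speciesAuditSummary(dm, spd)
    expect_true(all(is.na(s$MXID)))          # all singletons
    expect_equal(s$MNID[s$species_label == "Genua alpha"], 0.08)
    ## no congener for the lone species: MNID undefined under genus scope
    expect_true(is.na(s$MNID[s$species_label == "Sola una"]))
    ## under scope "all" it is defined
    s2 <- speciesAuditSummary(dm, spd, auditConfig(mnid_scope = "all"))
    expect_equal(s2$MNID[s2$species_label == "Sola una"], 0.20)
})

test_that("flags follow strict thresholds", {
    base <- S4Vectors::DataFrame(
        species_label = c("s1", "s2", "s3"),
        MXID = c(0.028, 0.022, 0.037),
        MNID = c(0.10, 0.10, 0.003),
        n_clusters_at_split = c(1L, 1L, 2L))
    f <- flagSpecies(base, auditConfig())
    expect_identical(f$deep_divergence, c(TRUE, FALSE, TRUE))
    expect_identical(f$multi_cluster, c(FALSE, FALSE, TRUE))
    expect_identical(f$gap_overlap, c(FALSE, FALSE, TRUE))
})

test_that("MNID is monotone under widening scope", {
    sim <- simulateReferenceLibrary(simulationConfig(seed = 4))
    dm <- k2pDistanceMatrix(sim$library)
    spd <- specimenData(sim$library)
    g <- suppressWarnings(speciesAuditSummary(dm, spd,
        auditConfig(mnid_scope = "genus")))
    f <- suppressWarnings(speciesAuditSummary(dm, spd,
        auditConfig(mnid_scope = "family")))
    a <- suppressWarnings(speciesAuditSummary(dm, spd,
        auditConfig(mnid_scope = "all")))
    both <- !is.na(g$MNID)
    expect_true(all(f$MNID[both] <= g$MNID[both] + 1e-15))
    both2 <- !is.na(f$MNID)
    expect_true(all(a$MNID[both2] <= f$MNID[both2] + 1e-15))
})

test_that("deep-cluster counts match planted group structure", {
    ids <- sprintf("x%d", 1:6)
    ## three groups of two, split by ~0.07
    d <- matrix(0.07, 6, 6, dimnames = list(ids, ids))
    d[1, 2] <- d[2, 1] <- 0.01
    d[3, 4] <- d[4, 3] <- 0.01
    d[5, 6] <- d[6, 5] <- 0.01
    diag(d) <- 0
    dm <- fakeDistanceMatrix(d)
    expect_identical(countDeepClusters(dm, ids, 0.05)$count, 3L)
    expect_identical(countDeepClusters(dm, ids[1:2], 0.05)$count, 1L)
})

test_that("unidentified specimens are excluded from summaries", {
    ids <- c("a1", "a2", "u1")
    d <- symMatrix(ids, list(list("a1", "a2", 0.01),
                             list("a1", "u1", 0.15),
                             list("a2", "u1", 0.15)))
    spd <- specimenFrame(ids, c("Genua alpha", "Genua alpha", "unknown"),
                         genus = "Genua",
                         confidence = c("expert", "expert",
                                        "unidentified"))
    s <- speciesAuditSummary(fakeDistanceMatrix(d), spd)
    expect_identical(s$species_label, "Genua alpha")
})

test_that("family rollup and global statistics match hand computation", {
    summary <- S4Vectors::DataFrame(
        species_label = c("Genua alpha", "Genua beta", "Sola una"),
        family = c("Famidae", "Famidae", "Solidae"),
        genus = c("Genua", "Genua", "Sola"),
        n_specimens = c(4L, 2L, 1L),
        MXID = c(0.03, 0.01, NA),
        mean_intra = c(0.02, 0.01, NA),
        MNID = c(0.08, 0.12, NA),
        nearest_neighbor_species = c("Genua beta", "Genua alpha", NA),
        n_clusters_at_split = c(1L, 1L, 1L),
        is_provisional = c(FALSE, FALSE, FALSE))
    summary <- flagSpecies(summary, auditConfig())
    checklist <- data.frame(family = c("Famidae", "Empty"),
                            n_known_species = c(5L, 3L))
    expect_message(roll <- summarizeLibrary(summary, checklist),
                   "Solidae")
    fam <- roll$families
    expect_identical(as.character(fam$family),
                     c("Empty", "Famidae", "Solidae"))
    expect_identical(fam$n_barcoded_species, c(0L, 2L, 1L))
    expect_identical(fam$n_known_species, c(3L, 5L, NA_integer_))
    expect_equal(fam$mean_MXID[2], 0.02)
    expect_true(is.na(fam$mean_MXID[1]))
    expect_equal(roll$global$mean_MNID, 0.10)       # mean of 0.08, 0.12
    expect_equal(roll$global$mean_specimens_per_species, 7 / 3)
    expect_equal(roll$global$pct_deep, 50)  # one of two multi-specimen
})

test_that("report tables render percentages and dashes", {
    summary <- S4Vectors::DataFrame(
        species_label = "Sola una", family = "Solidae", genus = "Sola",
        n_specimens = 1L, MXID = NA_real_, mean_intra = NA_real_,
        MNID = 0.079, nearest_neighbor_species = NA_character_,
        n_clusters_at_split = 1L, is_provisional = FALSE)
    summary <- flagSpecies(summary, auditConfig())
    dir <- withr::local_tempdir()
    paths <- writeAuditTables(summary, summarizeLibrary(summary), dir)
    sp <- readLines(file.path(dir, "species_summary.tsv"),
                    encoding = "UTF-8")
    expect_match(sp[2], "7\\.9")
    expect_match(sp[2], "–")
})
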