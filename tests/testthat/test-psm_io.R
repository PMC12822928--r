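test_that("modification strings parse, validate and round-trip", {
  mods <- parse_modifications(c("", "Deamidated:2;Oxidation:7", "Deamidated:4;Deamidated:1"))
  expect_equal(nrow(mods[[1]]), 0)
  expect_equal(mods[[2]]$name, c("Deamidated", "Oxidation"))
  expect_equal(mods[[3]]$position, c(1L, 4L))  # sorted by position
  expect_equal(format_modifications(mods),
               c("", "Deamidated:2;Oxidation:7", "Deamidated:1;Deamidated:4"))
  expect_error(parse_modifications("Deamidated-4"), "malformed")
})

test_that("PSM validation enforces modification placement invariants", {
  # TPEVDDEALEK with no mods is valid (D is sequence-level, not a modification)
  expect_silent(validate_psms(make_psm("TPEVDDEALEK")))
  # Deamidated on K (position 4 of ANQK) violates the N/Q rule
  expect_error(validate_psms(make_psm("ANQK", "Deamidated:4")), "row 1")
  # position outside the peptide
  expect_error(validate_psms(make_psm("ANQK", "Oxidation:9")), "outside")
  # Oxidation allowed on M and P, not elsewhere
  expect_silent(validate_psms(make_psm("AMPK", "Oxidation:2;Oxidation:3")))
  expect_error(validate_psms(make_psm("AMPK", "Oxidation:1")), "not allowed")
  expect_error(validate_psms(make_psm("ACK", "Carbamidomethyl:1")), "not allowed")
  expect_silent(validate_psms(make_psm("ACK", "Carbamidomethyl:2")))
})

test_that("generic PSM table round-trips bit-for-bit", {
  psms <- rbind(
    make_psm("TPEVDDEALEK", sample_id = "220", site = "Mamai-Gora"),
    make_psm("ANQK", "Deamidated:2", accessions = "A1;A2", is_decoy = TRUE),
    make_psm("AMPK", "Oxidation:2", ion_score = 12.5, e_value = 0.2)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(psms, path)
  back <- read_psm_table(path)
  rownames(psms) <- NULL
  expect_equal(back, psms)
})

test_that("PSM reading rejects missing columns and bad rows with row numbers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample_id\tpeptide", path)
  expect_error(read_psm_table(path), "individual_id")
  psms <- make_psm("ANQK")
  psms$e_value <- "not-a-number"
  path2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(psms, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_psm_table(path2), "row 1")
  # header-only file -> empty table, not an error
  utils::write.table(make_psm("ANQK")[0, ], path2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_equal(nrow(read_psm_table(path2)), 0)
})

test_that("mascot_csv dialect maps onto the canonical schema", {
  psms <- make_psm("TPEVDDEALEK", sample_id = "143")
  mascot <- data.frame(
    sample_id = psms$sample_id, individual_id = psms$individual_id,
    site = psms$site, subsite = psms$subsite,
    pep_scan_title = psms$spectrum_ref, pep_seq = psms$peptide,
    pep_var_mods = psms$modifications, prot_acc = psms$accessions,
    pep_score = psms$ion_score, pep_expect = psms$e_value,
    pep_isdecoy = psms$is_decoy, pep_exp_mz = psms$precursor_mz,
    pep_exp_z = psms$charge, stringsAsFactors = FALSE
  )
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(mascot, path, row.names = FALSE)
  back <- read_psm_table(path, dialect = "mascot_csv")
  expect_equal(back$peptide, psms$peptide)
  expect_equal(back$ion_score, psms$ion_score)
  expect_equal(names(back), names(psms))
})

test_that("MGF parsing sorts peaks, keys by TITLE and round-trips", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=scan_1", "PEPMASS=500.25", "CHARGE=2+",
               "300.1 10", "150.2 5", "420.9 2.5", "END IONS"), path)
  sp <- read_mgf(path)
  expect_named(sp, "scan_1")
  expect_equal(sp$scan_1$peaks[, "mz"], c(150.2, 300.1, 420.9))
  expect_equal(sp$scan_1$precursor_mz, 500.25)

  # duplicate TITLE is ambiguous
  writeLines(c("BEGIN IONS", "TITLE=s", "PEPMASS=1", "100 1", "END IONS",
               "BEGIN IONS", "TITLE=s", "PEPMASS=2", "100 1", "END IONS"), path)
  expect_error(read_mgf(path), "duplicate")

  # missing PEPMASS names the block
  writeLines(c("BEGIN IONS", "TITLE=a", "PEPMASS=1", "100 1", "END IONS",
               "BEGIN IONS", "TITLE=b", "100 1", "END IONS"), path)
  expect_error(read_mgf(path), "block 2")

  # write-then-read round trip within 1e-6
  orig <- spectrum("rt", 612.345678, 2L,
                   cbind(c(100.123456, 250.5, 900.000001), c(1.5, 22, 0.25)))
  write_mgf(list(orig), path)
  back <- read_mgf(path)[["rt"]]
  expect_equal(back$peaks, orig$peaks, tolerance = 1e-6)
  expect_equal(back$precursor_mz, orig$precursor_mz, tolerance = 1e-6)
})

test_that("reference loading validates lineages and resolves category overlap", {
  refdb <- generate_reference_db(3)
  dir <- withr::local_tempdir()
  write_reference_files(refdb$refsets, refdb$tree, dir)
  loaded <- load_reference_sets(file.path(dir, "dietary.fasta"),
                                file.path(dir, "lists.yaml"),
                                file.path(dir, "taxonomy.tsv"))
  expect_equal(sort(loaded$refsets$dietary$accession),
               sort(refdb$refsets$dietary$accession))
  expect_equal(loaded$refsets$reassignment_rules, c(SYN_STAPH01 = "BLG"))

  # accession in both lab and oral lists -> lab wins, with a warning
  y <- yaml::read_yaml(file.path(dir, "lists.yaml"))
  y$oral_microbiome <- c(y$oral_microbiome, y$lab_contaminants[[1]])
  yaml::write_yaml(y, file.path(dir, "lists.yaml"))
  expect_warning(
    loaded2 <- load_reference_sets(file.path(dir, "dietary.fasta"),
                                   file.path(dir, "lists.yaml"),
                                   file.path(dir, "taxonomy.tsv")),
    "precedence"
  )
  expect_false(y$lab_contaminants[[1]] %in% loaded2$refsets$oral_microbiome)
  expect_true(y$lab_contaminants[[1]] %in% loaded2$refsets$lab_contaminants)

  # lineage node absent from taxonomy -> error
  lin <- utils::read.delim(file.path(dir, "dietary_lineages.tsv"),
                           colClasses = "character")
  lin$lineage[1] <- "Life>Atlantis>Bos"
  utils::write.table(lin, file.path(dir, "dietary_lineages.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(load_reference_sets(file.path(dir, "dietary.fasta"),
                                   file.path(dir, "lists.yaml"),
                                   file.path(dir, "taxonomy.tsv")),
               "Atlantis")
})

test_that("generated PSM tables always satisfy the modification invariants", {
  sim <- simulate_study(simulation_params(n_samples = 2L,
                                          psm_per_sample = 150L, seed = 11))
  expect_silent(validate_psms(sim$psms))
  mods <- parse_modifications(sim$psms$modifications)
  for (i in seq_along(mods)) {
    m <- mods[[i]]
    if (!nrow(m)) next
    res <- substring(sim$psms$peptide[i], m$position, m$position)
    expect_true(all(res[m$name == "Deamidated"] %in% c("N", "Q")))
  }
})
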