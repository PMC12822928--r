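# Independent mass oracle: b/y m/z assembled from a second mass table,
# summed in the opposite direction to the implementation's cumulative sums.
oracle_by_mz <- function(peptide, series, index, z = 1) {
  masses <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
              V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
              I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
              K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
              F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
  res <- rev(strsplit(peptide, "")[[1]])  # reversed on purpose
  n <- length(res)
  frag <- if (series == "b") rev(res)[seq_len(index)] else res[seq_len(index)]
  neutral <- sum(masses[frag]) + if (series == "y") 18.01056 else 0
  (neutral + z * 1.00728) / z
}

test_that("b/y fragment m/z match the monoisotopic mass oracle", {
  fr <- predict_fragments("AG", charge = 1L)
  b1 <- fr$ions[fr$ions$series == "b" & fr$ions$index == 1, ]
  y1 <- fr$ions[fr$ions$series == "y" & fr$ions$index == 1, ]
  expect_equal(b1$mz, 72.04439, tolerance = 1e-7)
  expect_equal(y1$mz, 76.03930, tolerance = 1e-7)

  for (pep in c("TPEVDDEALEK", "ANQKW", "MCHPR")) {
    fr <- predict_fragments(pep, charge = 2L)
    for (i in seq_len(nrow(fr$ions))) {
      row <- fr$ions[i, ]
      expect_equal(row$mz,
                   oracle_by_mz(pep, row$series, row$index, row$ion_charge),
                   tolerance = 1e-9)
    }
  }
  expect_error(predict_fragments("A"), "length")
})

test_that("modification deltas shift exactly the ions containing the residue", {
  plain <- predict_fragments("ACK", charge = 1L)$ions
  mod <- predict_fragments("ACK", "Carbamidomethyl:2", charge = 1L)$ions
  delta <- mod$mz - plain$mz
  contains_c <- (mod$series == "b" & mod$index >= 2) |
    (mod$series == "y" & mod$index >= 2)
  expect_equal(delta[contains_c], rep(57.02146, sum(contains_c)),
               tolerance = 1e-9)
  expect_equal(delta[!contains_c], rep(0, sum(!contains_c)))
  # deamidation shifts by +0.98402
  plain <- predict_fragments("ANK", charge = 1L)$ions
  mod <- predict_fragments("ANK", "Deamidated:2", charge = 1L)$ions
  expect_equal(max(mod$mz - plain$mz), 0.98402, tolerance = 1e-9)
  expect_error(predict_fragments("ACK", "Carbamidomethyl:9"), "outside")
})

test_that("precursor stripping removes exactly the windowed peaks", {
  sp <- spectrum("s", 500.3, 2L, cbind(c(500.0, 500.5, 900.0), c(1, 2, 3)))
  out <- strip_precursor(sp, 500.3, 1.0)
  expect_equal(unname(out$peaks[, "mz"]), 900.0)
  out <- strip_precursor(sp, 100.0, 1.0)   # no peak in window
  expect_equal(out$peaks, sp$peaks)
  out <- strip_precursor(sp, 700.15, 250)  # everything in window
  expect_equal(nrow(out$peaks), 0)
  expect_error(strip_precursor(sp, 500, 0), "halfwidth")
})

test_that("self-match scores Pearson 1 and empty observations are undefined", {
  fr <- predict_fragments("TPEVDDEALEK", charge = 2L)
  self <- spectrum("s", 0, 2L, cbind(fr$ions$mz, fr$ions$predicted_intensity))
  sc <- score_psm(self, fr, tol_da = 0.001)
  expect_equal(sc$pearson, 1.0, tolerance = 1e-9)
  expect_equal(sc$n_matched, nrow(fr$ions))
  expect_equal(sc$contrast_angle, 1.0, tolerance = 1e-9)

  empty <- spectrum("e", 0, 2L, cbind(numeric(), numeric()))
  sc <- score_psm(empty, fr)
  expect_true(is.na(sc$pearson))
  expect_error(score_psm(self, list(ions = fr$ions[0, ])), "empty")
})

test_that("Pearson score is invariant under rescaling of either vector", {
  fr <- predict_fragments("ANQKW", charge = 2L)
  obs <- spectrum("s", 0, 2L,
                  cbind(fr$ions$mz, fr$ions$predicted_intensity *
                          exp(rnorm(nrow(fr$ions), 0, 0.2))))
  base <- score_psm(obs, fr)$pearson
  scaled_obs <- obs
  scaled_obs$peaks[, "intensity"] <- scaled_obs$peaks[, "intensity"] * 37
  expect_equal(score_psm(scaled_obs, fr)$pearson, base, tolerance = 1e-12)
  scaled_pred <- fr
  scaled_pred$ions$predicted_intensity <- fr$ions$predicted_intensity / 19
  expect_equal(score_psm(obs, scaled_pred)$pearson, base, tolerance = 1e-12)
})

test_that("raising the match tolerance never decreases n_matched", {
  set.seed(3)
  fr <- predict_fragments("TPEVDDEALEK", charge = 2L)
  obs <- spectrum("s", 0, 2L,
                  cbind(fr$ions$mz + rnorm(nrow(fr$ions), 0, 0.01),
                        fr$ions$predicted_intensity))
  n <- vapply(c(0.001, 0.005, 0.01, 0.05, 0.1),
              function(tol) score_psm(obs, fr, tol)$n_matched, numeric(1))
  expect_true(all(diff(n) >= 0))
})

test_that("noisy self-matches score high; shuffled decoys score lower", {
  set.seed(1234)
  peptide <- "TPEVDDEALEK"
  wins <- 0L
  for (trial in 1:100) {
    fr <- predict_fragments(peptide, charge = 2L)
    noisy <- fr$ions$predicted_intensity * exp(rnorm(nrow(fr$ions), 0, 0.05))
    keep <- !duplicated(round(fr$ions$mz, 6))
    obs <- spectrum("s", 0, 2L, cbind(fr$ions$mz[keep], noisy[keep]))
    self <- score_psm(obs, fr)$pearson
    expect_gte(self, 0.95)
    decoy_pep <- paste(sample(strsplit(peptide, "")[[1]]), collapse = "")
    decoy <- score_psm(obs, predict_fragments(decoy_pep, charge = 2L))$pearson
    if (is.na(decoy) || decoy < self) wins <- wins + 1L
  }
  expect_gte(wins, 95)
})

test_that("dietary validation applies score gate, thresholds and min-PSM rule", {
  refsets <- make_refsets(dietary = data.frame(
    accession = c("DIET_A", "DIET_B"), protein_name = c("BLG", "ASC"),
    sequence = c("TPEVDDEALEK", "AMPKW"), lineage = NA, taxon = "Bos",
    stringsAsFactors = FALSE))
  cfg <- pipeline_config()
  mk_spec <- function(peptide, mods, ref, noise_sd = 0, junk = FALSE) {
    fr <- predict_fragments(peptide, mods, 2L)
    set.seed(nchar(ref))
    int <- if (junk) rev(fr$ions$predicted_intensity) + runif(nrow(fr$ions), 0, 50)
           else fr$ions$predicted_intensity * exp(rnorm(nrow(fr$ions), 0, noise_sd))
    keep <- !duplicated(round(fr$ions$mz, 6))
    spectrum(ref, precursor_mz(peptide, 2L, mods), 2L,
             cbind(fr$ions$mz[keep], int[keep]))
  }
  psms <- rbind(
    make_psm("TPEVDDEALEK", accessions = "DIET_A", ion_score = 55,
             spectrum_ref = "high"),                       # above cutoff
    make_psm("TPEVDDEALEK", accessions = "DIET_A", ion_score = 30,
             spectrum_ref = "good_low", e_value = 2e-4),   # scored, passes
    make_psm("AMPKW", "Oxidation:2", accessions = "DIET_B", ion_score = 25,
             spectrum_ref = "oxidized"),                   # 0.60 threshold
    make_psm("GGSSK", accessions = "ORAL_A")
  )
  spectra <- list(
    good_low = mk_spec("TPEVDDEALEK", "", "good_low", noise_sd = 0.05),
    oxidized = mk_spec("AMPKW", "Oxidation:2", "oxidized", noise_sd = 0.2)
  )
  out <- validate_dietary(psms, spectra, refsets, cfg)
  res <- out$results
  expect_equal(res$decision[res$spectrum_ref == "high"], "pass_ion_score")
  expect_equal(res$decision[res$spectrum_ref == "good_low"], "pass_pearson")
  expect_equal(res$threshold_used[res$spectrum_ref == "oxidized"], 0.60)
  # non-dietary PSMs pass through untouched
  expect_true("ORAL_A" %in% out$kept$accessions)

  # a spectral exclusion that strands a protein at 1 PSM removes that PSM too
  psms2 <- rbind(
    make_psm("TPEVDDEALEK", accessions = "DIET_A", ion_score = 30,
             spectrum_ref = "ok"),
    make_psm("TPEVDDEALEK", accessions = "DIET_A", ion_score = 30,
             spectrum_ref = "junk")
  )
  spectra2 <- list(ok = mk_spec("TPEVDDEALEK", "", "ok", noise_sd = 0.05),
                   junk = mk_spec("TPEVDDEALEK", "", "junk", junk = TRUE))
  out2 <- validate_dietary(psms2, spectra2, refsets, cfg)
  expect_equal(sort(out2$results$decision), c("fail_min_psm", "fail_pearson"))
  expect_equal(nrow(out2$kept), 0)

  # missing spectrum for a PSM that needs scoring names the reference
  expect_error(validate_dietary(psms2, spectra2["ok"], refsets, cfg), "junk")
})
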