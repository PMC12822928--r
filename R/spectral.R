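#' Remove the precursor ion peak from a spectrum
#'
#' @param sp a `calcproteo_spectrum`.
#' @param precursor precursor m/z around which peaks are stripped.
#' @param halfwidth window half-width in m/z (> 0); peaks with
#'   |mz - precursor| <= halfwidth are removed.
#' @return The stripped spectrum.
#' @export
strip_precursor <- function(sp, precursor = sp$precursor_mz, halfwidth = 1.0) {
  if (halfwidth <= 0) stop("halfwidth must be > 0", call. = FALSE)
  keep <- abs(sp$peaks[, "mz"] - precursor) > halfwidth
  sp$peaks <- sp$peaks[keep, , drop = FALSE]
  sp
}

#' Score a PSM against a predicted fragment spectrum
#'
#' For every predicted ion the observed intensity is the largest peak
#' intensity within +/- `tol_da` of the predicted m/z (0 if no peak falls in
#' the window). The Pearson correlation between predicted and observed
#' intensity vectors over all predicted ions is the validation score; the
#' normalised spectral contrast angle over the same vectors is reported
#' alongside. If either vector has zero variance the correlation is undefined
#' (`NA`) and validation fails downstream.
#'
#' @param observed a precursor-stripped `calcproteo_spectrum`.
#' @param predicted a `calcproteo_fragments`.
#' @param tol_da fragment-match tolerance in Da.
#' @return A list with `pearson`, `contrast_angle` and `n_matched` (predicted
#'   ions with at least one observed peak in the window).
#' @export
score_psm <- function(observed, predicted, tol_da = 0.01) {
  ions <- predicted$ions
  if (!nrow(ions)) stop("predicted ion list is empty", call. = FALSE)
  peaks <- observed$peaks
  obs <- vapply(ions$mz, function(m) {
    inside <- abs(peaks[, "mz"] - m) <= tol_da
    if (any(inside)) max(peaks[inside, "intensity"]) else 0
  }, numeric(1))
  pred <- ions$predicted_intensity
  pearson <- if (stats::sd(obs) == 0 || stats::sd(pred) == 0) {
    NA_real_
  } else {
    stats::cor(obs, pred)
  }
  dot <- sum(obs * pred)
  norm <- sqrt(sum(obs^2)) * sqrt(sum(pred^2))
  contrast <- if (norm == 0) NA_real_ else 1 - 2 * acos(pmin(1, dot / norm)) / pi
  list(pearson = pearson, contrast_angle = contrast, n_matched = sum(obs > 0))
}

#' Spectrally validate low-scoring dietary PSMs
#'
#' Dietary PSMs with ion score at or above the cutoff pass without spectral
#' scoring. PSMs below the cutoff are scored against the predicted fragment
#' spectrum of their peptide after precursor stripping; the Pearson threshold
#' is 0.60 when the PSM carries any Oxidation modification (methionine or
#' proline) and 0.70 otherwise. After spectral removals the minimum-PSM-per-
#' protein rule is re-applied to the dietary proteins, excluding PSMs of
#' proteins left under-supported.
#'
#' @param psms filtered PSM data frame.
#' @param spectra named spectrum list (from [read_mgf()]) covering every PSM
#'   that requires scoring.
#' @param refsets a `calcproteo_refsets`.
#' @param config a [pipeline_config()].
#' @param predictor optional plug-in intensity predictor for
#'   [predict_fragments()].
#' @return A list with `kept` (non-dietary PSMs plus surviving dietary PSMs)
#'   and `results`, one row per dietary PSM: `spectrum_ref`, `peptide`,
#'   `ion_score`, `pearson`, `contrast_angle`, `n_matched`, `threshold_used`,
#'   `decision` (`pass_ion_score`, `pass_pearson`, `fail_pearson`,
#'   `fail_undefined`, `fail_min_psm`) and `validated`.
#' @export
validate_dietary <- function(psms, spectra, refsets, config = pipeline_config(),
                             predictor = NULL) {
  cats <- classify_psm(psms, refsets)
  dietary_idx <- which(cats == "dietary")
  others <- psms[cats != "dietary", , drop = FALSE]
  if (!length(dietary_idx)) {
    return(list(kept = psms, results = data.frame(
      spectrum_ref = character(), peptide = character(), ion_score = numeric(),
      pearson = numeric(), contrast_angle = numeric(), n_matched = integer(),
      threshold_used = numeric(), decision = character(), validated = logical(),
      stringsAsFactors = FALSE)))
  }
  diet <- psms[dietary_idx, , drop = FALSE]
  needs_scoring <- diet$ion_score < config$ion_score_validation_cutoff
  missing <- setdiff(diet$spectrum_ref[needs_scoring], names(spectra))
  if (length(missing)) {
    stop("spectra missing for PSM(s) requiring validation: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- nrow(diet)
  results <- data.frame(
    spectrum_ref = diet$spectrum_ref, peptide = diet$peptide,
    ion_score = diet$ion_score, pearson = NA_real_,
    contrast_angle = NA_real_, n_matched = NA_integer_,
    threshold_used = NA_real_, decision = NA_character_,
    validated = FALSE, stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    if (!needs_scoring[i]) {
      results$decision[i] <- "pass_ion_score"
      results$validated[i] <- TRUE
      next
    }
    mods <- parse_modifications(diet$modifications[i])[[1]]
    thr <- if (any(mods$name == "Oxidation")) {
      config$pearson_threshold_oxidized
    } else {
      config$pearson_threshold_unmodified
    }
    results$threshold_used[i] <- thr
    sp <- strip_precursor(spectra[[diet$spectrum_ref[i]]],
                          precursor = diet$precursor_mz[i],
                          halfwidth = config$precursor_strip_halfwidth_mz)
    pred <- predict_fragments(diet$peptide[i], diet$modifications[i],
                              diet$charge[i], predictor = predictor)
    sc <- score_psm(sp, pred, tol_da = config$fragment_match_tol_da)
    results$pearson[i] <- sc$pearson
    results$contrast_angle[i] <- sc$contrast_angle
    results$n_matched[i] <- sc$n_matched
    if (is.na(sc$pearson)) {
      results$decision[i] <- "fail_undefined"
    } else if (sc$pearson >= thr) {
      results$decision[i] <- "pass_pearson"
      results$validated[i] <- TRUE
    } else {
      results$decision[i] <- "fail_pearson"
    }
  }
  # re-apply min-PSM-per-protein to the surviving dietary PSMs
  acc <- primary_accession(diet)
  support <- table(acc[results$validated])
  under <- results$validated &
    support[acc] < config$min_psm_per_protein
  under[is.na(under)] <- FALSE
  if (any(under)) {
    results$decision[under] <- "fail_min_psm"
    results$validated[under] <- FALSE
  }
  kept <- rbind(others, diet[results$validated, , drop = FALSE])
  rownames(kept) <- NULL
  list(kept = kept, results = results)
}
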