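#' Pipeline configuration
#'
#' Bundles every tunable threshold of the inference chain. Defaults mirror the
#' settings a typical ancient-calculus study runs with: an e-value cut-off of
#' 0.01 and a minimum of 2 PSMs per protein for the initial filter, sample
#' exclusion above 5% protein / 2% peptide FDR, an oral-signature pass
#' threshold of 0.5 on the min-max normalised score, spectral validation of
#' dietary PSMs scoring below a Mascot-style ion score of 40 with Pearson
#' thresholds 0.70 (unmodified) / 0.60 (oxidised), a 0.01 Da fragment-match
#' tolerance and a 1.0 m/z precursor-strip half-width.
#'
#' @param e_value_max maximum PSM e-value retained by the filter.
#' @param min_psm_per_protein minimum surviving PSMs a primary accession needs.
#' @param protein_fdr_max_pct,peptide_fdr_max_pct FDR gates in percent
#'   (inclusive upper bounds).
#' @param auth_threshold normalised oral-signature score needed to pass
#'   (inclusive).
#' @param ion_score_validation_cutoff dietary PSMs below this ion score are
#'   spectrally validated.
#' @param pearson_threshold_unmodified,pearson_threshold_oxidized Pearson
#'   thresholds for spectral validation without / with an Oxidation
#'   modification.
#' @param fragment_match_tol_da tolerance (Da) when matching predicted
#'   fragment m/z to observed peaks.
#' @param precursor_strip_halfwidth_mz half-width (m/z) of the window removed
#'   around the precursor before spectral scoring.
#' @param random_seed integer seed governing every stochastic component.
#' @return A list of class `calcproteo_config`.
#' @export
pipeline_config <- function(e_value_max = 0.01,
                            min_psm_per_protein = 2L,
                            protein_fdr_max_pct = 5,
                            peptide_fdr_max_pct = 2,
                            auth_threshold = 0.5,
                            ion_score_validation_cutoff = 40,
                            pearson_threshold_unmodified = 0.70,
                            pearson_threshold_oxidized = 0.60,
                            fragment_match_tol_da = 0.01,
                            precursor_strip_halfwidth_mz = 1.0,
                            random_seed = 1L) {
  cfg <- list(
    e_value_max = as.numeric(e_value_max),
    min_psm_per_protein = as.integer(min_psm_per_protein),
    protein_fdr_max_pct = as.numeric(protein_fdr_max_pct),
    peptide_fdr_max_pct = as.numeric(peptide_fdr_max_pct),
    auth_threshold = as.numeric(auth_threshold),
    ion_score_validation_cutoff = as.numeric(ion_score_validation_cutoff),
    pearson_threshold_unmodified = as.numeric(pearson_threshold_unmodified),
    pearson_threshold_oxidized = as.numeric(pearson_threshold_oxidized),
    fragment_match_tol_da = as.numeric(fragment_match_tol_da),
    precursor_strip_halfwidth_mz = as.numeric(precursor_strip_halfwidth_mz),
    random_seed = as.integer(random_seed)
  )
  thresholds <- unlist(cfg[c("e_value_max", "min_psm_per_protein",
                             "protein_fdr_max_pct", "peptide_fdr_max_pct",
                             "auth_threshold", "ion_score_validation_cutoff",
                             "fragment_match_tol_da",
                             "precursor_strip_halfwidth_mz")])
  if (any(!is.finite(thresholds)) || any(thresholds < 0)) {
    stop("all thresholds must be finite and >= 0", call. = FALSE)
  }
  prs <- c(cfg$pearson_threshold_unmodified, cfg$pearson_threshold_oxidized)
  if (any(prs < -1 | prs > 1)) {
    stop("pearson thresholds must lie in [-1, 1]", call. = FALSE)
  }
  structure(cfg, class = "calcproteo_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected so that typos in a config file surface loudly.
#'
#' @param path path to a YAML file whose top-level keys are
#'   [pipeline_config()] arguments.
#' @return A `calcproteo_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' @export
print.calcproteo_config <- function(x, ...) {
  cat("calcproteo pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-30s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
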