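#' Target-decoy false discovery rate
#'
#' FDR% = 100 x (distinct decoy units) / (distinct target units), with the
#' unit a distinct primary accession at the protein level and a distinct
#' (peptide, modifications) pair at the peptide level.
#'
#' @param psms a PSM data frame with decoy flags.
#' @param level `"protein"` or `"peptide"`.
#' @return FDR in percent; 0 when there are targets but no decoys.
#' @export
compute_fdr <- function(psms, level = c("protein", "peptide")) {
  level <- match.arg(level)
  if (!nrow(psms)) stop("cannot compute FDR on an empty PSM set", call. = FALSE)
  unit <- if (level == "protein") {
    primary_accession(psms)
  } else {
    mods <- format_modifications(parse_modifications(psms$modifications))
    paste(psms$peptide, mods, sep = "|")
  }
  targets <- length(unique(unit[!psms$is_decoy]))
  decoys <- length(unique(unit[psms$is_decoy]))
  if (targets == 0L) {
    stop("no target units; FDR undefined", call. = FALSE)
  }
  100 * decoys / targets
}

#' Filter PSMs by e-value and minimum PSM support per protein
#'
#' Two rules applied in order, once (no fixpoint iteration): (1) drop PSMs
#' with e-value above `e_value_max`; (2) drop target PSMs whose primary
#' accession is supported by fewer than `min_psm_per_protein` surviving
#' target PSMs. Decoy PSMs surviving the e-value rule are counted for the FDR
#' estimates but removed from the kept set.
#'
#' @param psms a PSM data frame for one sample.
#' @param config a [pipeline_config()].
#' @return A list with `kept` (target PSMs passing both rules) and `report`
#'   (sample id, in/out counts, protein and peptide FDR percent over the
#'   post-e-value set, the quality-gate verdict, and a removal log with one
#'   row per removed PSM and its reason).
#' @export
apply_filters <- function(psms, config = pipeline_config()) {
  validate_psms(psms)
  sample_id <- if (nrow(psms)) unique(psms$sample_id)[1] else NA_character_
  empty_log <- data.frame(psm_index = integer(), reason = character(),
                          stringsAsFactors = FALSE)
  if (!nrow(psms)) {
    report <- list(sample_id = sample_id, n_psm_in = 0L, n_psm_out = 0L,
                   protein_fdr_pct = NA_real_, peptide_fdr_pct = NA_real_,
                   passed_gate = NA, removal_log = empty_log)
    return(list(kept = psms, report = report))
  }
  idx <- seq_len(nrow(psms))
  reason <- rep(NA_character_, nrow(psms))

  surv_e <- psms$e_value <= config$e_value_max
  reason[!surv_e] <- "e_value"

  post_e <- psms[surv_e, , drop = FALSE]
  protein_fdr <- if (any(!post_e$is_decoy)) compute_fdr(post_e, "protein") else NA_real_
  peptide_fdr <- if (any(!post_e$is_decoy)) compute_fdr(post_e, "peptide") else NA_real_

  reason[surv_e & psms$is_decoy] <- "decoy"

  is_target <- surv_e & !psms$is_decoy
  acc <- primary_accession(psms)
  support <- table(acc[is_target])
  weak <- is_target & support[acc] < config$min_psm_per_protein
  weak[is.na(weak)] <- FALSE
  reason[weak] <- "min_psm_per_protein"

  kept <- psms[is_target & !weak, , drop = FALSE]
  rownames(kept) <- NULL
  removed <- which(!is.na(reason))
  report <- list(
    sample_id = sample_id,
    n_psm_in = nrow(psms),
    n_psm_out = nrow(kept),
    protein_fdr_pct = protein_fdr,
    peptide_fdr_pct = peptide_fdr,
    passed_gate = NA,
    removal_log = data.frame(psm_index = removed, reason = reason[removed],
                             stringsAsFactors = FALSE)
  )
  report$passed_gate <- qc_gate(report, config)
  list(kept = kept, report = report)
}

#' Sample-level FDR quality gate
#'
#' A sample passes when its protein FDR and peptide FDR are both at or below
#' the configured maxima (inclusive bounds: exclusion applies to strictly
#' greater FDR). Samples with undefined FDR (no targets) fail.
#'
#' @param report a filter report from [apply_filters()].
#' @param config a [pipeline_config()].
#' @return Logical.
#' @export
qc_gate <- function(report, config = pipeline_config()) {
  p <- report$protein_fdr_pct
  q <- report$peptide_fdr_pct
  if (is.na(p) || is.na(q)) return(FALSE)
  p <= config$protein_fdr_max_pct && q <= config$peptide_fdr_max_pct
}
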