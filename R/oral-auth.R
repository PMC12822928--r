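#' Classify PSMs by primary accession
#'
#' Category membership of the primary accession decides, with precedence
#' lab contaminant > common contaminant > oral microbiome > salivary >
#' dietary; an accession in no list is `"other"`.
#'
#' @param psms a PSM data frame (or any data frame with an `accessions`
#'   column).
#' @param refsets a `calcproteo_refsets`.
#' @return Character vector of categories, one per PSM.
#' @export
classify_psm <- function(psms, refsets) {
  acc <- primary_accession(psms)
  out <- rep("other", length(acc))
  members <- list(
    dietary = refsets$dietary$accession,
    salivary = refsets$salivary,
    oral_microbiome = refsets$oral_microbiome,
    common_contaminant = refsets$common_contaminants,
    lab_contaminant = refsets$lab_contaminants
  )
  # assign lowest precedence first so higher precedence overwrites
  for (cat in names(members)) out[acc %in% members[[cat]]] <- cat
  out
}

#' Oral-signature score of one sample
#'
#' Counts PSMs per category and computes the raw authentication score
#' oral / (oral + contaminant), where oral = oral microbiome + salivary and
#' contaminant = common + lab contaminants. Dietary and unclassified PSMs are
#' excluded from both numerator and denominator. A zero denominator yields a
#' raw score of 0 with a warning.
#'
#' @param psms PSMs of a single sample (post filtering).
#' @param refsets a `calcproteo_refsets`.
#' @return A one-row data frame with the sample id, the six category counts,
#'   `raw_score`, and `NA` placeholders for `norm_score` and `passed`.
#' @export
score_sample <- function(psms, refsets) {
  sid <- unique(psms$sample_id)
  if (length(sid) > 1L) {
    stop("score_sample expects one sample, got: ",
         paste(sid, collapse = ", "), call. = FALSE)
  }
  if (!length(sid)) sid <- NA_character_
  cats <- classify_psm(psms, refsets)
  n <- function(cat) sum(cats == cat)
  oral <- n("oral_microbiome") + n("salivary")
  cont <- n("common_contaminant") + n("lab_contaminant")
  raw <- if (oral + cont == 0) {
    warning(sprintf("sample %s: no oral or contaminant PSMs; raw score set to 0", sid),
            call. = FALSE)
    0
  } else {
    oral / (oral + cont)
  }
  data.frame(sample_id = sid,
             n_oral_microbiome = n("oral_microbiome"), n_salivary = n("salivary"),
             n_common_contaminant = n("common_contaminant"),
             n_lab_contaminant = n("lab_contaminant"),
             n_dietary = n("dietary"), n_other = n("other"),
             raw_score = raw, norm_score = NA_real_, passed = NA,
             stringsAsFactors = FALSE)
}

#' Min-max normalise authentication scores across a batch
#'
#' norm = (x - min) / (max - min) over all samples scored in one pipeline
#' invocation. If all raw scores are equal (including a single-sample batch)
#' every normalised score is set to the midpoint 0.5 with a warning, so the
#' inclusive pass threshold does not silently fail a degenerate batch.
#'
#' @param results row-bound output of [score_sample()].
#' @return `results` with `norm_score` filled.
#' @export
normalize_batch <- function(results) {
  if (!nrow(results)) stop("cannot normalise an empty batch", call. = FALSE)
  x <- results$raw_score
  rng <- range(x)
  if (diff(rng) == 0) {
    warning("all raw scores equal; normalised scores set to 0.5", call. = FALSE)
    results$norm_score <- rep(0.5, length(x))
  } else {
    results$norm_score <- (x - rng[1]) / (rng[2] - rng[1])
  }
  results
}

#' Threshold normalised oral-signature scores
#'
#' A sample passes when its normalised score is at or above the threshold
#' (inclusive).
#'
#' @param results output of [normalize_batch()].
#' @param config a [pipeline_config()].
#' @return `results` with `passed` filled.
#' @export
authenticate <- function(results, config = pipeline_config()) {
  if (anyNA(results$norm_score)) {
    stop("norm_score not set; run normalize_batch() first", call. = FALSE)
  }
  results$passed <- results$norm_score >= config$auth_threshold
  results
}

#' Merge passing replicate samples per individual
#'
#' For every individual with two or more passing samples, the constituents are
#' replaced by one merged sample whose id joins the sorted constituent ids
#' with a hyphen (e.g. `"220-221"`) and whose PSM list is their
#' concatenation. Samples without a passing replicate partner (including
#' failing samples) are left as they are; the caller re-runs filtering,
#' scoring, batch normalisation and authentication on the returned table.
#'
#' @param psms PSM data frame covering the whole batch (pre-filter PSMs so the
#'   merged sample can be re-filtered).
#' @param auth authenticated results ([authenticate()] output) for the batch.
#' @return The updated PSM data frame.
#' @export
merge_replicates <- function(psms, auth) {
  passing <- auth$sample_id[auth$passed]
  sub <- psms[psms$sample_id %in% passing, c("sample_id", "individual_id")]
  pairs <- unique(sub)
  counts <- table(pairs$individual_id)
  for (ind in names(counts)[counts >= 2L]) {
    ids <- sort(unique(pairs$sample_id[pairs$individual_id == ind]))
    merged_id <- paste(ids, collapse = "-")
    psms$sample_id[psms$sample_id %in% ids] <- merged_id
  }
  rownames(psms) <- NULL
  psms
}
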