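#' Asparagine/glutamine residue observations of a single PSM
#'
#' Counts the N and Q residue instances in the peptide and how many of them
#' carry a Deamidated modification at their position.
#'
#' @param peptide peptide string.
#' @param modifications canonical modification string (`"Name:pos;..."`).
#' @return Named integer vector `c(n_N, deam_N, n_Q, deam_Q)`.
#' @export
residue_observations <- function(peptide, modifications = "") {
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  mods <- parse_modifications(modifications)[[1]]
  deam_pos <- mods$position[mods$name == "Deamidated"]
  is_deam <- seq_along(res) %in% deam_pos
  c(n_N = sum(res == "N"), deam_N = sum(res == "N" & is_deam),
    n_Q = sum(res == "Q"), deam_Q = sum(res == "Q" & is_deam))
}

#' Bulk deamidation rates per protein or per sample
#'
#' Sums N/Q residue observations over all PSMs of each unit (every PSM
#' contributes its residue instances once, so abundant peptides weigh more,
#' as in a bulk estimate). Units with no N or Q sites are omitted with a
#' message. Each unit is assigned to the `contaminant` group (common + lab
#' contaminants) or the `oral_plus_dietary` group (oral microbiome + salivary
#' + dietary); PSMs classified `other` are excluded.
#'
#' @param psms a PSM data frame.
#' @param refsets a `calcproteo_refsets`.
#' @param unit `"protein"` (primary accession; the comparison unit) or
#'   `"sample"`.
#' @return Data frame with `unit_id`, `group`, site and deamidation counts,
#'   `rate_N`, `rate_Q` and the pooled `rate_total`.
#' @export
bulk_rates <- function(psms, refsets, unit = c("protein", "sample")) {
  unit <- match.arg(unit)
  cats <- classify_psm(psms, refsets)
  group <- ifelse(cats %in% c("common_contaminant", "lab_contaminant"),
                  "contaminant",
           ifelse(cats %in% c("oral_microbiome", "salivary", "dietary"),
                  "oral_plus_dietary", NA_character_))
  keep <- !is.na(group)
  psms <- psms[keep, , drop = FALSE]
  group <- group[keep]
  if (!nrow(psms)) {
    return(data.frame(unit_id = character(), group = character(),
                      n_sites_N = integer(), n_deam_N = integer(),
                      n_sites_Q = integer(), n_deam_Q = integer(),
                      rate_N = numeric(), rate_Q = numeric(),
                      rate_total = numeric(), stringsAsFactors = FALSE))
  }
  uid <- if (unit == "protein") primary_accession(psms) else psms$sample_id
  obs <- t(mapply(residue_observations, psms$peptide, psms$modifications))
  agg <- stats::aggregate(obs, by = list(unit_id = uid, group = group), FUN = sum)
  omit <- agg$n_N + agg$n_Q == 0
  if (any(omit)) {
    message("omitting ", sum(omit), " unit(s) with no N or Q sites: ",
            paste(agg$unit_id[omit], collapse = ", "))
    agg <- agg[!omit, , drop = FALSE]
  }
  out <- data.frame(
    unit_id = agg$unit_id, group = agg$group,
    n_sites_N = agg$n_N, n_deam_N = agg$deam_N,
    n_sites_Q = agg$n_Q, n_deam_Q = agg$deam_Q,
    rate_N = ifelse(agg$n_N > 0, agg$deam_N / agg$n_N, NA_real_),
    rate_Q = ifelse(agg$n_Q > 0, agg$deam_Q / agg$n_Q, NA_real_),
    rate_total = (agg$deam_N + agg$deam_Q) / (agg$n_N + agg$n_Q),
    stringsAsFactors = FALSE
  )
  out[order(out$group, out$unit_id), , drop = FALSE]
}

#' Compare total deamidation rates between contaminant and endogenous proteins
#'
#' Two-sided Wilcoxon rank-sum test on per-unit `rate_total` between the
#' `contaminant` and `oral_plus_dietary` groups: exact null distribution when
#' both groups have at most 12 units and there are no ties, normal
#' approximation with tie correction otherwise. Units with fewer than
#' `min_sites` observed N + Q sites are excluded first: a rate estimated from
#' a handful of sites is so coarse (mostly exactly 0) that rank tests pick up
#' the difference in site counts between groups rather than any difference in
#' deamidation.
#'
#' @param summaries output of [bulk_rates()] (typically restricted to the
#'   samples that passed, or failed, authentication before calling).
#' @param min_sites minimum N + Q site observations for a unit to enter the
#'   test (ignored when `summaries` carries no site-count columns).
#' @return A list with `statistic` (rank-sum W), `p_value`, `n_contaminant`
#'   and `n_oral_dietary`.
#' @export
compare_groups <- function(summaries, min_sites = 10L) {
  if (all(c("n_sites_N", "n_sites_Q") %in% names(summaries))) {
    summaries <- summaries[summaries$n_sites_N + summaries$n_sites_Q >=
                             min_sites, , drop = FALSE]
  }
  x <- summaries$rate_total[summaries$group == "contaminant"]
  y <- summaries$rate_total[summaries$group == "oral_plus_dietary"]
  if (!length(x)) stop("contaminant group is empty", call. = FALSE)
  if (!length(y)) stop("oral_plus_dietary group is empty", call. = FALSE)
  if (length(unique(c(x, y))) == 1L) {
    # complete ties: no evidence of separation
    return(list(statistic = length(x) * length(y) / 2, p_value = 1.0,
                n_contaminant = length(x), n_oral_dietary = length(y)))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 12 && length(y) <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_contaminant = length(x), n_oral_dietary = length(y))
}
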