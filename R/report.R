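# Display groups used in site-level summaries: assignments are pooled when
# grouping does not lose taxonomic specification.
DEFAULT_MERGE_MAP <- list(
  "Pecora and Bovidae" = c("Pecora", "Bovidae"),
  "Bovinae and/or Ovis" = c("Bovinae", "Ovis", "Bovinae/Ovis"),
  "Caprinae and Capra" = c("Caprinae", "Capra")
)

# Protein display name of each PSM: primary accession mapped through the
# dietary database, honouring reassignment rules for bacterial homologs.
psm_protein_name <- function(psms, refsets) {
  acc <- primary_accession(psms)
  name <- refsets$dietary$protein_name[match(acc, refsets$dietary$accession)]
  hit <- acc %in% names(refsets$reassignment_rules)
  name[hit] <- unname(refsets$reassignment_rules[acc[hit]])
  name
}

#' Per-individual dietary summary
#'
#' One row per individual in the style of a study summary table: identified
#' dietary proteins, PSM count, unique peptides (distinct
#' peptide/modification pairs) and taxa identified. Individuals listed in
#' `individuals` but without dietary PSMs are emitted with zero counts and
#' an en-dash placeholder.
#'
#' @param psms validated dietary PSM data frame.
#' @param assignments output of [assign_peptides()] covering every peptide in
#'   `psms`.
#' @param refsets a `calcproteo_refsets`.
#' @param individuals optional data frame (`individual_id`, `site`,
#'   `subsite`) enumerating all study individuals, so dietary-negative ones
#'   appear too.
#' @return Data frame with columns `individual_id`, `site`, `subsite`,
#'   `proteins`, `psm_count`, `unique_peptides`, `taxa` (`proteins`/`taxa`
#'   semicolon-joined, deduplicated, order-stable; `"-"` when empty).
#' @export
summarize_individuals <- function(psms, assignments, refsets,
                                  individuals = NULL) {
  unassigned <- setdiff(psms$peptide, assignments$peptide)
  if (length(unassigned)) {
    stop("PSM peptide(s) without assignment: ",
         paste(unique(unassigned), collapse = ", "), call. = FALSE)
  }
  label <- stats::setNames(assignments$label, assignments$peptide)
  rows <- list()
  if (nrow(psms)) {
    psms$..protein <- psm_protein_name(psms, refsets)
    psms$..taxon <- unname(label[psms$peptide])
    psms$..pepmod <- paste(psms$peptide,
                           format_modifications(parse_modifications(psms$modifications)),
                           sep = "|")
    for (ind in unique(psms$individual_id)) {
      sub <- psms[psms$individual_id == ind, , drop = FALSE]
      rows[[ind]] <- data.frame(
        individual_id = ind, site = sub$site[1], subsite = sub$subsite[1],
        proteins = paste(unique(sub$..protein), collapse = ";"),
        psm_count = nrow(sub),
        unique_peptides = length(unique(sub$..pepmod)),
        taxa = paste(unique(sub$..taxon), collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!is.null(individuals)) {
    for (i in seq_len(nrow(individuals))) {
      ind <- individuals$individual_id[i]
      if (is.null(rows[[ind]])) {
        rows[[ind]] <- data.frame(
          individual_id = ind, site = individuals$site[i],
          subsite = individuals$subsite[i],
          proteins = "-", psm_count = 0L, unique_peptides = 0L, taxa = "-",
          stringsAsFactors = FALSE
        )
      }
    }
    rows <- rows[individuals$individual_id]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-site dietary summary
#'
#' Site totals, per-individual per-protein PSM counts (stacked-bar data) and
#' per-taxon-group PSM counts (pie-chart data), with taxonomic assignments
#' pooled into display groups via `merge_map`; labels outside the map are
#' kept as they are.
#'
#' @param psms validated dietary PSM data frame.
#' @param assignments output of [assign_peptides()].
#' @param refsets a `calcproteo_refsets`.
#' @param merge_map named list of display groups (defaults to pooling
#'   Pecora/Bovidae, Bovinae with Ovis, and Caprinae with Capra).
#' @return A list keyed by site, each with `site`, `total_psms`,
#'   `per_individual` (data frame `individual_id`, `protein`, `psms`) and
#'   `per_taxon_group` (data frame `group`, `psms`).
#' @export
summarize_sites <- function(psms, assignments, refsets,
                            merge_map = DEFAULT_MERGE_MAP) {
  unassigned <- setdiff(psms$peptide, assignments$peptide)
  if (length(unassigned)) {
    stop("PSM peptide(s) without assignment: ",
         paste(unique(unassigned), collapse = ", "), call. = FALSE)
  }
  label <- stats::setNames(assignments$label, assignments$peptide)
  display <- unname(label[psms$peptide])
  for (grp in names(merge_map)) {
    display[display %in% merge_map[[grp]]] <- grp
  }
  psms$..protein <- if (nrow(psms)) psm_protein_name(psms, refsets) else character()
  out <- list()
  for (site in unique(psms$site)) {
    sub <- psms[psms$site == site, , drop = FALSE]
    disp <- display[psms$site == site]
    per_ind <- stats::aggregate(
      list(psms = rep(1L, nrow(sub))),
      by = list(individual_id = sub$individual_id, protein = sub$..protein),
      FUN = sum
    )
    per_grp <- stats::aggregate(
      list(psms = rep(1L, nrow(sub))),
      by = list(group = disp), FUN = sum
    )
    out[[site]] <- list(site = site, total_psms = nrow(sub),
                        per_individual = per_ind[order(per_ind$individual_id,
                                                       per_ind$protein), ,
                                                 drop = FALSE],
                        per_taxon_group = per_grp[order(per_grp$group), ,
                                                  drop = FALSE])
  }
  out
}
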