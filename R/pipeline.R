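#' Run the full inference chain end-to-end
#'
#' Stage order: read inputs, per-sample PSM filtering with the FDR quality
#' gate, oral-signature authentication (score, min-max normalise, threshold),
#' replicate merging with filtering and authentication repeated on the merged
#' batch, bulk deamidation analysis with the contaminant-versus-endogenous
#' comparison inside the passed and failed groups, spectral validation of
#' low-scoring dietary PSMs, deamidation-aware taxonomic assignment, and
#' per-individual/per-site summaries. Every excluded sample or PSM is logged
#' with a reason; a run manifest (config snapshot, input digests, per-stage
#' record counts, seed) makes reruns byte-identical.
#'
#' @param psms_path generic-TSV PSM table ([read_psm_table()]).
#' @param refs_dir directory holding `dietary.fasta`, `dietary_lineages.tsv`,
#'   `lists.yaml`, `taxonomy.tsv` (see [write_reference_files()]).
#' @param out_dir output directory (created if needed).
#' @param mgf_path optional MGF with the spectra needed for spectral
#'   validation.
#' @param config a [pipeline_config()].
#' @param individuals optional data frame (`individual_id`, `site`,
#'   `subsite`) enumerating all study individuals for the summary table.
#' @return Invisibly, a list with the per-stage results (`filter_reports`,
#'   `auth`, `deamidation`, `validation`, `assignments`, `table1`,
#'   `site_summary`, `manifest`).
#' @export
run_pipeline <- function(psms_path, refs_dir, out_dir, mgf_path = NULL,
                         config = pipeline_config(), individuals = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  refs <- load_reference_sets(
    fasta = file.path(refs_dir, "dietary.fasta"),
    lists = file.path(refs_dir, "lists.yaml"),
    taxonomy = file.path(refs_dir, "taxonomy.tsv")
  )
  psms <- read_psm_table(psms_path)
  spectra <- if (!is.null(mgf_path)) read_mgf(mgf_path) else list()
  set.seed(config$random_seed)

  filter_auth <- function(psms) {
    # per-sample filtering + gate, then batch authentication
    reports <- list()
    kept <- list()
    for (sid in unique(psms$sample_id)) {
      fa <- apply_filters(psms[psms$sample_id == sid, , drop = FALSE], config)
      reports[[sid]] <- fa$report
      if (isTRUE(fa$report$passed_gate)) kept[[sid]] <- fa$kept
    }
    kept_psms <- if (length(kept)) do.call(rbind, kept) else
      psms[0, , drop = FALSE]
    rownames(kept_psms) <- NULL
    scored <- do.call(rbind, lapply(unique(kept_psms$sample_id), function(sid) {
      score_sample(kept_psms[kept_psms$sample_id == sid, , drop = FALSE], refs$refsets)
    }))
    auth <- if (!is.null(scored) && nrow(scored)) {
      authenticate(normalize_batch(scored), config)
    } else {
      stop("no sample passed the FDR quality gate", call. = FALSE)
    }
    list(reports = reports, kept = kept_psms, auth = auth)
  }

  first <- filter_auth(psms)
  merged_input <- merge_replicates(psms, first$auth)
  merged <- !identical(merged_input$sample_id, psms$sample_id)
  final <- if (merged) filter_auth(merged_input) else first
  auth <- final$auth
  kept <- final$kept

  passed_ids <- auth$sample_id[auth$passed]
  kept_passed <- kept[kept$sample_id %in% passed_ids, , drop = FALSE]
  kept_failed <- kept[!kept$sample_id %in% passed_ids, , drop = FALSE]

  deam_passed <- bulk_rates(kept_passed, refs$refsets, unit = "protein")
  deam_failed <- if (nrow(kept_failed)) {
    bulk_rates(kept_failed, refs$refsets, unit = "protein")
  } else NULL
  cmp <- function(s) {
    if (is.null(s) || length(unique(s$group)) < 2) return(NULL)
    # not computable when a group has no unit with enough N/Q sites
    tryCatch(compare_groups(s), error = function(e) NULL)
  }
  comparison <- list(passed = cmp(deam_passed), failed = cmp(deam_failed))

  val <- validate_dietary(kept_passed, spectra, refs$refsets, config)
  dietary <- val$kept[classify_psm(val$kept, refs$refsets) == "dietary", ,
                      drop = FALSE]
  assignments <- if (nrow(dietary)) {
    assign_peptides(unique(dietary$peptide), refs$refsets, refs$tree)
  } else {
    data.frame(peptide = character(), label = character(),
               deamidation_dependent = logical(),
               matched_accessions = character(), protein_names = character(),
               stringsAsFactors = FALSE)
  }
  table1 <- summarize_individuals(dietary, assignments, refs$refsets,
                                  individuals = individuals)
  site_summary <- summarize_sites(dietary, assignments, refs$refsets)

  # ---- outputs ----
  write_psm_table(kept, file.path(out_dir, "filtered_psms.tsv"))
  utils::write.table(auth, file.path(out_dir, "authentication.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  deam_all <- rbind(
    if (nrow(deam_passed)) cbind(subset = "passed", deam_passed),
    if (!is.null(deam_failed) && nrow(deam_failed)) cbind(subset = "failed", deam_failed)
  )
  utils::write.table(deam_all, file.path(out_dir, "deamidation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(comparison, file.path(out_dir, "deamidation_tests.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(val$results, file.path(out_dir, "spectral_validation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(assignments, file.path(out_dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table1, file.path(out_dir, "table1.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(site_summary, file.path(out_dir, "site_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  exclusions <- do.call(rbind, lapply(final$reports, function(r) {
    if (!nrow(r$removal_log)) return(NULL)
    cbind(sample_id = r$sample_id, r$removal_log)
  }))
  if (is.null(exclusions)) {
    exclusions <- data.frame(sample_id = character(), psm_index = integer(),
                             reason = character(), stringsAsFactors = FALSE)
  }
  utils::write.table(exclusions, file.path(out_dir, "exclusions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    config = unclass(config),
    inputs = as.list(tools::md5sum(c(psms = psms_path,
                                     if (!is.null(mgf_path)) c(mgf = mgf_path)))),
    seed = config$random_seed,
    counts = list(
      psms_in = nrow(psms),
      psms_after_filtering = nrow(kept),
      samples_gated_out = sum(!vapply(final$reports, function(r)
        isTRUE(r$passed_gate), logical(1))),
      samples_passed_auth = length(passed_ids),
      dietary_psms_validated = nrow(dietary)
    ),
    merged_replicates = merged,
    version = as.character(utils::packageVersion("calcproteo"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(filter_reports = final$reports, auth = auth,
                 deamidation = list(passed = deam_passed, failed = deam_failed,
                                    tests = comparison),
                 validation = val$results, assignments = assignments,
                 table1 = table1, site_summary = site_summary,
                 manifest = manifest))
}
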