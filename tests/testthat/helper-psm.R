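# Compact PSM row builder for tests; defaults are a valid target PSM.
make_psm <- function(peptide = "ANQK", modifications = "",
                     accessions = "ACC_1", sample_id = "S1",
                     individual_id = sample_id, site = "SiteA", subsite = "",
                     spectrum_ref = NULL, ion_score = 60, e_value = 1e-4,
                     is_decoy = FALSE, charge = 2L,
                     precursor = NULL) {
  n <- max(lengths(list(peptide, modifications, accessions, sample_id,
                        ion_score, e_value, is_decoy)))
  df <- data.frame(
    sample_id = rep_len(sample_id, n),
    individual_id = rep_len(individual_id, n),
    site = rep_len(site, n), subsite = rep_len(subsite, n),
    spectrum_ref = if (is.null(spectrum_ref)) {
      sprintf("scan_%d_%d", sample(1e6, 1), seq_len(n))
    } else rep_len(spectrum_ref, n),
    peptide = rep_len(peptide, n),
    modifications = rep_len(modifications, n),
    accessions = rep_len(accessions, n),
    ion_score = rep_len(ion_score, n),
    e_value = rep_len(e_value, n),
    is_decoy = rep_len(is_decoy, n),
    precursor_mz = NA_real_,
    charge = rep_len(as.integer(charge), n),
    stringsAsFactors = FALSE
  )
  df$precursor_mz <- if (is.null(precursor)) {
    # fall back to a placeholder for deliberately non-peptidic test strings
    mapply(function(p, z, m) tryCatch(precursor_mz(p, z, m),
                                      error = function(e) 500.0),
           df$peptide, df$charge, df$modifications)
  } else rep_len(precursor, n)
  df
}

# Minimal reference sets for classification tests (no dietary DB I/O).
make_refsets <- function(oral = c("ORAL_A", "ORAL_B"),
                         salivary = c("SAL_A"),
                         common = c("CONT_A"),
                         lab = c("LAB_A"),
                         dietary = NULL) {
  if (is.null(dietary)) {
    dietary <- data.frame(accession = "DIET_A", protein_name = "BLG",
                          sequence = "TPEVDDEALEK",
                          lineage = "Life>Mammalia>Artiodactyla>Pecora>Bovidae>Bovinae>Bos",
                          taxon = "Bos", stringsAsFactors = FALSE)
  }
  structure(list(oral_microbiome = oral, salivary = salivary,
                 common_contaminants = common, lab_contaminants = lab,
                 dietary = dietary, exclusion_accessions = character(),
                 reassignment_rules = character()),
            class = "calcproteo_refsets")
}
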