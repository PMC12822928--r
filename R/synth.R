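# ---- packaged milk-protein fixture database -------------------------------
#
# Synthetic dietary database: protein sequences are concatenations of
# designed tryptic marker peptides whose sharing pattern across taxa encodes
# the assignment structure real milk proteins show (species-unique peptides,
# subfamily/family/infraorder-conserved peptides, a deamidation-ambiguous
# BLG locus, and bacterial homologs from genome-sequencing contamination).
# Sequences are synthetic stand-ins, not database entries.

FIXTURE_PEPTIDES <- list(
  pecora      = "AGTWHSVAMK",   # conserved across all pecoran BLGs
  bovidae_blg = "VFPTYSGFWK",   # Bos + Ovis + Capra BLG
  bovinae     = "GPTHWSYVAK",   # Bos BLG only
  bovis       = "TPEVDDEALEK",  # Bos BLG; ovine locus TPEVDNEALEK (N at 6)
  caprinae    = "WTVHGPAFSK",   # Ovis + Capra BLG
  ovis        = "YSHWGTPVFK",   # Ovis BLG only
  capra       = "HGWFTSYPAK",   # Capra BLG only
  unspec      = "SGVYWHAPTK",   # conserved ruminants + Equus BLG-2
  eq1         = "FHWSPVTGYK",   # Equus BLG-1 only
  eq2         = "PWYGHVSTFK",
  eq3         = "STYWPHGVFK",
  asc_bovidae = "YGPSWFHTAK",   # Bos + Ovis + Capra Alpha-S1-casein
  asc_bovidab = "WFSGYPTHVK",   # idem (also in the Jeotgalicoccus homolog)
  asc_bovinae = "PYTVWGFHSK",   # Bos Alpha-S1-casein only
  btn1        = "GSHYWVAPFK",   # Bos BTN1A1
  btn2        = "TWHYGSVAPK"
)

FIXTURE_TAXONOMY <- data.frame(
  name = c("Life", "Bacteria", "Staphylococcus", "Jeotgalicoccus",
           "Mammalia", "Artiodactyla", "Pecora", "Bovidae", "Bovinae", "Bos",
           "Caprinae", "Ovis", "Capra", "Cervidae", "Cervus",
           "Perissodactyla", "Equidae", "Equus"),
  rank = c("root", "domain", "genus", "genus",
           "class", "order", "infraorder", "family", "subfamily", "genus",
           "subfamily", "genus", "genus", "family", "genus",
           "order", "family", "genus"),
  parent = c(NA, "Life", "Bacteria", "Bacteria",
             "Life", "Mammalia", "Artiodactyla", "Pecora", "Bovidae",
             "Bovinae", "Bovidae", "Caprinae", "Caprinae", "Pecora",
             "Cervidae", "Mammalia", "Perissodactyla", "Equidae"),
  stringsAsFactors = FALSE
)

fixture_dietary_table <- function() {
  p <- FIXTURE_PEPTIDES
  cat0 <- function(...) paste0(...)
  entries <- list(
    list("BLG_BOS", "BLG", "Bos",
         cat0(p$pecora, p$bovidae_blg, p$bovinae, p$bovis, p$unspec)),
    list("BLG_OVIS", "BLG", "Ovis",
         cat0(p$pecora, p$bovidae_blg, "TPEVDNEALEK", p$caprinae, p$ovis, p$unspec)),
    list("BLG_CAPRA", "BLG", "Capra",
         cat0(p$pecora, p$bovidae_blg, p$caprinae, p$capra, p$unspec)),
    list("BLG_CERVUS", "BLG", "Cervus", cat0(p$pecora, p$unspec)),
    list("BLG1_EQUUS", "BLG-1", "Equus", cat0(p$eq1, p$eq2, p$eq3)),
    list("BLG2_EQUUS", "BLG-2", "Equus", cat0(p$unspec, "VGHTWAYSPK")),
    list("ASC_BOS", "Alpha-S1-casein", "Bos",
         cat0(p$asc_bovidae, p$asc_bovidab, p$asc_bovinae)),
    list("ASC_OVIS", "Alpha-S1-casein", "Ovis",
         cat0(p$asc_bovidae, p$asc_bovidab)),
    list("ASC_CAPRA", "Alpha-S1-casein", "Capra",
         cat0(p$asc_bovidae, p$asc_bovidab)),
    list("BTN1A1_BOS", "BTN1A1", "Bos", cat0(p$btn1, p$btn2)),
    list("SYN_STAPH01", "lipocalin family protein (synthetic bacterial homolog)",
         "Staphylococcus", cat0(p$bovis, "WSHGTVYPAK")),
    list("SYN_JEOT01", "hypothetical protein (synthetic bacterial homolog)",
         "Jeotgalicoccus", cat0(p$asc_bovidab, "HTWGSYVPAK"))
  )
  df <- do.call(rbind, lapply(entries, function(e) {
    data.frame(accession = e[[1]], protein_name = e[[2]], taxon = e[[3]],
               sequence = e[[4]], stringsAsFactors = FALSE)
  }))
  tree <- taxonomy_tree(FIXTURE_TAXONOMY)
  df$lineage <- vapply(df$taxon, function(t) paste(tax_path(tree, t), collapse = ">"),
                       character(1))
  df[c("accession", "protein_name", "sequence", "lineage", "taxon")]
}

#' Generate the packaged reference database
#'
#' Emits the fixture milk-protein dietary database (deterministic), the
#' taxonomy tree, and seeded randomised oral-microbiome / salivary / common-
#' contaminant / lab-contaminant accession lists for use with the study
#' simulator. The bacterial homolog entries carry the packaged
#' exclusion/reassignment rules (the Jeotgalicoccus-like hypothetical protein
#' is excluded; the Staphylococcus-like lipocalin is reassigned to BLG).
#'
#' @param seed integer seed for the randomised accession lists.
#' @param n_accessions_per_list size of each non-dietary accession list.
#' @return A list with `refsets` (`calcproteo_refsets`) and `tree`
#'   (`calcproteo_taxonomy`).
#' @export
generate_reference_db <- function(seed = 1L, n_accessions_per_list = 30L) {
  set.seed(seed)
  mk <- function(prefix) {
    sprintf("%s_%04d", prefix, sort(sample.int(9999L, n_accessions_per_list)))
  }
  dietary <- fixture_dietary_table()
  refsets <- structure(list(
    oral_microbiome = mk("ORAL"),
    salivary = mk("SALI"),
    common_contaminants = mk("CONT"),
    lab_contaminants = mk("LABC"),
    dietary = dietary,
    exclusion_accessions = "SYN_JEOT01",
    reassignment_rules = c(SYN_STAPH01 = "BLG")
  ), class = "calcproteo_refsets")
  list(refsets = refsets, tree = taxonomy_tree(FIXTURE_TAXONOMY))
}

#' Write reference sets to their on-disk formats
#'
#' Writes `dietary.fasta` (+ `dietary_lineages.tsv` sidecar), `lists.yaml`
#' and `taxonomy.tsv` under `dir`, in the formats [load_reference_sets()]
#' reads.
#'
#' @param refsets a `calcproteo_refsets`.
#' @param tree a `calcproteo_taxonomy`.
#' @param dir output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_reference_files <- function(refsets, tree, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "dietary.fasta")
  seqs <- Biostrings::AAStringSet(stats::setNames(refsets$dietary$sequence,
                                                  refsets$dietary$accession))
  Biostrings::writeXStringSet(seqs, fasta, width = 60L)
  lineages <- file.path(dir, "dietary_lineages.tsv")
  utils::write.table(refsets$dietary[c("accession", "protein_name", "lineage")],
                     lineages, sep = "\t", quote = FALSE, row.names = FALSE)
  lists <- file.path(dir, "lists.yaml")
  yaml::write_yaml(list(
    oral_microbiome = as.list(refsets$oral_microbiome),
    salivary = as.list(refsets$salivary),
    common_contaminants = as.list(refsets$common_contaminants),
    lab_contaminants = as.list(refsets$lab_contaminants),
    exclusion_accessions = as.list(refsets$exclusion_accessions),
    reassignment_rules = as.list(refsets$reassignment_rules)
  ), lists)
  taxonomy <- file.path(dir, "taxonomy.tsv")
  utils::write.table(as.data.frame(tree), taxonomy, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(c(fasta = fasta, lineages = lineages, lists = lists,
              taxonomy = taxonomy))
}

#' Study individuals of the worked example
#'
#' The eleven individuals with an authenticated oral signature, with their
#' site and subsite labels.
#'
#' @return Data frame with `individual_id`, `site`, `subsite`.
#' @export
fixture_individuals <- function() {
  data.frame(
    individual_id = c("135", "143", "147", "151-152", "158",
                      "181-182", "185-186", "192", "200", "203", "220-221"),
    site = c("Bilsk", "Bilsk", "Bilsk", "Bilsk", "Bilsk", "Bilsk",
             "Mamai-Gora", "Mamai-Gora", "Mamai-Gora", "Mamai-Gora",
             "Mamai-Gora"),
    subsite = c("Cemetery B", "Tsarina", "Cemetery B", "Marchenki 8th Field",
                "Tsarina", "Marchenki 9th Field", "", "", "", "", ""),
    stringsAsFactors = FALSE
  )
}

#' Dietary PSM table of the worked example
#'
#' Deterministically regenerates the dietary PSM table of the worked example:
#' per-individual, per-protein PSM counts for the six dietary-positive
#' individuals (143, 151-152, 181-182 at Bilsk; 192, 203, 220-221 at
#' Mamai-Gora), with peptides drawn from the fixture database so that
#' taxonomy assignment and the unique-peptide counts are reproducible from
#' the package alone. All ion scores sit above the spectral-validation
#' cutoff.
#'
#' @return A validated PSM data frame (50 rows).
#' @export
make_inpaper_fixture <- function() {
  p <- FIXTURE_PEPTIDES
  tpev_acc <- "BLG_BOS;BLG_OVIS;SYN_STAPH01"
  spec_rows <- list(
    # individual, site, subsite, accessions, peptide, count
    list("143", "Bilsk", "Tsarina", "BLG_BOS", p$bovinae, 1),
    list("143", "Bilsk", "Tsarina", tpev_acc, p$bovis, 2),
    list("143", "Bilsk", "Tsarina", "BLG_OVIS", p$caprinae, 2),
    list("143", "Bilsk", "Tsarina", "BLG_OVIS", p$ovis, 2),
    list("143", "Bilsk", "Tsarina", "BLG_BOS", p$unspec, 1),
    list("143", "Bilsk", "Tsarina", "BLG_BOS", p$bovidae_blg, 1),
    list("143", "Bilsk", "Tsarina", "BLG1_EQUUS", p$eq1, 3),
    list("143", "Bilsk", "Tsarina", "BLG1_EQUUS", p$eq2, 2),
    list("143", "Bilsk", "Tsarina", "BLG1_EQUUS", p$eq3, 2),
    list("143", "Bilsk", "Tsarina", "ASC_BOS", p$asc_bovidae, 1),
    list("143", "Bilsk", "Tsarina", "ASC_BOS", p$asc_bovinae, 1),
    list("151-152", "Bilsk", "Marchenki 8th Field", "ASC_BOS", p$asc_bovidae, 1),
    list("151-152", "Bilsk", "Marchenki 8th Field", "ASC_BOS", p$asc_bovinae, 1),
    list("181-182", "Bilsk", "Marchenki 9th Field", "BLG_BOS", p$pecora, 1),
    list("181-182", "Bilsk", "Marchenki 9th Field", "BLG_BOS", p$bovinae, 1),
    list("181-182", "Bilsk", "Marchenki 9th Field", tpev_acc, p$bovis, 2),
    list("181-182", "Bilsk", "Marchenki 9th Field", "ASC_BOS", p$asc_bovidae, 1),
    list("181-182", "Bilsk", "Marchenki 9th Field", "ASC_BOS", p$asc_bovidab, 1),
    list("181-182", "Bilsk", "Marchenki 9th Field", "ASC_BOS", p$asc_bovinae, 1),
    list("192", "Mamai-Gora", "", "BLG_BOS", p$bovinae, 1),
    list("192", "Mamai-Gora", "", tpev_acc, p$bovis, 1),
    list("203", "Mamai-Gora", "", "BLG_BOS", p$pecora, 1),
    list("203", "Mamai-Gora", "", tpev_acc, p$bovis, 2),
    list("203", "Mamai-Gora", "", "BLG_BOS", p$unspec, 1),
    list("203", "Mamai-Gora", "", "BLG_BOS", p$bovidae_blg, 1),
    list("203", "Mamai-Gora", "", "ASC_BOS", p$asc_bovidae, 2),
    list("203", "Mamai-Gora", "", "ASC_BOS", p$asc_bovinae, 1),
    list("203", "Mamai-Gora", "", "ASC_BOS", p$asc_bovidab, 1),
    list("203", "Mamai-Gora", "", "BTN1A1_BOS", p$btn1, 1),
    list("203", "Mamai-Gora", "", "BTN1A1_BOS", p$btn2, 1),
    list("220-221", "Mamai-Gora", "", "BLG_BOS", p$pecora, 2),
    list("220-221", "Mamai-Gora", "", "BLG_BOS", p$bovidae_blg, 1),
    list("220-221", "Mamai-Gora", "", "BLG_BOS", p$bovinae, 1),
    list("220-221", "Mamai-Gora", "", tpev_acc, p$bovis, 2),
    list("220-221", "Mamai-Gora", "", "BLG_CAPRA", p$capra, 2),
    list("220-221", "Mamai-Gora", "", "ASC_BOS", p$asc_bovidae, 1),
    list("220-221", "Mamai-Gora", "", "ASC_BOS", p$asc_bovinae, 1)
  )
  rows <- list()
  scan <- 0L
  for (r in spec_rows) {
    for (k in seq_len(r[[6]])) {
      scan <- scan + 1L
      rows[[scan]] <- data.frame(
        sample_id = r[[1]], individual_id = r[[1]], site = r[[2]],
        subsite = r[[3]],
        spectrum_ref = sprintf("fixture_scan_%03d", scan),
        peptide = r[[5]], modifications = "", accessions = r[[4]],
        ion_score = 60, e_value = 1e-4, is_decoy = FALSE,
        precursor_mz = precursor_mz(r[[5]], 2L), charge = 2L,
        stringsAsFactors = FALSE
      )
    }
  }
  psms <- do.call(rbind, rows)
  rownames(psms) <- NULL
  validate_psms(psms)
  psms
}

# ---- synthetic multi-sample study -----------------------------------------

#' Simulation parameters for a synthetic calculus study
#'
#' Defaults emulate the study conditions the analysis assumes: samples whose
#' PSM composition is dominated by oral-signature proteins (80% oral / 15%
#' contaminant) for well-preserved samples and the reverse for poorly
#' preserved ones, a small dietary fraction, per-residue Bernoulli
#' deamidation with endogenous rates (N 0.5, Q 0.15) well above contaminant
#' rates (N 0.05, Q 0.02), a 1% decoy fraction (matching the low post-search
#' FDR range of authenticated calculus proteomes), Gaussian ion scores, and
#' 5% multiplicative log-normal spectral noise.
#'
#' @param n_samples number of samples.
#' @param psm_per_sample PSMs drawn per sample.
#' @param oral_fraction,contaminant_fraction,dietary_fraction PSM category
#'   fractions for well-preserved samples (remainder is `other`); poorly
#'   preserved samples swap the oral and contaminant fractions.
#' @param bad_sample_fraction fraction of samples simulated as poorly
#'   preserved.
#' @param deam_n_endogenous,deam_q_endogenous,deam_n_contaminant,deam_q_contaminant
#'   per-residue-instance deamidation probabilities by group.
#' @param decoy_fraction fraction of PSMs flagged as decoys.
#' @param ion_score_mean,ion_score_sd Gaussian ion-score parameters for
#'   non-dietary PSMs.
#' @param dietary_low_score_fraction fraction of dietary PSMs drawn below the
#'   spectral-validation cutoff (paired with a simulated spectrum).
#' @param spectral_noise standard deviation of the log-normal multiplicative
#'   peak noise.
#' @param seed integer seed.
#' @return A list of class `calcproteo_simparams`.
#' @export
simulation_params <- function(n_samples = 8L, psm_per_sample = 200L,
                              oral_fraction = 0.80,
                              contaminant_fraction = 0.15,
                              dietary_fraction = 0.03,
                              bad_sample_fraction = 0.5,
                              deam_n_endogenous = 0.5,
                              deam_q_endogenous = 0.15,
                              deam_n_contaminant = 0.05,
                              deam_q_contaminant = 0.02,
                              decoy_fraction = 0.01,
                              ion_score_mean = 60, ion_score_sd = 10,
                              dietary_low_score_fraction = 0.5,
                              spectral_noise = 0.05,
                              seed = 1L) {
  params <- as.list(environment())
  fr <- c(oral_fraction, contaminant_fraction, dietary_fraction)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1) {
    stop("category fractions must lie in [0,1] and sum to at most 1",
         call. = FALSE)
  }
  probs <- c(deam_n_endogenous, deam_q_endogenous, deam_n_contaminant,
             deam_q_contaminant, decoy_fraction, bad_sample_fraction,
             dietary_low_score_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0,1]", call. = FALSE)
  }
  structure(params, class = "calcproteo_simparams")
}

# random tryptic-looking peptide with guaranteed N and Q content
random_peptide <- function(len = sample(8:14, 1L)) {
  pool <- c("A", "G", "S", "T", "V", "P", "F", "Y", "H", "W", "N", "Q",
            "D", "E", "M", "N", "Q")
  paste0(paste(sample(pool, len - 1L, replace = TRUE), collapse = ""), "K")
}

# place Deamidated mods on N/Q residues by Bernoulli draws
draw_deamidation <- function(peptide, p_n, p_q) {
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  pos <- which(res %in% c("N", "Q"))
  if (!length(pos)) return("")
  p <- ifelse(res[pos] == "N", p_n, p_q)
  hit <- pos[stats::runif(length(pos)) < p]
  if (!length(hit)) return("")
  paste(sprintf("Deamidated:%d", hit), collapse = ";")
}

# observed spectrum for a peptide: built-in prediction x log-normal noise
simulate_spectrum <- function(ref, peptide, modifications, charge, noise) {
  pred <- predict_fragments(peptide, modifications, charge)
  mz <- pred$ions$mz
  intensity <- pred$ions$predicted_intensity *
    exp(stats::rnorm(length(mz), 0, noise))
  keep <- !duplicated(round(mz, 6))
  spectrum(spectrum_ref = ref,
           precursor_mz = precursor_mz(peptide, charge, modifications),
           charge = charge, peaks = cbind(mz[keep], intensity[keep]))
}

#' Simulate a complete synthetic calculus study
#'
#' Draws a multi-sample PSM table with the statistical structure the
#' pipeline assumes (category composition differing between well- and poorly
#' preserved samples, group-specific deamidation, injected decoys, dietary
#' milk peptides from the fixture database, and MS2 spectra from the built-in
#' fragment-intensity model with multiplicative noise for low-scoring dietary
#' PSMs), together with a truth record holding every latent label.
#'
#' @param params a [simulation_params()].
#' @param refdb output of [generate_reference_db()]; defaults to one
#'   generated from `params$seed`.
#' @return A list with `psms` (validated PSM data frame), `spectra` (named
#'   spectrum list), `truth` (per-PSM data frame: `sample_id`, `preserved`,
#'   `category`, `group`, `is_decoy`, `low_score_dietary`) and `params`.
#' @export
simulate_study <- function(params = simulation_params(),
                           refdb = generate_reference_db(params$seed)) {
  set.seed(params$seed)
  refsets <- refdb$refsets
  dietary_pool <- unlist(FIXTURE_PEPTIDES, use.names = FALSE)
  dietary_acc <- vapply(dietary_pool, function(pep) {
    hit <- which(vapply(refsets$dietary$sequence, grepl, logical(1),
                        pattern = pep, fixed = TRUE))
    refsets$dietary$accession[hit[1]]
  }, character(1))
  n_bad <- round(params$n_samples * params$bad_sample_fraction)
  preserved <- rep(c(TRUE, FALSE), c(params$n_samples - n_bad, n_bad))
  psm_rows <- list()
  truth_rows <- list()
  spectra <- list()
  scan <- 0L
  for (s in seq_len(params$n_samples)) {
    sid <- sprintf("S%03d", s)
    pr <- if (preserved[s]) {
      c(oral = params$oral_fraction, cont = params$contaminant_fraction)
    } else {
      c(oral = params$contaminant_fraction, cont = params$oral_fraction)
    }
    probs <- c(oral_microbiome = unname(pr["oral"]) * 0.6,
               salivary = unname(pr["oral"]) * 0.4,
               common_contaminant = unname(pr["cont"]) * 0.5,
               lab_contaminant = unname(pr["cont"]) * 0.5,
               dietary = params$dietary_fraction)
    probs <- c(probs, other = max(0, 1 - sum(probs)))
    cats <- sample(names(probs), params$psm_per_sample, replace = TRUE,
                   prob = probs)
    for (cat in cats) {
      scan <- scan + 1L
      ref <- sprintf("sim_scan_%06d", scan)
      is_decoy <- stats::runif(1) < params$decoy_fraction
      # in poorly preserved samples the apparent oral/dietary content is
      # itself modern contamination, so it deamidates at contaminant rates
      group <- if (preserved[s] && !is_decoy &&
                   !cat %in% c("common_contaminant", "lab_contaminant")) {
        "endogenous"
      } else {
        "contaminant"
      }
      if (cat == "dietary" && !is_decoy) {
        k <- sample(length(dietary_pool), 1L)
        peptide <- dietary_pool[k]
        accession <- dietary_acc[k]
      } else {
        peptide <- random_peptide()
        accession <- if (is_decoy) {
          sprintf("DECOY_%04d", sample.int(9999L, 1L))
        } else {
          switch(cat,
                 oral_microbiome = sample(refsets$oral_microbiome, 1L),
                 salivary = sample(refsets$salivary, 1L),
                 common_contaminant = sample(refsets$common_contaminants, 1L),
                 lab_contaminant = sample(refsets$lab_contaminants, 1L),
                 dietary = sprintf("DECOY_%04d", sample.int(9999L, 1L)),
                 sprintf("OTHR_%04d", sample.int(999L, 1L)))
        }
      }
      mods <- if (group == "endogenous") {
        draw_deamidation(peptide, params$deam_n_endogenous,
                         params$deam_q_endogenous)
      } else {
        draw_deamidation(peptide, params$deam_n_contaminant,
                         params$deam_q_contaminant)
      }
      low_diet <- cat == "dietary" && !is_decoy &&
        stats::runif(1) < params$dietary_low_score_fraction
      ion_score <- if (low_diet) {
        stats::runif(1, 20, 39)
      } else {
        stats::rnorm(1, params$ion_score_mean, params$ion_score_sd)
      }
      charge <- sample(2:4, 1L, prob = c(0.6, 0.3, 0.1))
      if (low_diet) {
        spectra[[ref]] <- simulate_spectrum(ref, peptide, mods, charge,
                                            params$spectral_noise)
      }
      psm_rows[[scan]] <- data.frame(
        sample_id = sid, individual_id = sprintf("IND%03d", s),
        site = "SimSite", subsite = "",
        spectrum_ref = ref, peptide = peptide, modifications = mods,
        accessions = accession, ion_score = ion_score,
        e_value = 10^stats::runif(1, -5, -3), is_decoy = is_decoy,
        precursor_mz = precursor_mz(peptide, charge, mods), charge = charge,
        stringsAsFactors = FALSE
      )
      truth_rows[[scan]] <- data.frame(
        sample_id = sid, preserved = preserved[s], category = cat,
        group = group, is_decoy = is_decoy, low_score_dietary = low_diet,
        stringsAsFactors = FALSE
      )
    }
  }
  psms <- do.call(rbind, psm_rows)
  rownames(psms) <- NULL
  validate_psms(psms)
  list(psms = psms, spectra = spectra,
       truth = do.call(rbind, truth_rows), params = params)
}
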