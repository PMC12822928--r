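# Monoisotopic residue masses (Da), proton and water, and modification deltas.
AA_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
PROTON_MASS <- 1.00728
WATER_MASS <- 18.01056
MOD_DELTA <- c(Carbamidomethyl = 57.02146, Oxidation = 15.99491,
               Deamidated = 0.98402)

#' Monoisotopic peptide mass
#'
#' @param peptide peptide string.
#' @param modifications canonical modification string.
#' @return Neutral monoisotopic mass in Da (residues + water + modification
#'   deltas).
#' @export
peptide_mass <- function(peptide, modifications = "") {
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  bad <- setdiff(res, names(AA_MONO_MASS))
  if (length(bad)) {
    stop("unknown residue(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  mods <- parse_modifications(modifications)[[1]]
  sum(AA_MONO_MASS[res]) + WATER_MASS + sum(MOD_DELTA[mods$name])
}

#' Precursor m/z of a peptide at a given charge
#'
#' @inheritParams peptide_mass
#' @param charge precursor charge.
#' @return (neutral mass + charge x proton) / charge.
#' @export
precursor_mz <- function(peptide, charge, modifications = "") {
  (peptide_mass(peptide, modifications) + charge * PROTON_MASS) / charge
}

# Deterministic built-in intensity model: y ions weighted 1.5x b ions, both
# scaled by a triangular profile peaking at mid-sequence (floor 0.1 so every
# ion keeps nonzero predicted intensity); doubly charged ions at 0.3x.
builtin_intensity_model <- function(series, index, ion_charge, peptide_length) {
  centre <- peptide_length / 2
  tri <- pmax(0.1, 1 - abs(index - centre) / centre)
  base <- ifelse(series == "y", 1.5, 1.0)
  zfac <- ifelse(ion_charge == 2L, 0.3, 1.0)
  100 * base * tri * zfac
}

#' Predict a b/y fragment spectrum for a peptide
#'
#' Generates singly charged b and y ions (plus doubly charged ones when the
#' precursor charge is 2 or more) with monoisotopic m/z from standard residue
#' masses; modification deltas shift every ion containing the modified
#' residue. Predicted intensities come from the built-in deterministic model
#' unless a `predictor` function is supplied; an external predictor receives
#' `(peptide, modifications, charge)` and must return a data frame in the
#' same ion-table shape, whose intensities are then used as-is.
#'
#' @param peptide peptide string of length >= 2.
#' @param modifications canonical modification string.
#' @param charge precursor charge.
#' @param predictor optional plug-in intensity predictor.
#' @return A list of class `calcproteo_fragments` with `peptide`, `charge` and
#'   `ions` (data frame: `series`, `index`, `ion_charge`, `mz`,
#'   `predicted_intensity`).
#' @export
predict_fragments <- function(peptide, modifications = "", charge = 2L,
                              predictor = NULL) {
  n <- nchar(peptide)
  if (n < 2L) stop("peptide must have length >= 2", call. = FALSE)
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  bad <- setdiff(res, names(AA_MONO_MASS))
  if (length(bad)) {
    stop("unknown residue(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  mods <- parse_modifications(modifications)[[1]]
  msg <- check_modifications(peptide, mods)
  if (!is.null(msg)) stop(msg, call. = FALSE)
  if (!is.null(predictor)) {
    ions <- predictor(peptide, modifications, charge)
    return(structure(list(peptide = peptide, charge = as.integer(charge),
                          ions = ions), class = "calcproteo_fragments"))
  }
  residue_mass <- unname(AA_MONO_MASS[res])
  if (nrow(mods)) {
    residue_mass[mods$position] <- residue_mass[mods$position] +
      unname(MOD_DELTA[mods$name])
  }
  prefix <- cumsum(residue_mass)           # neutral b fragment masses
  suffix <- rev(cumsum(rev(residue_mass))) # y_i = suffix mass + water
  idx <- seq_len(n - 1L)
  charges <- if (charge >= 2L) 1:2 else 1L
  ions <- do.call(rbind, lapply(charges, function(z) {
    rbind(
      data.frame(series = "b", index = idx, ion_charge = z,
                 mz = (prefix[idx] + z * PROTON_MASS) / z,
                 stringsAsFactors = FALSE),
      data.frame(series = "y", index = idx, ion_charge = z,
                 mz = (suffix[n - idx + 1L] + WATER_MASS + z * PROTON_MASS) / z,
                 stringsAsFactors = FALSE)
    )
  }))
  ions$predicted_intensity <- builtin_intensity_model(
    ions$series, ions$index, ions$ion_charge, n
  )
  rownames(ions) <- NULL
  structure(list(peptide = peptide, charge = as.integer(charge), ions = ions),
            class = "calcproteo_fragments")
}
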