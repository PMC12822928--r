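#' Read an MGF file of MS2 spectra
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `TITLE`, `PEPMASS` and `CHARGE`
#' headers. `TITLE` is used as the spectrum reference; peak lists are returned
#' sorted ascending by m/z regardless of file order.
#'
#' @param path path to an MGF file.
#' @return A named list of spectra keyed by spectrum reference; each spectrum
#'   is a list with `spectrum_ref`, `precursor_mz`, `charge` and `peaks`
#'   (two-column matrix `mz`, `intensity`).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins)) {
    stop("unbalanced BEGIN IONS/END IONS blocks", call. = FALSE)
  }
  spectra <- vector("list", length(begins))
  refs <- character(length(begins))
  for (b in seq_along(begins)) {
    block <- lines[(begins[b] + 1L):(ends[b] - 1L)]
    block <- block[nzchar(trimws(block))]
    is_header <- grepl("=", block, fixed = TRUE) & grepl("^[A-Z]", block)
    headers <- block[is_header]
    keys <- sub("=.*$", "", headers)
    vals <- sub("^[^=]*=", "", headers)
    names(vals) <- keys
    if (!"TITLE" %in% keys) {
      stop(sprintf("MGF block %d: missing TITLE", b), call. = FALSE)
    }
    if (!"PEPMASS" %in% keys) {
      stop(sprintf("MGF block %d: missing PEPMASS", b), call. = FALSE)
    }
    charge <- if ("CHARGE" %in% keys) {
      as.integer(sub("\\+$", "", trimws(vals[["CHARGE"]])))
    } else NA_integer_
    peak_lines <- block[!is_header]
    if (length(peak_lines)) {
      fields <- strsplit(trimws(peak_lines), "[ \t]+")
      mz <- as.numeric(vapply(fields, `[`, character(1), 1L))
      it <- as.numeric(vapply(fields, `[`, character(1), 2L))
      if (anyNA(mz) || anyNA(it)) {
        stop(sprintf("MGF block %d: malformed peak line", b), call. = FALSE)
      }
    } else {
      mz <- numeric()
      it <- numeric()
    }
    o <- order(mz)
    refs[b] <- trimws(vals[["TITLE"]])
    spectra[[b]] <- spectrum(
      spectrum_ref = refs[b],
      precursor_mz = as.numeric(strsplit(trimws(vals[["PEPMASS"]]), "[ \t]+")[[1]][1]),
      charge = charge,
      peaks = cbind(mz = mz[o], intensity = it[o])
    )
  }
  if (anyDuplicated(refs)) {
    stop("duplicate spectrum TITLE(s): ",
         paste(unique(refs[duplicated(refs)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(spectra, refs)
}

#' Construct a spectrum object
#'
#' @param spectrum_ref unique reference string (MGF TITLE).
#' @param precursor_mz precursor m/z.
#' @param charge precursor charge.
#' @param peaks two-column matrix (`mz`, `intensity`); reordered ascending.
#' @return A list of class `calcproteo_spectrum`.
#' @export
spectrum <- function(spectrum_ref, precursor_mz, charge, peaks) {
  peaks <- matrix(as.numeric(peaks), ncol = 2,
                  dimnames = list(NULL, c("mz", "intensity")))
  peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  if (nrow(peaks) > 1 && any(diff(peaks[, "mz"]) <= 0)) {
    stop("spectrum m/z values must be strictly increasing", call. = FALSE)
  }
  if (any(peaks[, "intensity"] < 0)) {
    stop("spectrum intensities must be non-negative", call. = FALSE)
  }
  structure(list(spectrum_ref = spectrum_ref,
                 precursor_mz = as.numeric(precursor_mz),
                 charge = as.integer(charge), peaks = peaks),
            class = "calcproteo_spectrum")
}

#' Write spectra to an MGF file
#'
#' @param spectra a list of spectra as returned by [read_mgf()].
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", sp$spectrum_ref),
                 sprintf("PEPMASS=%.6f", sp$precursor_mz),
                 sprintf("CHARGE=%d+", sp$charge),
                 sprintf("%.6f %.6f", sp$peaks[, "mz"], sp$peaks[, "intensity"]),
                 "END IONS", ""), con)
  }
  invisible(path)
}
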