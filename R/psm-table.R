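# Required columns of the canonical (generic) PSM table, in schema order.
PSM_COLUMNS <- c("sample_id", "individual_id", "site", "subsite",
                 "spectrum_ref", "peptide", "modifications", "accessions",
                 "ion_score", "e_value", "is_decoy", "precursor_mz", "charge")

# Variable/fixed modifications understood by the pipeline and the residues
# they are chemically allowed on.
MOD_ALLOWED_RESIDUES <- list(
  Carbamidomethyl = "C",
  Oxidation       = c("M", "P"),
  Deamidated      = c("N", "Q")
)

#' Parse a semicolon-joined modification string
#'
#' The canonical encoding is `"Name:pos"` tokens joined by `";"`, positions
#' 1-based within the peptide, e.g. `"Deamidated:2;Oxidation:7"`. An empty
#' string (or `NA`) means no modifications.
#'
#' @param x character vector of modification strings.
#' @return A list (one element per input) of data frames with columns
#'   `position` (integer) and `name` (character), sorted by position.
#' @export
parse_modifications <- function(x) {
  lapply(x, function(s) {
    empty <- data.frame(position = integer(), name = character(),
                        stringsAsFactors = FALSE)
    if (is.na(s) || !nzchar(trimws(s))) return(empty)
    toks <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
    toks <- toks[nzchar(trimws(toks))]
    if (!length(toks)) return(empty)
    parts <- regmatches(toks, regexec("^\\s*([A-Za-z]+)\\s*:\\s*([0-9]+)\\s*$", toks))
    bad <- vapply(parts, function(p) length(p) != 3L, logical(1))
    if (any(bad)) {
      stop("malformed modification token(s): ",
           paste(toks[bad], collapse = ", "), call. = FALSE)
    }
    out <- data.frame(
      position = as.integer(vapply(parts, `[`, character(1), 3L)),
      name = vapply(parts, `[`, character(1), 2L),
      stringsAsFactors = FALSE
    )
    out[order(out$position), , drop = FALSE]
  })
}

#' Format parsed modifications back to the canonical string
#'
#' @param mods a data frame as returned by [parse_modifications()], or a list
#'   of them.
#' @return Character vector of `"Name:pos"` strings joined by `";"`.
#' @export
format_modifications <- function(mods) {
  if (is.data.frame(mods)) mods <- list(mods)
  vapply(mods, function(m) {
    if (!nrow(m)) return("")
    m <- m[order(m$position), , drop = FALSE]
    paste(sprintf("%s:%d", m$name, m$position), collapse = ";")
  }, character(1))
}

# Validates modification placement for one peptide; returns NULL or a message.
check_modifications <- function(peptide, mods) {
  if (!nrow(mods)) return(NULL)
  n <- nchar(peptide)
  if (any(mods$position < 1L | mods$position > n)) {
    return(sprintf("modification position outside peptide of length %d", n))
  }
  unknown <- setdiff(mods$name, names(MOD_ALLOWED_RESIDUES))
  if (length(unknown)) {
    return(paste("unknown modification:", paste(unknown, collapse = ", ")))
  }
  res <- substring(peptide, mods$position, mods$position)
  ok <- mapply(function(r, nm) r %in% MOD_ALLOWED_RESIDUES[[nm]], res, mods$name)
  if (!all(ok)) {
    i <- which(!ok)[1]
    return(sprintf("%s not allowed on residue %s at position %d",
                   mods$name[i], res[i], mods$position[i]))
  }
  NULL
}

#' Validate a PSM table against the domain invariants
#'
#' Checks column presence and types, peptide alphabet, modification placement
#' (Deamidated only on N/Q, Oxidation only on M/P, Carbamidomethyl only on C,
#' positions within the peptide), non-empty accession lists, positive
#' e-values and charges.
#'
#' @param psms a PSM data frame.
#' @return `psms` invisibly; errors name the offending row(s).
#' @export
validate_psms <- function(psms) {
  missing <- setdiff(PSM_COLUMNS, names(psms))
  if (length(missing)) {
    stop("PSM table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!nrow(psms)) return(invisible(psms))
  errs <- character()
  bad_pep <- grepl("[^A-Z]", psms$peptide) | !nzchar(psms$peptide)
  if (any(bad_pep)) {
    errs <- c(errs, sprintf("row %d: peptide must be an uppercase amino-acid string",
                            which(bad_pep)))
  }
  if (any(!nzchar(trimws(psms$accessions)))) {
    errs <- c(errs, sprintf("row %d: accessions must be non-empty",
                            which(!nzchar(trimws(psms$accessions)))))
  }
  if (any(!is.finite(psms$e_value) | psms$e_value <= 0)) {
    errs <- c(errs, sprintf("row %d: e_value must be > 0",
                            which(!is.finite(psms$e_value) | psms$e_value <= 0)))
  }
  if (any(psms$charge < 1L)) {
    errs <- c(errs, sprintf("row %d: charge must be >= 1", which(psms$charge < 1L)))
  }
  mods <- parse_modifications(psms$modifications)
  for (i in seq_len(nrow(psms))) {
    msg <- tryCatch(check_modifications(psms$peptide[i], mods[[i]]),
                    error = function(e) conditionMessage(e))
    if (!is.null(msg)) errs <- c(errs, sprintf("row %d: %s", i, msg))
  }
  if (length(errs)) {
    stop("invalid PSM table:\n  ", paste(errs, collapse = "\n  "), call. = FALSE)
  }
  invisible(psms)
}

#' Primary accession of each PSM
#'
#' The first accession listed carries all protein-level bookkeeping
#' (filtering support counts, classification, deamidation units).
#'
#' @param psms a PSM data frame.
#' @return Character vector of primary accessions.
#' @export
primary_accession <- function(psms) {
  vapply(strsplit(psms$accessions, ";", fixed = TRUE),
         function(a) trimws(a[1]), character(1))
}

#' Read a PSM table
#'
#' @param path path to a delimited PSM export.
#' @param dialect `"generic_tsv"` for the canonical tab-separated schema
#'   (columns `sample_id, individual_id, site, subsite, spectrum_ref, peptide,
#'   modifications, accessions, ion_score, e_value, is_decoy, precursor_mz,
#'   charge`), or `"mascot_csv"` for a comma-separated export with Mascot-style
#'   headers (`pep_seq`, `pep_var_mod_conf`-free `pep_var_mod_pos` handling is
#'   out of scope; the adapter expects columns `pep_seq`, `pep_var_mods`
#'   already in `Name:pos` form, `prot_acc`, `pep_score`, `pep_expect`,
#'   `pep_isdecoy`, `pep_exp_mz`, `pep_exp_z`, plus the provenance columns).
#' @return A validated PSM data frame.
#' @export
read_psm_table <- function(path, dialect = c("generic_tsv", "mascot_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("PSM file not found: ", path, call. = FALSE)
  if (dialect == "generic_tsv") {
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            colClasses = "character", na.strings = NULL)
    missing <- setdiff(PSM_COLUMNS, names(df))
    if (length(missing)) {
      stop("missing required column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
    mascot_map <- c(sample_id = "sample_id", individual_id = "individual_id",
                    site = "site", subsite = "subsite",
                    spectrum_ref = "pep_scan_title", peptide = "pep_seq",
                    modifications = "pep_var_mods", accessions = "prot_acc",
                    ion_score = "pep_score", e_value = "pep_expect",
                    is_decoy = "pep_isdecoy", precursor_mz = "pep_exp_mz",
                    charge = "pep_exp_z")
    missing <- setdiff(unname(mascot_map), names(raw))
    if (length(missing)) {
      stop("missing required column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    df <- stats::setNames(raw[unname(mascot_map)], names(mascot_map))
  }
  df <- df[PSM_COLUMNS]
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(df[[col]]))
    if (length(bad)) {
      stop(sprintf("row %s: cannot parse %s value '%s'",
                   paste(bad, collapse = ","), col, df[[col]][bad[1]]),
           call. = FALSE)
    }
    v
  }
  df$ion_score <- num("ion_score")
  df$e_value <- num("e_value")
  df$precursor_mz <- num("precursor_mz")
  df$charge <- as.integer(num("charge"))
  dec <- toupper(trimws(df$is_decoy))
  bad <- which(!dec %in% c("TRUE", "FALSE", "T", "F", "1", "0", "YES", "NO"))
  if (length(bad)) {
    stop("row ", paste(bad, collapse = ","), ": cannot parse is_decoy",
         call. = FALSE)
  }
  df$is_decoy <- dec %in% c("TRUE", "T", "1", "YES")
  rownames(df) <- NULL
  validate_psms(df)
  df
}

#' Write a PSM table in the canonical generic TSV schema
#'
#' Round-trips with [read_psm_table()] field for field.
#'
#' @param psms a PSM data frame.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_psm_table <- function(psms, path) {
  validate_psms(psms)
  out <- psms[PSM_COLUMNS]
  out$is_decoy <- ifelse(out$is_decoy, "TRUE", "FALSE")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
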