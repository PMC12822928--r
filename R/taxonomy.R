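# Reporting conventions for milk-peptide taxonomy: genus-level hits within
# Bovinae roll up to the subfamily (the packaged database does not
# distinguish congeners of Bos), while Ovis, Capra and Equus stay specific.
DEFAULT_RANK_ROLLUP <- c(Bos = "Bovinae")
DEFAULT_CEILING_NODE <- "Mammalia"

#' Match a peptide against the dietary protein database
#'
#' Exact substring matching with isoleucine/leucine equivalence (the two are
#' mass-identical in MS). In `deamidation_aware` mode an observed D may
#' additionally align to a database N and an observed E to a database Q
#' (never the reverse); such positions are recorded so downstream assignment
#' can flag labels that hinge on assuming deamidation.
#'
#' @param peptide observed peptide string.
#' @param refsets a `calcproteo_refsets`.
#' @param mode `"deamidation_aware"` (default) or `"strict"`.
#' @return Data frame with one row per occurrence: `peptide`, `accession`,
#'   `protein_name`, `taxon`, `start` (1-based offset in the protein),
#'   `deamidation_positions` and `il_positions` (comma-joined 1-based peptide
#'   positions, `""` if none), `reassigned` (always `FALSE` here).
#' @export
match_peptide <- function(peptide, refsets,
                          mode = c("deamidation_aware", "strict")) {
  mode <- match.arg(mode)
  if (!nrow(refsets$dietary)) stop("dietary database is empty", call. = FALSE)
  q <- strsplit(peptide, "", fixed = TRUE)[[1]]
  k <- length(q)
  rows <- list()
  for (i in seq_len(nrow(refsets$dietary))) {
    s <- strsplit(refsets$dietary$sequence[i], "", fixed = TRUE)[[1]]
    n <- length(s)
    if (n < k) next
    for (start in seq_len(n - k + 1L)) {
      win <- s[start:(start + k - 1L)]
      exact <- win == q
      il <- !exact & q %in% c("I", "L") & win %in% c("I", "L")
      deam <- !exact & ((q == "D" & win == "N") | (q == "E" & win == "Q"))
      if (mode == "strict") deam <- rep(FALSE, k)
      if (all(exact | il | deam)) {
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = peptide,
          accession = refsets$dietary$accession[i],
          protein_name = refsets$dietary$protein_name[i],
          taxon = refsets$dietary$taxon[i],
          start = start,
          deamidation_positions = paste(which(deam), collapse = ","),
          il_positions = paste(which(il), collapse = ","),
          reassigned = FALSE,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(peptide = character(), accession = character(),
                      protein_name = character(), taxon = character(),
                      start = integer(), deamidation_positions = character(),
                      il_positions = character(), reassigned = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply homolog exclusion and reassignment rules to peptide matches
#'
#' Matches to accessions on the exclusion list (hypothetical bacterial
#' proteins attributed to genome-sequencing contamination) are dropped.
#' Matches to accessions with a reassignment rule are relabelled to the
#' mapped dietary protein name and flagged `reassigned`; their own (e.g.
#' bacterial) taxon is excluded from assignment evidence, which then rests on
#' the co-matching dietary entries only.
#'
#' @param matches output of [match_peptide()].
#' @param refsets a `calcproteo_refsets`.
#' @return The filtered/relabelled match table.
#' @export
apply_reassignment_rules <- function(matches, refsets) {
  bad_target <- setdiff(unname(refsets$reassignment_rules),
                        refsets$dietary$protein_name)
  if (length(bad_target)) {
    stop("reassignment target(s) absent from dietary database: ",
         paste(bad_target, collapse = ", "), call. = FALSE)
  }
  matches <- matches[!matches$accession %in% refsets$exclusion_accessions, ,
                     drop = FALSE]
  hit <- matches$accession %in% names(refsets$reassignment_rules)
  if (any(hit)) {
    matches$protein_name[hit] <-
      unname(refsets$reassignment_rules[matches$accession[hit]])
    matches$reassigned[hit] <- TRUE
  }
  rownames(matches) <- NULL
  matches
}

# Label for one set of matched taxa: LCA, then rank rollup, then the
# "unspecific" ceiling (LCA at or above the ceiling node).
label_taxa <- function(taxa, tree, rollup = DEFAULT_RANK_ROLLUP,
                       ceiling_node = DEFAULT_CEILING_NODE) {
  lca <- tax_lca(tree, taxa)
  if (lca %in% names(rollup)) lca <- unname(rollup[lca])
  if (lca %in% tax_path(tree, ceiling_node)) return("unspecific")
  lca
}

#' Assign a taxonomic group label to a peptide's matches
#'
#' A single matched taxon yields that taxon (after reporting-rank rollup).
#' When the match set splits into deamidation-free and deamidation-assumed
#' interpretations that support different labels, the label is the
#' alternation of the two maximally specific alternatives (e.g.
#' `"Bovinae/Ovis"` for the BLG peptide TPEVDDEALEK, readable as either an
#' unmodified bovine sequence or a deamidated ovine one). Otherwise multiple
#' taxa collapse to their lowest common ancestor; an LCA at or above the
#' ceiling node (class Mammalia) reports as `"unspecific"`. Reassigned
#' matches contribute their protein name but no taxon evidence.
#'
#' @param matches match table (after [apply_reassignment_rules()]).
#' @param tree a `calcproteo_taxonomy`.
#' @param merge_map optional named list collapsing labels into display groups
#'   (applied to the final label).
#' @param rollup named character vector mapping taxa to their reporting rank.
#' @param ceiling_node node at/above which labels become `"unspecific"`.
#' @return A list with `peptide`, `matches`, `label` and
#'   `deamidation_dependent`.
#' @export
assign_group <- function(matches, tree, merge_map = NULL,
                         rollup = DEFAULT_RANK_ROLLUP,
                         ceiling_node = DEFAULT_CEILING_NODE) {
  peptide <- if (nrow(matches)) matches$peptide[1] else NA_character_
  evid <- matches[!matches$reassigned, , drop = FALSE]
  if (!nrow(evid)) {
    label <- if (nrow(matches)) "unspecific" else "unmatched"
    return(list(peptide = peptide, matches = matches, label = label,
                deamidation_dependent = FALSE))
  }
  is_deam <- nzchar(evid$deamidation_positions)
  strict <- evid[!is_deam, , drop = FALSE]
  deam <- evid[is_deam, , drop = FALSE]
  lab <- function(m) label_taxa(unique(m$taxon), tree, rollup, ceiling_node)
  if (nrow(strict) && nrow(deam)) {
    label_all <- lab(evid)
    label_strict <- lab(strict)
    if (identical(label_strict, label_all)) {
      label <- label_all
      dependent <- FALSE
    } else {
      label_deam <- lab(deam)
      label <- if (identical(label_strict, label_deam)) label_strict else
        paste(label_strict, label_deam, sep = "/")
      dependent <- TRUE
    }
  } else if (nrow(strict)) {
    label <- lab(strict)
    dependent <- FALSE
  } else {
    label <- lab(deam)
    dependent <- TRUE
  }
  if (!is.null(merge_map)) {
    for (grp in names(merge_map)) {
      if (label %in% merge_map[[grp]]) label <- grp
    }
  }
  list(peptide = peptide, matches = matches, label = label,
       deamidation_dependent = dependent)
}

#' Assign taxonomy labels to a set of peptides
#'
#' Convenience driver: match, apply exclusion/reassignment rules, assign.
#'
#' @param peptides character vector (deduplicated internally).
#' @param refsets a `calcproteo_refsets`.
#' @param tree a `calcproteo_taxonomy`.
#' @param mode matching mode, see [match_peptide()].
#' @inheritParams assign_group
#' @return Data frame with one row per unique peptide: `peptide`, `label`,
#'   `deamidation_dependent`, `matched_accessions`, `protein_names`
#'   (semicolon-joined).
#' @export
assign_peptides <- function(peptides, refsets, tree,
                            mode = "deamidation_aware", merge_map = NULL,
                            rollup = DEFAULT_RANK_ROLLUP,
                            ceiling_node = DEFAULT_CEILING_NODE) {
  peptides <- unique(peptides)
  rows <- lapply(peptides, function(p) {
    m <- apply_reassignment_rules(match_peptide(p, refsets, mode), refsets)
    a <- assign_group(m, tree, merge_map, rollup, ceiling_node)
    data.frame(peptide = p, label = a$label,
               deamidation_dependent = a$deamidation_dependent,
               matched_accessions = paste(unique(m$accession), collapse = ";"),
               protein_names = paste(unique(m$protein_name), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
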