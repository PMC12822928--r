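# Category precedence used everywhere an accession appears in several lists:
# contamination wins ties (conservative authentication).
CATEGORY_PRECEDENCE <- c("lab_contaminant", "common_contaminant",
                         "oral_microbiome", "salivary", "dietary")

#' Construct a taxonomy tree
#'
#' A rooted, acyclic tree of named nodes with ranks, held as a node table.
#'
#' @param nodes data frame with columns `name`, `rank`, `parent` (`NA` or `""`
#'   for the single root).
#' @return A data frame of class `calcproteo_taxonomy`.
#' @export
taxonomy_tree <- function(nodes) {
  stopifnot(all(c("name", "rank", "parent") %in% names(nodes)))
  nodes$parent[!is.na(nodes$parent) & !nzchar(nodes$parent)] <- NA_character_
  if (anyDuplicated(nodes$name)) {
    stop("duplicate taxonomy node name(s)", call. = FALSE)
  }
  roots <- nodes$name[is.na(nodes$parent)]
  if (length(roots) != 1L) {
    stop("taxonomy must have exactly one root, found: ",
         paste(roots, collapse = ", "), call. = FALSE)
  }
  known <- nodes$parent[!is.na(nodes$parent)]
  if (!all(known %in% nodes$name)) {
    stop("parent(s) absent from node table: ",
         paste(setdiff(known, nodes$name), collapse = ", "), call. = FALSE)
  }
  # acyclicity: every node must reach the root
  for (nm in nodes$name) tax_path(structure(nodes, class = c("calcproteo_taxonomy", "data.frame")), nm)
  structure(nodes, class = c("calcproteo_taxonomy", "data.frame"))
}

#' Root-to-node path in a taxonomy tree
#'
#' @param tree a `calcproteo_taxonomy`.
#' @param name node name.
#' @return Character vector of node names from the root down to `name`.
#' @export
tax_path <- function(tree, name) {
  if (!name %in% tree$name) {
    stop("taxon absent from tree: ", name, call. = FALSE)
  }
  path <- character()
  cur <- name
  parent <- stats::setNames(tree$parent, tree$name)
  while (!is.na(cur)) {
    if (cur %in% path) stop("taxonomy cycle at node: ", cur, call. = FALSE)
    path <- c(cur, path)
    cur <- parent[[cur]]
  }
  path
}

#' Lowest common ancestor of a set of taxa
#'
#' @param tree a `calcproteo_taxonomy`.
#' @param taxa character vector of node names.
#' @return The name of the deepest node lying on every root-to-taxon path.
#' @export
tax_lca <- function(tree, taxa) {
  taxa <- unique(taxa)
  if (!length(taxa)) stop("no taxa given", call. = FALSE)
  paths <- lapply(taxa, function(t) tax_path(tree, t))
  depth <- min(lengths(paths))
  lca <- paths[[1]][1]
  for (d in seq_len(depth)) {
    level <- vapply(paths, `[`, character(1), d)
    if (length(unique(level)) == 1L) lca <- level[1] else break
  }
  lca
}

#' Load reference sets and the taxonomy tree
#'
#' @param fasta dietary protein FASTA (headers are accessions).
#' @param lists YAML file with keys `oral_microbiome`, `salivary`,
#'   `common_contaminants`, `lab_contaminants` (accession lists) and optional
#'   `exclusion_accessions` and `reassignment_rules` (accession to dietary
#'   protein name mapping).
#' @param taxonomy TSV of taxonomy nodes (`name`, `rank`, `parent`).
#' @param lineages sidecar TSV for the FASTA (`accession`, `protein_name`,
#'   `lineage` as a `">"`-joined root-to-node path); defaults to the FASTA
#'   path with extension replaced by `_lineages.tsv`.
#' @return A list with components `refsets` (class `calcproteo_refsets`) and
#'   `tree` (class `calcproteo_taxonomy`). An accession appearing in several
#'   category lists is kept in the highest-precedence one
#'   (lab > common contaminant > oral microbiome > salivary > dietary) with a
#'   warning.
#' @export
load_reference_sets <- function(fasta, lists, taxonomy,
                                lineages = paste0(sub("\\.[^.]*$", "", fasta),
                                                  "_lineages.tsv")) {
  for (p in c(fasta, lists, taxonomy, lineages)) {
    if (!file.exists(p)) stop("reference file not found: ", p, call. = FALSE)
  }
  tree <- taxonomy_tree(utils::read.delim(taxonomy, stringsAsFactors = FALSE,
                                          colClasses = "character",
                                          na.strings = c("NA", "")))
  seqs <- Biostrings::readAAStringSet(fasta)
  acc <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  lin <- utils::read.delim(lineages, stringsAsFactors = FALSE,
                           colClasses = "character")
  stopifnot(all(c("accession", "protein_name", "lineage") %in% names(lin)))
  missing <- setdiff(acc, lin$accession)
  if (length(missing)) {
    stop("FASTA accession(s) without lineage entry: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dietary <- data.frame(
    accession = acc,
    protein_name = lin$protein_name[match(acc, lin$accession)],
    sequence = as.character(seqs),
    lineage = lin$lineage[match(acc, lin$accession)],
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (any(grepl("[^A-Z]", dietary$sequence))) {
    stop("dietary sequences must be uppercase amino-acid strings", call. = FALSE)
  }
  # every lineage must be a root-to-node path in the tree
  for (i in seq_len(nrow(dietary))) {
    nodes <- strsplit(dietary$lineage[i], ">", fixed = TRUE)[[1]]
    absent <- setdiff(nodes, tree$name)
    if (length(absent)) {
      stop("lineage node(s) absent from taxonomy: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    if (!identical(nodes, tax_path(tree, nodes[length(nodes)]))) {
      stop("lineage of ", dietary$accession[i],
           " is not a root-to-node path in the taxonomy", call. = FALSE)
    }
  }
  dietary$taxon <- vapply(strsplit(dietary$lineage, ">", fixed = TRUE),
                          function(p) p[length(p)], character(1))
  yl <- yaml::read_yaml(lists)
  getset <- function(key) unique(as.character(unlist(yl[[key]])))
  sets <- list(
    lab_contaminant = getset("lab_contaminants"),
    common_contaminant = getset("common_contaminants"),
    oral_microbiome = getset("oral_microbiome"),
    salivary = getset("salivary"),
    dietary = dietary$accession
  )
  # precedence resolution: drop an accession from every lower-precedence set
  seen <- character()
  for (cat in CATEGORY_PRECEDENCE) {
    dup <- intersect(sets[[cat]], seen)
    if (length(dup)) {
      warning(sprintf("accession(s) in multiple categories kept at higher precedence: %s",
                      paste(dup, collapse = ", ")), call. = FALSE)
      sets[[cat]] <- setdiff(sets[[cat]], dup)
    }
    seen <- c(seen, sets[[cat]])
  }
  reassign <- unlist(yl[["reassignment_rules"]])
  reassign <- if (is.null(reassign)) character() else
    stats::setNames(as.character(reassign), names(reassign))
  refsets <- structure(list(
    oral_microbiome = sets$oral_microbiome,
    salivary = sets$salivary,
    common_contaminants = sets$common_contaminant,
    lab_contaminants = sets$lab_contaminant,
    dietary = dietary[dietary$accession %in% sets$dietary, , drop = FALSE],
    exclusion_accessions = getset("exclusion_accessions"),
    reassignment_rules = reassign
  ), class = "calcproteo_refsets")
  bad_target <- setdiff(unname(reassign), refsets$dietary$protein_name)
  if (length(bad_target)) {
    stop("reassignment target(s) absent from dietary database: ",
         paste(bad_target, collapse = ", "), call. = FALSE)
  }
  list(refsets = refsets, tree = tree)
}

#' @export
print.calcproteo_refsets <- function(x, ...) {
  cat("calcproteo reference sets\n")
  cat(sprintf("  oral microbiome: %d  salivary: %d  common contaminants: %d  lab contaminants: %d\n",
              length(x$oral_microbiome), length(x$salivary),
              length(x$common_contaminants), length(x$lab_contaminants)))
  cat(sprintf("  dietary proteins: %d  exclusions: %d  reassignment rules: %d\n",
              nrow(x$dietary), length(x$exclusion_accessions),
              length(x$reassignment_rules)))
  invisible(x)
}
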