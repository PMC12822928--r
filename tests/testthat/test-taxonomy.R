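refdb <- generate_reference_db(1)
refsets <- refdb$refsets
tree <- refdb$tree

test_that("TPEVDDEALEK matches bovine strictly and ovine via deamidation at 6", {
  m <- match_peptide("TPEVDDEALEK", refsets, mode = "deamidation_aware")
  expect_setequal(unique(m$accession), c("BLG_BOS", "BLG_OVIS", "SYN_STAPH01"))
  ovis <- m[m$accession == "BLG_OVIS", ]
  expect_equal(ovis$deamidation_positions, "6")
  bos <- m[m$accession == "BLG_BOS", ]
  expect_equal(bos$deamidation_positions, "")
  # strict mode drops the ovine interpretation
  s <- match_peptide("TPEVDDEALEK", refsets, mode = "strict")
  expect_false("BLG_OVIS" %in% s$accession)
  expect_true("BLG_BOS" %in% s$accession)
})

test_that("I/L equivalence matches and records positions", {
  rs <- make_refsets(dietary = data.frame(
    accession = "X1", protein_name = "P", sequence = "GGIAAAKGG",
    lineage = NA, taxon = "Bos", stringsAsFactors = FALSE))
  m <- match_peptide("LAAAK", rs, mode = "strict")
  expect_equal(nrow(m), 1)
  expect_equal(m$il_positions, "1")
  expect_equal(m$start, 3)
})

test_that("deamidation-aware matches are a superset of strict matches", {
  peps <- c("TPEVDDEALEK", unlist(calcproteo:::FIXTURE_PEPTIDES,
                                  use.names = FALSE))
  for (p in peps) {
    strict <- match_peptide(p, refsets, "strict")
    aware <- match_peptide(p, refsets, "deamidation_aware")
    key <- function(m) paste(m$accession, m$start)
    expect_true(all(key(strict) %in% key(aware)))
  }
})

test_that("exclusion and reassignment rules prune bacterial homologs", {
  m <- match_peptide("WFSGYPTHVK", refsets)  # casein peptide + Jeotgalicoccus homolog
  expect_true("SYN_JEOT01" %in% m$accession)
  pruned <- apply_reassignment_rules(m, refsets)
  expect_false("SYN_JEOT01" %in% pruned$accession)

  m <- match_peptide("TPEVDDEALEK", refsets)
  pruned <- apply_reassignment_rules(m, refsets)
  staph <- pruned[pruned$accession == "SYN_STAPH01", ]
  expect_equal(staph$protein_name, "BLG")  # counted as Beta-lactoglobulin
  expect_true(staph$reassigned)
  # without rules nothing changes
  rs0 <- refsets
  rs0$exclusion_accessions <- character()
  rs0$reassignment_rules <- character()
  expect_equal(apply_reassignment_rules(m, rs0), m)
  # reassignment target missing from dietary DB is a configuration error
  rs_bad <- refsets
  rs_bad$reassignment_rules <- c(SYN_STAPH01 = "NotAProtein")
  expect_error(apply_reassignment_rules(m, rs_bad), "NotAProtein")
})

test_that("assignment labels follow the alternation / LCA / ceiling rules", {
  assign_of <- function(pep) {
    m <- apply_reassignment_rules(match_peptide(pep, refsets), refsets)
    assign_group(m, tree)
  }
  a <- assign_of("TPEVDDEALEK")
  expect_equal(a$label, "Bovinae/Ovis")
  expect_true(a$deamidation_dependent)

  # Bos-only peptide reports at the subfamily rank
  a <- assign_of("GPTHWSYVAK")
  expect_equal(a$label, "Bovinae")
  expect_false(a$deamidation_dependent)

  # Ovis + Capra -> subfamily LCA
  expect_equal(assign_of("WTVHGPAFSK")$label, "Caprinae")
  # Bos + Ovis + Capra -> family LCA
  expect_equal(assign_of("VFPTYSGFWK")$label, "Bovidae")
  # all pecorans incl. Cervidae -> infraorder LCA
  expect_equal(assign_of("AGTWHSVAMK")$label, "Pecora")
  # ruminants + Equus -> LCA at the Mammalia ceiling -> unspecific
  expect_equal(assign_of("SGVYWHAPTK")$label, "unspecific")
  # species-specific labels kept where unique
  expect_equal(assign_of("YSHWGTPVFK")$label, "Ovis")
  expect_equal(assign_of("HGWFTSYPAK")$label, "Capra")
  expect_equal(assign_of("FHWSPVTGYK")$label, "Equus")
})

test_that("LCA agrees with brute-force path intersection on random trees", {
  set.seed(77)
  for (trial in 1:10) {
    n <- sample(10:50, 1)
    parent <- c(NA, sprintf("n%d", vapply(2:n, function(i)
      sample(seq_len(i - 1), 1), numeric(1))))
    tr <- taxonomy_tree(data.frame(name = sprintf("n%d", 1:n),
                                   rank = "clade", parent = parent,
                                   stringsAsFactors = FALSE))
    taxa <- sprintf("n%d", sample(n, sample(2:5, 1)))
    paths <- lapply(taxa, function(t) tax_path(tr, t))
    common <- Reduce(intersect, paths)
    # brute force: deepest node present in every path
    depth <- vapply(common, function(x) length(tax_path(tr, x)), numeric(1))
    expect_equal(tax_lca(tr, taxa), common[which.max(depth)])
  }
})

test_that("single-lineage matches never produce an alternation label", {
  for (pep in unlist(calcproteo:::FIXTURE_PEPTIDES, use.names = FALSE)) {
    m <- apply_reassignment_rules(match_peptide(pep, refsets), refsets)
    evid <- m[!m$reassigned, ]
    if (length(unique(evid$taxon)) == 1L) {
      expect_false(grepl("/", assign_group(m, tree)$label, fixed = TRUE))
    }
  }
})

test_that("removing taxa from the database never broadens a label", {
  rank_depth <- function(label) {
    if (label %in% c("unspecific", "unmatched")) return(0L)
    first <- strsplit(label, "/", fixed = TRUE)[[1]][1]
    length(tax_path(tree, first))
  }
  for (pep in c("TPEVDDEALEK", "VFPTYSGFWK", "AGTWHSVAMK")) {
    full <- assign_group(
      apply_reassignment_rules(match_peptide(pep, refsets), refsets), tree)
    for (drop_taxon in c("Ovis", "Capra", "Cervus")) {
      rs <- refsets
      rs$dietary <- rs$dietary[rs$dietary$taxon != drop_taxon, , drop = FALSE]
      m <- apply_reassignment_rules(match_peptide(pep, rs), rs)
      if (!nrow(m)) next
      reduced <- assign_group(m, tree)
      expect_gte(rank_depth(reduced$label), rank_depth(full$label))
    }
  }
})
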