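---
title: "Methods: authentication and dietary analysis of dental-calculus proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: authentication and dietary analysis of dental-calculus proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcproteo)
```

# The problem

Shotgun proteomics of archaeological dental calculus yields peptide-spectrum
matches (PSMs) from a mixture of sources: the oral microbiome and host
salivary proteins (the *oral signature* that marks a sample as genuinely
endogenous), environmental and laboratory contaminants, and — the analytes of
interest — dietary proteins such as the milk proteins beta-lactoglobulin
(BLG), alpha-S1-casein and BTN1A1. calcproteo implements the post-search
inference chain that turns a search-engine export into authenticated,
validated, taxonomically assigned dietary identifications: PSM/protein
filtering with target-decoy FDR gates, oral-signature authentication,
deamidation-based damage assessment, spectral validation of weak dietary
PSMs, deamidation-aware taxonomy, and per-individual/per-site summaries.
Everything downstream of the search engine is in scope; acquisition and the
search itself are not — the pipeline consumes a PSM table and (optionally)
MGF spectra.

# Filtering and the FDR gate

A PSM survives when its e-value is at most `e_value_max` (default 0.01) and
its primary accession (the first listed; no protein inference is attempted)
is supported by at least `min_psm_per_protein` surviving target PSMs
(default 2). The two rules are applied in order, once — no fixpoint
iteration. A single pass is deterministic and reproducible; iterating to a
fixpoint would only remove additional borderline proteins whose support was
itself made of borderline PSMs, which the downstream dietary re-check
catches anyway.

The FDR estimator is the plain decoy/target ratio over *distinct units*
(primary accessions at protein level; (peptide, modifications) pairs at
peptide level), reported in percent. The classical 2D/(T+D) alternative is
not used; the quantity gated on here is a sample-quality indicator, not a
per-PSM error bound, and D/T is the more conservative of the two. Samples
are excluded when protein FDR exceeds 5% or peptide FDR exceeds 2%; the
bounds are inclusive (exclusion applies to *strictly greater* FDR).

# Oral-signature authentication

Each PSM is classified by its primary accession against four reference
lists plus the dietary database. An accession appearing in several lists is
resolved conservatively — contamination wins ties:

lab contaminant > common contaminant > oral microbiome > salivary > dietary.

The raw score of a sample is oral / (oral + contaminant), with
oral = oral microbiome + salivary and contaminant = common + lab. Dietary
and unclassified PSMs sit in neither numerator nor denominator: the score
asks whether the *background* proteome looks oral, and dietary evidence
should neither reward nor penalise it. A sample with no oral or contaminant
PSMs at all scores 0 with a warning.

Raw scores are min-max normalised across all samples processed in one
invocation, and a sample passes at a normalised score of at least 0.5
(inclusive — the threshold is stated as the value to *pass*). Two degenerate
cases are handled explicitly: a single-sample batch and an all-equal batch
have no range, so every normalised score is set to the midpoint 0.5 and a
loud warning is emitted; with the inclusive threshold such batches pass
rather than silently failing, and the warning directs the analyst to the
per-sample category counts that replace visual inspection.

When two samples from the same individual both pass, they are merged under a
hyphenated id joining the sorted constituent ids ("220-221") and the batch
is re-filtered, re-scored, re-normalised and re-thresholded. The merge
concatenates the already-extracted PSM lists; the original workflow re-runs
the database search on merged raw data, which is out of scope here, so this
is a documented approximation. A failing replicate never joins a merge.

# Bulk deamidation

Asparagine and glutamine deamidate spontaneously over archaeological time
(N→D, Q→E, +0.984 Da), so ancient endogenous proteins should be heavily
deamidated while modern contaminants should not. For every PSM the N and Q
residue instances are counted, an instance being deamidated when a
`Deamidated` modification sits at its position; instances are summed per
protein (each PSM contributing once, so abundant peptides weigh more, as in
any bulk estimate), and rates are reported per residue and pooled
(`rate_total`). The protein is the comparison unit — per-sample rates are
available for reporting.

The contaminant group (common + lab) is compared against the endogenous
group (oral microbiome + salivary + dietary) with a two-sided Wilcoxon
rank-sum test — exact when both groups have at most 12 units and no ties,
normal approximation with tie correction otherwise. Two-sided because no
direction is assumed a priori, even though the expected pattern in an
authentic sample is endogenous ≫ contaminant.

Only proteins with at least `min_sites = 10` observed N + Q sites enter the
test. This is an estimator-validity requirement, not a tuning knob: a rate
estimated from a handful of sites is almost always exactly 0, so when one
group systematically has fewer sites per protein than the other, a rank
test detects the difference in *site counts*, not in deamidation. In
simulations with identical per-site probabilities in both groups the
unfiltered test is spuriously significant; with the threshold it is not,
while the genuine contrast (endogenous N ≈ 0.5 vs contaminant ≈ 0.05)
remains significant at any threshold.

# Spectral validation of dietary PSMs

Dietary identifications with an ion score below 40 are re-examined against
a predicted fragment spectrum. The observed spectrum is first stripped of
the precursor peak (±1.0 m/z by default — wide enough to cover the isotope
envelope at charge ≥ 2; the width is configurable). For every predicted b/y
ion the observed intensity is the largest peak within ±0.01 Da (matching
the upstream fragment tolerance), zero if none; the Pearson correlation
between predicted and observed intensity vectors over *all* predicted ions
is the validation score. Raw intensities are correlated; a square-root or
rank transform is a configurable alternative left off by default. The
normalised spectral contrast angle is reported alongside for transparency
but not thresholded. If either vector has zero variance (e.g. an empty
stripped spectrum) the score is undefined and the PSM fails.

The threshold is 0.70, relaxed to 0.60 for PSMs carrying any Oxidation
modification (on methionine or proline): intensity prediction is less
reliable for modified peptides. After spectral exclusions the minimum-PSM
rule is re-applied to dietary proteins, so a protein stranded with a single
surviving PSM loses that PSM too.

The fragment predictor is pluggable. The built-in model generates singly
charged b/y ions (doubly charged too at precursor charge ≥ 2) at
monoisotopic m/z from standard residue masses (proton 1.00728, water
18.01056; modification deltas +57.02146 carbamidomethyl, +15.99491
oxidation, +0.98402 deamidation), with a deterministic intensity model:
y ions weighted 1.5× b ions, a triangular profile peaking at mid-sequence
(floor 0.1), doubly charged ions at 0.3×. These weights encode the
qualitative shape of tryptic HCD spectra (y-dominant, mid-sequence-heavy);
no learned model is bundled or trained. An external predictor — e.g. a
deep-learned intensity model — supplies intensities through the same ion
table, and the validation machinery is unchanged.

# Deamidation-aware taxonomy of milk peptides

Dietary peptides are matched against a packaged milk-protein database by
exact substring matching with I/L equivalence (mass-identical in MS). In
deamidation-aware mode an observed D may additionally align to a database N
and an observed E to a database Q — never the reverse — with the positions
recorded. BLAST-against-nr is deliberately replaced by this local matcher:
for short tryptic milk peptides, substitution matrices and gaps add nothing,
and a packaged database makes the assignment reproducible.

Assignment: a single matched taxon reports as that taxon; multiple taxa
without deamidation dependence collapse to their lowest common ancestor
(LCA) in the packaged taxonomy; an LCA at or above class Mammalia reports
as "unspecific". When the deamidation-free and deamidation-assumed
interpretations support different labels, the label is their alternation —
the classic case is the BLG peptide TPEVDDEALEK, which is either an
unmodified bovine sequence or a deamidated ovine one (N at position 6), and
reports as "Bovinae/Ovis" with `deamidation_dependent = TRUE`. Genus-level
hits within Bovinae roll up to the subfamily (the database does not
distinguish congeners of *Bos*), while *Ovis*, *Capra* and *Equus* are kept
where unique.

Two classes of bacterial homolog are handled by rules: accessions on the
exclusion list (hypothetical proteins attributed to genome-sequencing
contamination of the source assemblies) are dropped outright; accessions
with a reassignment rule (a predicted bacterial lipocalin homologous to
BLG) keep their protein name mapped to the dietary protein but contribute
no taxon evidence, which then rests on the co-matching dietary entries.

For site-level summaries, labels are pooled into display groups that do not
lose specification: "Pecora and Bovidae", "Bovinae and/or Ovis", "Caprinae
and Capra"; other labels (e.g. *Equus*, "unspecific") stand alone.

# The synthetic-data generator

`simulate_study()` draws a multi-sample study with the statistical
structure the analysis assumes, and a truth record sufficient to score every
stage. Defaults are the study conditions, chosen once:

* composition: well-preserved samples draw 80% oral / 15% contaminant / 3%
  dietary PSMs; poorly preserved samples swap the oral and contaminant
  fractions (half the samples by default);
* deamidation: per-residue-instance Bernoulli draws at N 0.5 / Q 0.15 for
  endogenous material and N 0.05 / Q 0.02 for contaminants; in poorly
  preserved samples the apparent oral and dietary matches are themselves
  modern contamination and deamidate at contaminant rates — this is what
  makes the group contrast vanish in the failed subset, as observed in real
  failed calculus proteomes;
* decoys: 1% of PSMs, matching the low post-search FDR range (protein
  0–3.76%, peptide 0–1.16%) reported for authenticated calculus proteomes;
* spectra: low-scoring dietary PSMs are paired with spectra from the
  built-in intensity model under multiplicative log-normal noise (σ = 0.05);
* ion scores: Gaussian (mean 60, sd 10) for confident PSMs; low-scoring
  dietary PSMs uniform on [20, 39].

The generator emulates category composition, deamidation structure, decoy
prevalence and fragment-intensity noise. It does *not* emulate retention
time, isotope envelopes, chimeric spectra, homology between the random
background peptides, or search-engine score correlation — so passing tests
demonstrate the correctness of the inference chain under its stated
assumptions, not performance on real instrument data.

The fixture milk-protein database is synthetic: sequences are
concatenations of designed marker peptides whose sharing pattern across
taxa encodes the assignment structure of real milk proteins
(species-unique, subfamily-, family- and infraorder-conserved peptides, the
deamidation-ambiguous BLG locus, and the two bacterial homolog classes). A
Cervidae BLG entry is included although cervids are not dairy species: a
reference database restricted to dairy taxa could never resolve a peptide
only to Pecora, because the LCA of any set of bovid sequences is at most
Bovidae — mirroring how searches against comprehensive databases hit
homologs of non-dairy pecorans.

`make_inpaper_fixture()` deterministically regenerates a 50-PSM worked
example whose per-individual, per-protein counts reproduce a published
summary table of a two-site study (individuals 143, 151-152, 181-182 at
Bilsk; 192, 203, 220-221 at Mamai-Gora; site totals 27 and 23). The
peptides themselves are fixture-defined (chosen from the fixture proteins),
except the one the source study prints (TPEVDDEALEK).

# Numerical and degenerate-input choices

* Positions are 1-based and intervals closed throughout.
* All thresholds are inclusive (≥ / ≤) unless the excluding condition is
  stated strictly.
* The min-max batch for normalisation is whatever set of samples was
  processed together, recomputed after replicate merging.
* Ties in min-max (all-equal batch) go to 0.5 with a warning, not an error.
* Fragment m/z collisions in simulated spectra are deduplicated before
  constructing the (strictly increasing) peak list.
* A single global seed in the configuration governs every stochastic
  component; reruns with identical inputs are byte-identical, which the
  test suite asserts file by file.

Problem sizes in the test suite (6–8 samples of 150–400 PSMs, 100 spectral
trials, 20–25 random FDR instances) were chosen as the smallest at which
every asserted statistical property is comfortably powered.

# Known limitations

* No protein inference: the primary accession carries all protein-level
  bookkeeping; shared peptides are not re-distributed.
* Replicate merging concatenates extracted PSMs instead of re-searching
  merged raw data.
* The built-in intensity model is deterministic and schematic; validation
  thresholds were defined for learned predictors, so with the built-in
  model the spectral stage is best read as self-consistency screening.
* The packaged taxonomy is a small fixed tree, not NCBI taxonomy.
* The Wilcoxon unit is the protein; if the original analysis pooled at
  another level (peptide, sample), p-values are not directly comparable.
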