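---
title: "Methods: linking exposures to disease mechanisms by GO BP overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking exposures to disease mechanisms by GO BP overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aoplink)
```

## The model

`aoplink` quantifies putative mechanistic connectivity between a chemical
exposure and a respiratory disease as the overlap between two sets of
Gene Ontology Biological Process (GO BP) terms:

* a **disease set**, assembled from expert-curated Adverse Outcome
  Pathway (AOP) events — molecular initiating events (MIEs) and key
  events (KEs) mapped to GO terms and expanded over the ontology — and
  optionally augmented by overrepresentation analysis of disease-gene
  lists;
* an **exposure set**, the GO BP terms enriched in a ranked
  differential-expression profile of cells exposed to the chemical
  *in vitro*.

The working assumption is the one behind AOP thinking generally: if an
exposure transcriptionally activates the same biological programs that
the curated disease mechanism comprises, the overlap supports a
mechanistic hypothesis — it does not prove causation, and an empty
overlap can reflect curation gaps or model-system limitations as much as
true absence of effect.

## Ontology expansion

Curated events name *parent* GO terms; the biological claim extends to
their specialisations. `derive_aop_term_set()` therefore expands each
mapped term to its reflexive transitive descendant closure.

* **Closure, not direct children.** Child lists in curated resources are
  produced by descendant browsing, which is multi-level; a
  direct-children-only mode (`mode = "children"`) is available for
  sensitivity analysis.
* **`is_a` only by default.** `part_of` in the BP namespace can cross
  semantic intent (a part of a process is not necessarily a kind of it);
  traversal of `part_of` is opt-in via `relations`.
* **The parent is a member of its own expansion.** Pre-deduplication
  counts (`raw_count`) are the sum of per-event expansion lengths, so the
  familiar accounting — *N parent + M child terms, K unique after
  removing duplicates* — is reproducible from the result object.
* Obsolete terms are dropped with a warning; `alt_id` accessions resolve
  silently to their canonical term; closures never leave the term's
  namespace.

## Enrichment engines

Two engines cover the two curation-to-enrichment routes.

**Overrepresentation (`ora()`).** One-sided hypergeometric upper-tail
probability of the observed query/term overlap, Benjamini–Hochberg FDR
across tested terms. The default universe is every gene with at least one
BP annotation after true-path propagation — the same universe the term
sets are defined on — and an explicit background can be supplied. Gene
symbols match case-insensitively. The test is conservative
(super-uniform p-values) because of hypergeometric discreteness; the
suite checks an empirical type-I error of at most 0.07 at nominal 0.05.

**Ranked-list GSEA (`gsea()`).** The weighted Kolmogorov–Smirnov running
sum: for a ranked list of N genes and a set with N_h members present,
hits advance the sum by |fc|^p normalised over hit weights, misses
retreat by 1/(N − N_h); the enrichment score (ES) is the deviation of
maximal magnitude, so ES ∈ [−1, 1] always.

* `weight_exponent` p defaults to 1 (the canonical weighted statistic);
  0 gives the classic unweighted variant. If all hit weights are zero
  (degenerate all-zero fold changes) equal weights are used.
* **Null model: gene-set permutation.** Inputs are per-condition
  fold-change lists without sample-level replicates, so phenotype
  permutation is unavailable by construction. For each distinct set size,
  `n_permutations` (default 1000) random same-size gene sets are drawn
  from the ranked genes under a fixed seed. NES divides ES by the mean
  |null ES| of the same sign and size; p-values are one-sided within
  sign; the FDR is the pooled-NES tail-ratio procedure.
* **Selection:** terms with FDR strictly below `fdr_threshold`
  (default 0.25, the conventional exploratory GSEA cut-off) form the
  exposure set — "below" is implemented as `<`, so an FDR of exactly
  0.25 is excluded.
* **Determinism.** Ranking sorts by descending fold change with a
  lexicographic tie-break on gene id (C-locale radix sort); duplicate
  gene ids keep the record of largest |fold change| (probe-collapse
  convention); the collection is processed in sorted term order and the
  permutation stream is seeded, so results are bit-reproducible across
  runs and across input orderings. The permutation inner loop is a small
  C++ routine driven by R's RNG.

A realised-behaviour caveat worth stating: on a GO-like collection the
term sets are nested (true-path propagation), so observed scores are
correlated up the DAG. Ancestors of a genuinely perturbed leaf term
*contain* the perturbed genes and are legitimately flagged, and the
pooled-NES FDR — which compares observed and null NES tail fractions —
can let clusters of correlated moderate scores through. The suite
measures exactly this: planted leaf terms are always recovered at
FDR < 0.25, while the fraction of non-planted terms left unselected sits
near, and in some seed sets just below, 90%, with flagged non-planted
terms dominated by ancestors of the planted leaves.

## Overlap statistics

`jaccard()` implements J(A,B) = |A∩B| / |A∪B| on deduplicated sets
(never multisets): 0 means no overlap, 1 complete overlap, and the
normalisation by the union makes comparisons across conditions with
different set sizes fair. J(∅,∅) is defined as 0 with a warning — the
degenerate case carries no evidence of overlap, and returning 1 would
fabricate "complete" agreement. `go_overlap()` records the full Venn
accounting (with the inclusion–exclusion identity asserted in tests) plus
an optional back-mapping of each intersecting term to the curated
event(s) whose expansion contributes it. `common_signature()` intersects
per-chemical overlaps into a cross-chemical signature with a term ×
chemical membership matrix for UpSet-style reporting. Statistical
significance of overlaps is deliberately not computed: the counts and
Jaccard indices are descriptive, and attaching an overlap p-value would
overstate what the curated sets support.

## Dosimetry comparison

`to_micromolar()` canonicalises concentrations: mM × 1000; µg/mL ×
1000 / molar mass (g/mol); µmol/mmol-creatinine × an assumed urinary
creatinine concentration in mmol/L (the conversion is recorded in a trace
attribute; 14.0 µmol/mmol at 8.2 mmol/L gives 114.8 µmol/L). Air
concentrations in µg/m³ are deliberately *not* convertible: they describe
an external exposure scenario whose translation to internal dose is a
physiologically based kinetic (PBK) model's job, upstream of this
comparator; the packaged table consumes such PBK outputs as plain µM
records. `compare_concentrations()` crosses every in vitro record with
every in vivo record per chemical; chemicals with only qualitative in
vivo evidence (e.g. antigen-specific antibodies) yield a single
fold-absent row with the reason. Report rounding quotes folds ≥ 100 as
integers and smaller folds to one decimal (1739; 18.2; 3.8), with
unrounded values retained alongside.

`vocabulary_coverage()` reports a term set's share of the BP vocabulary
rounded *down* to one decimal, so the quoted share never overstates
coverage (2205 of 27047 terms is quoted as 8.1%).

## What the synthetic data emulate — and what they do not

The generators produce, from a master seed, every input dialect the
pipeline reads: a rooted `is_a` DAG in OBO format (about 15% of terms get
a second parent, so it is a genuine DAG), leaf-level gene annotations,
AOP event tables with controlled term duplication across events, a
contaminated disease gene list, and ranked fold-change tables. Each
generator runs on its own RNG stream (L'Ecuyer-CMRG stream splitting), so
adding one call never perturbs another module's draws, and truth
manifests (descendant counts, propagated gene sets, expected
pre-dedup/unique counts) are computed directly from the edge lists,
independent of the package's own traversal code, so they can serve as
oracles.

Default study conditions: 200 terms, at most 4 children per term, 2000
genes, 5–50 genes per leaf, 5 planted leaf terms of 20–50 genes, an
additive fold-change shift of 1.5 against unit Gaussian noise, 20%
disease-gene contamination. Genes are dealt to leaves from independently
reshuffled decks, which balances coverage (every gene annotated, each to
one or two leaves) and keeps unrelated leaf sets nearly disjoint, so the
planted signal stays identifiable. The additive (not multiplicative)
effect keeps the null symmetric and the power property analytically
predictable; planting at leaves makes the ground truth exactly one term
per planted program, with ancestor enrichment an expected and
interpretable consequence rather than contamination of the truth.

What passing these tests shows is that the machinery recovers planted
signal and controls background at the stated rates *under these
conditions*. Real transcriptomics data differ in ways the generator does
not emulate: gene–gene correlation, heavy-tailed fold changes,
annotation incompleteness and bias, and much deeper ontologies. Recovery
rates on synthetic data are therefore upper bounds, not predictions, for
real studies.

## Problem sizes and numerical choices

The test suite runs the full default conditions (2000 genes, 200 terms,
1000 permutations) across ten seeds for the recovery and null-calibration
properties, and smaller instances (40–120 terms, 200–800 genes, 150–200
permutations) for end-to-end workflow, determinism and report checks.
Oracle equivalences are asserted to 1e-12 (hypergeometric vs exhaustive
enumeration of all draws; running sums vs an element-by-element loop),
with one documented exception: under the unweighted statistic the
positive and negative running-sum extrema can tie exactly, and the
reported sign then rests on floating-point noise, so tied cases compare
magnitudes only. Unit round-trips hold to 1e-9 relative. Report files are
byte-identical across reruns of the same configuration and seed.

## Known limitations

* The curated event tables are inputs; the expert curation itself, and
  lookups against live AOP/annotation services, are out of scope — the
  package never touches the network.
* Enrichment FDR control on nested GO collections is approximate (see
  the realised-behaviour caveat above); interpret borderline terms, and
  especially ancestors of strong hits, accordingly.
* The dosimetry comparator consumes PBK outputs; it does not simulate
  kinetics, and creatinine-normalised urinary conversions inherit the
  uncertainty of the assumed urinary creatinine concentration.
* Overlap counts are descriptive; no inferential claim is attached.
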