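---
title: "From protein similarity networks to environmental biogeography: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From protein similarity networks to environmental biogeography: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pfcbiogeo implements an inference chain for ocean (or any environmental)
metagenomics that starts from a catalog of predicted proteins binned into
metagenome-assembled genomes (MAGs) and ends at a constrained ordination of
protein families along environmental gradients. This vignette documents the
statistical models, the tunable parameters and their defaults, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## Sequence similarity network and protein functional clusters

A sequence similarity network (SSN) has proteins as nodes and an edge
between two proteins when their pairwise alignment reaches both a percent
identity threshold and a coverage threshold. The defaults are the
widely used 80/80 rule (`id_threshold = 80`, `cov_threshold = 80`, both in
percent). Three choices here were genuinely open and are worth making
explicit:

* **Coverage side.** "80% coverage" does not say whether the query's or the
  subject's span is constrained. `filter_hits()` defaults to the
  conservative *mutual coverage* rule (`min(cov_query, cov_subject) >=
  threshold`), the common reading in SSN studies, with
  `coverage_mode = "query"` and `"either"` available for sensitivity
  analysis.
* **Inclusive comparisons.** Thresholds are compared with `>=`, so a hit at
  exactly 80/80/80 creates an edge.
* **Multiple hits per pair.** Tabular searches often report reciprocal and
  duplicate hits; `read_hits()` collapses each unordered pair to a single
  hit keeping the maximum percent identity before any filtering.

Protein functional clusters (PFCs) are the connected components of the SSN
with at least two members; all remaining proteins are singletons and take no
further part in the analysis. Cluster numbering is deterministic: clusters
are sorted by their lexicographically smallest member ID and numbered from
1. The partition property (clusters plus singletons tile the catalog
exactly) is asserted on every extraction.

For desk-scale catalogs without an external all-vs-all search,
`align_pair()`/`all_vs_all_hits()` provide Smith–Waterman local alignment
(BLOSUM62, affine gap open 11 / extend 1, the BLAST-style convention where a
gap of length L costs 11 + L). Percent identity is identities over alignment
columns; coverage is each side's aligned span over its full length.

## Functional homogeneity, taxonomy, and dark clusters

For a cluster of `N_prot` proteins carrying `N_annot` unique annotation
terms in a database (KEGG orthologs or eggNOG descriptions):

* `N_annot = 0` → the score is *missing* (the cluster is unannotated in
  that database);
* `N_annot = 1` → score 1 (perfect homogeneity);
* otherwise → score `1 - N_annot / N_prot`, floored at 0.

Two conventions had to be fixed because the formula alone does not: `N_prot`
counts **all** members, annotated or not (the cluster size is the natural
denominator, and unannotated members genuinely dilute homogeneity), and a
protein carrying several terms contributes all of them to `N_annot`, which
is why the floor at 0 is needed to keep the score in [0, 1]. Clusters whose
scores fall below 0.8 (or 0.5) in *both* databases are tagged `low_08`
(`low_05`) but never excluded — eggNOG descriptions in particular can
fragment one function into several spellings, so a low score is a flag, not
a verdict.

Taxonomy is summarized per rank (phylum to genus): a cluster is
single-taxon at a rank when all members annotated at that rank agree, and
the summary is missing when no member is annotated there. A cluster is
**dark** when it has no functional annotation in either database *and* no
member taxonomy below phylum. `dark_abundance_test()` compares dark versus
all other clusters per sample with a two-sided Wilcoxon rank-sum test;
samples whose values are all identical are reported with p = 1 and flagged
rather than dropped.

## Abundance normalization

Raw per-gene read counts are normalized as

```
abundance[g, s] = count[g, s] / (length_nt[g] * total_reads[s]) * scale
```

with `scale = 1e9` by default. This is TPM-like, but the per-sample
denominator is the **total sequenced reads (mapped + unmapped)**, not the
mapped total: environmental samples differ enormously in how much of their
sequencing effort maps to any given gene catalog, and dividing by mapped
reads alone would inflate poorly-mapping samples. Gene lengths are in
nucleotides; using amino-acid lengths would silently change results by a
factor of ~3, so the unit is part of the contract. The scale is a parameter
so that either power-of-ten reading of a "×10⁹-style" constant is
reproducible; it cancels from every downstream analysis that is invariant
to global rescaling (the random-forest ranks and the ordination are).
A PFC's abundance in a sample is the arithmetic mean of its members'
abundances.

## Environmental table curation

`prepare_env()` applies, in order: near-zero-variance filtering,
correlation filtering, scaling/centering, then k-nearest-neighbour
imputation. Near-zero variance uses the conjunctive rule (see below).
Correlation filtering greedily resolves quantitative pairs with |Pearson r|
above `corr_cut` (default 0.90, the conventional default of the caret
preprocessing this mirrors), dropping the member with the larger mean
absolute correlation to everything else; qualitative variables are exempt.
Scaling uses observed entries only (n−1 denominator). Imputation replaces
each missing cell by the mean of the variable over the `k = 5` nearest
samples where it is observed, with inter-sample distance defined as
Euclidean distance over the quantitative variables observed in both
samples, normalized by the number of shared variables. Qualitative
variables do not enter the distance — there is no principled common scale
for mixing them with standardized quantitative ones, and the imputation
only ever fills quantitative cells. Distance ties are broken by sample
order, making imputation deterministic. Imputed values are means of
observed values, hence always inside the observed range.

## Random-forest screening

Before modelling, cluster abundance profiles with near-zero variance are
removed by `nzv_flag()`: flagged when the percentage of distinct values is
below `unique_cut = 10` **and** the frequency ratio of the most common to
the second most common value exceeds `freq_cut = 95/5 = 19`. The
conjunction is the standard tool behaviour; a disjunctive reading exists in
the field's prose descriptions, so the operator exposes `mode = "either"`,
but the conjunctive default is what `screen_pfcs()` uses.

Each surviving cluster's abundance vector is regressed on the prepared
environmental table with the following protocol (`screen_config()`
defaults):

* 10 repeats, each on a fresh train/test split with 75% training
  (`ceiling`, so 93 samples give 70);
* within each training set, `mtry` tuned over 5..9 by 5-fold
  cross-validation minimizing out-of-fold RMSE (ties to the smallest
  `mtry`); the default `mtry` of the underlying forest would be
  `floor(sqrt(p))`, e.g. 7 at 52 predictors, which sits mid-grid;
* 500 trees per forest; the winner is refit on the full training set and
  evaluated on the held-out 25%;
* R² is the squared Pearson correlation between predictions and
  observations (the convention of the caret-style training frameworks this
  protocol mirrors; `r2_method = "sst"` switches to 1 − SSE/SST);
* variable importance is the forest's permutation importance (unscaled
  %IncMSE, computed on out-of-bag samples of the refit), converted to ranks
  1..v with ties broken by variable order.

All quantities are averaged over repeats. A repeat with a constant training
response contributes R² = 0 and is counted in `n_degenerate_repeats`.
Classification is strict: mean cross-validated R² over 0.5 → `hle`
("highly linked to environment"), over 0.25 → `linked`, else `none`.
Factor predictors are passed to the forest natively as categoricals (the
randomForest backend supports up to 53 levels), not one-hot encoded; the
choice is visible in the importance table, which has one row per variable.

The test suite exercises this screen at a scaled-down setting (3 repeats,
100 trees, 40 clusters, 93 samples, 14 predictors) chosen so the
calibration properties — at least 90% of planted signal-to-noise-3 clusters
reaching `hle`, no pure-noise cluster reaching 0.5 and at most 2 of 20
reaching 0.25 — are informative while the whole suite stays fast; the
exported defaults remain the full 10×500 protocol.

## Constrained correspondence analysis

`fit_cca()` implements the canonical CCA triplet: chi-square
standardization of the response table (`Q = (P - r cᵀ) / sqrt(r cᵀ)` with
row/column masses `r`, `c`), row-mass-weighted projection of `Q` onto the
span of the centered constraint matrix, and SVD of the fitted part.
Eigenvalues are squared singular values; their sum is the constrained
inertia and `sum(Q²)` the total. Qualitative constraints are one-hot
encoded with the reference level dropped; linearly dependent columns are
removed with a warning. Scores default to species-focused scaling
(scaling 2: feature scores carry the singular values, site scores are the
unscaled linear combinations), with `scaling = 1` available. Because SVD
signs are arbitrary, each axis is oriented so its largest-magnitude biplot
score is positive, which makes outputs comparable across runs and
platforms.

Significance is assessed by permuting sample rows of the constraint table:
`p = (1 + #{permuted ratio >= observed}) / (1 + n_perm)` on the
constrained-to-total inertia ratio, so the smallest attainable p with 999
permutations is 1/1000. Variable selection is a bidirectional greedy search
(forward then backward per sweep) on an AIC analogue for constrained
ordination, `n·log(residual_inertia / n) + 2(k + 1)` with `k` the number of
fitted constraint columns. No single AIC definition is standard for
ordination, so the formula is fixed and documented here for
reproducibility; ties break by variable order, making selection
deterministic. Group barycenters (e.g. per KEGG pathway or per phylum) are
per-axis means of member feature scores with (n−1) standard deviations;
groups below `min_size = 10` members are flagged, never dropped.

## The synthetic-data generator

`simulate_dataset()` produces every input the pipeline consumes, with
planted ground truth:

* **Catalogs** grow each homology family from a random root (80–400 aa) by
  point substitutions at a controlled per-site rate. Substitutions only —
  no indels — so within-family coverage stays at 100% and the identity
  threshold is the active margin when testing the 80/80 rule. Dark
  clusters are planted by leaving designated families unannotated and
  sourcing them from MAGs whose taxonomy is truncated at phylum.
  Annotation rates default to 0.5 (KEGG) and 0.85 (eggNOG), the sparse
  regime typical of environmental catalogs.
* **Environment tables** are Gaussian with requested pairwise correlations
  (Cholesky construction), uniform qualitative variables (default level
  counts 8/4/3/2, emulating province, ocean region, season moment, and
  depth layer), and completely-at-random missingness at 6.6% by default.
  The default sample count is 93 — deliberately the "under 100 samples"
  regime in which this screening approach is meant to operate.
* **Abundances** are log-linear in a quantitative driver (or carry
  per-level offsets of a qualitative driver) with log-scale Gaussian
  noise; pure-noise and near-constant roles are available, the latter
  constructed (one perturbed sample) to fail the near-zero-variance filter
  for any n ≥ 21. The cluster target is spread over member proteins by a
  fixed multiplicative jitter normalized to mean 1, so the cluster mean
  recovers the target exactly and, with noise off, equals the specified
  function of the driver to machine precision.
* **Counts** invert the normalization formula exactly, with optional
  Poisson resampling.

What the generator does **not** emulate: realistic oceanographic
covariance structure, phylogenetically realistic sequence evolution,
compositionality of real read counts, or spatially structured missingness.
Passing the calibration suites therefore shows the machinery is correct and
well calibrated under its stated model, not that any particular real
data set will yield predictable clusters.

## Worked example

```{r, eval = FALSE}
library(pfcbiogeo)
cfg <- pipeline_config(
  outdir = "pfc_out", seed = 42,
  simulate = list(n_families = 45, n_samples = 93,
                  n_linked = 20, n_noise = 20, n_near_constant = 5,
                  n_dark_families = 4),
  screen = screen_config(n_repeats = 3, n_trees = 100))
res <- run_pipeline(cfg)
table(res$screen$results$category)
res$ordination$perm$p_value
```

## Numerical choices and limitations

* All randomness flows from one master seed through a stage-name hash
  (`screen/<cluster>`, `ordination`, ...), so stages are independently
  reproducible and two runs with the same config are byte-identical.
* Rank-deficient constraint matrices are handled by QR with column
  dropping; SVD components are kept above a tolerance scaled to the
  largest singular value.
* The Wilcoxon comparison uses the exact null distribution for small
  tie-free groups and the tie-corrected normal approximation otherwise
  (the behaviour of `stats::wilcox.test`).
* The screen is O(repeats × folds × |mtry grid|) forest fits per cluster:
  the full default protocol on hundreds of thousands of clusters is a
  compute-cluster job, not a laptop one. The package parallelizes nothing
  internally; callers can shard clusters across workers since each cluster
  is seeded independently.
* Near-zero-variance flagging of a qualitative variable uses its level
  frequencies; for quantitative variables with measurement noise the
  unique-percentage condition is rarely met, which is by design (the
  filter targets degenerate, not merely skewed, profiles).
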