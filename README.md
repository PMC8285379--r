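# pfcbiogeo

Environmental metagenomics yields millions of predicted proteins, most of
them functionally unannotated. `pfcbiogeo` groups such proteins into
**protein functional clusters (PFCs)** — connected components of a sequence
similarity network — and asks, for each cluster, whether its abundance
across samples can be predicted from the environmental context, regardless
of whether anyone knows what the cluster does. That makes it possible to
map the biogeography of "microbial dark matter": clusters with no KEGG or
eggNOG annotation and no taxonomy below phylum behave like first-class
citizens throughout.

The chain, end to end:

1. **SSN → PFCs.** An edge joins proteins with pairwise identity ≥ 80% and
   coverage ≥ 80% (mutual coverage by default; both thresholds
   configurable). Connected components with ≥ 2 members are the PFCs.
2. **Scoring.** Per cluster, the functional homogeneity score
   `F_hom = 1 − N_annot / N_prot` (with `F_hom = 1` when a single unique
   term is shared, missing when no member is annotated), per-rank taxonomy
   homogeneity, and the dark flag. Dark vs non-dark abundances are compared
   per sample with a two-sided Wilcoxon rank-sum test.
3. **Quantification.** TPM-like normalization against *total sequenced
   reads*: `abundance = count / (gene_length_nt × total_reads) × 10⁹`;
   cluster abundance is the member mean.
4. **Environment preparation.** Near-zero-variance and |r| > 0.9
   correlation filtering, scaling/centering, k = 5 nearest-neighbour
   imputation.
5. **Screening.** Per cluster, repeated random-forest regression of
   abundance on the environment: 10 repeats of 75/25 train/test splits,
   mtry tuned over 5..9 by 5-fold CV minimizing RMSE, 500 trees; clusters
   with mean CV R² > 0.5 are *hlePFCs* (highly linked to environment),
   > 0.25 *linked*. Variable importance is aggregated as mean permutation-
   importance ranks.
6. **Biogeography.** Canonical correspondence analysis of the linked
   clusters' abundances constrained by the environment, with permutation
   significance, bidirectional AIC stepwise variable selection, and group
   barycenters (per pathway, per phylum, ...).

A synthetic-data generator (`simulate_dataset()`) produces every input with
planted ground truth — homology families at controlled divergence, planted
dark clusters, environment tables with correlated variables and missing
cells, and cluster abundances that are log-linear in planted drivers — so
the whole chain is testable without any external download.

## Worked example

```r
library(pfcbiogeo)

cfg <- pipeline_config(
  outdir = "pfc_out", seed = 42,
  simulate = list(n_families = 12, family_size_range = c(2, 4),
                  divergence = 0.03, n_dark_families = 2,
                  n_samples = 40, n_quant = 8, n_qual = 2,
                  missing_fraction = 0.05,
                  n_linked = 5, n_noise = 4, n_near_constant = 1),
  screen = screen_config(n_repeats = 3, n_trees = 100),
  n_perm = 199)
res <- run_pipeline(cfg)

length(res$ssn$partition$clusters)   # 12  — all planted families recovered
sum(res$scores$is_dark)              # 2   — both planted dark clusters found
table(res$screen$results$category)
#>    hle linked   none
#>      2      3      6
res$ordination$perm$p_value          # 0.005 — smallest attainable at 199 perms
round(res$ordination$fit$eigenvalues, 4)
#>   CCA1   CCA2   CCA3   CCA4
#> 0.3087 0.2356 0.0529 0.0110
```

Reading this: the similarity network at 80/80 recovers the 12 planted
homology families exactly (no singletons); the two families planted with no
annotation and phylum-only taxonomy are classified dark; the random-forest
screen separates environment-driven clusters from noise ones (at this small
sample size and a scaled-down 3×100 protocol, 2 of the 5 planted clusters
clear the strict 0.5 threshold and 3 more the 0.25 threshold, while noise
and near-constant clusters land in `none` or are removed by the variance
filter); and the ordination of the linked clusters against the environment
is as significant as 199 permutations can certify, with its first axis
carrying 0.3087 / (0.3087+0.2356+0.0529+0.0110) ≈ 51% of the constrained
inertia. Every output table is also written as TSV under `outdir`.

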