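test_that("catalog generation is seed-deterministic with exact families at divergence 0", {
  g1 <- generate_catalog(n_families = 5, family_size_range = c(2, 4),
                         divergence = 0, seed = 3)
  g2 <- generate_catalog(n_families = 5, family_size_range = c(2, 4),
                         divergence = 0, seed = 3)
  expect_identical(g1$catalog$sequence, g2$catalog$sequence)
  expect_identical(g1$truth, g2$truth)
  # divergence 0: all family members identical
  for (fam in g1$truth$planted_families) {
    seqs <- g1$catalog$sequence[match(fam, g1$catalog$protein_id)]
    expect_equal(length(unique(seqs)), 1)
  }
})

test_that("dark families come from phylum-only MAGs and are unannotated", {
  g <- generate_catalog(n_families = 6, family_size_range = c(2, 3),
                        divergence = 0.02, n_dark_families = 2,
                        n_phylum_only_mags = 3, seed = 13)
  for (fam in g$truth$planted_dark) {
    ids <- g$truth$planted_families[[fam]]
    rows <- match(ids, g$catalog$protein_id)
    expect_true(all(lengths(g$catalog$kegg_ids[rows]) == 0))
    expect_true(all(lengths(g$catalog$eggnog_terms[rows]) == 0))
    mags <- g$catalog$mag_id[rows]
    tx <- g$taxonomy[match(mags, g$taxonomy$mag_id), ]
    expect_true(all(tx$class == "unannotated"))
  }
})

test_that("environmental generator honours correlations, levels, and missingness", {
  env0 <- generate_env(n_samples = 50, n_quant = 4, n_qual = 1,
                       missing_fraction = 0, seed = 5)
  expect_false(anyNA(as.data.frame(env0)))

  envc <- generate_env(n_samples = 500, n_quant = 4, n_qual = 0,
                       corr_pairs = data.frame(i = 1, j = 2, r = 0.95),
                       missing_fraction = 0, seed = 6)
  expect_equal(cor(envc$q01, envc$q02), 0.95, tolerance = 0.05)

  envq <- generate_env(n_samples = 120, n_quant = 2, n_qual = 1,
                       qual_levels = 4L, missing_fraction = 0, seed = 7)
  expect_equal(nlevels(droplevels(envq$f01)), 4)

  envm <- generate_env(n_samples = 93, n_quant = 10, n_qual = 2,
                       missing_fraction = 0.066, seed = 8)
  frac <- mean(is.na(as.matrix(as.data.frame(envm)[
    is_quantitative(envm)])))
  expect_lt(abs(frac - 0.066), 0.02)

  expect_error(generate_env(n_quant = 2,
                            corr_pairs = data.frame(i = 1, j = 2, r = 1.5),
                            seed = 1),
               "positive definite")
})

test_that("planted abundances follow their role specs", {
  env <- generate_env(n_samples = 93, n_quant = 4, n_qual = 1,
                      missing_fraction = 0, seed = 9)
  part <- tiny_partition(list(A = c("p1", "p2"), B = c("p3", "p4"),
                              C = c("p5", "p6")))
  spec <- list(A = list(type = "linked", driver = "q01", effect = 1,
                        noise_sd = 0),
               B = list(type = "noise", noise_sd = 0.5),
               C = list(type = "near_constant"))
  ab <- generate_abundances(part, env, spec, seed = 10)
  # noiseless link: the cluster mean IS the specified function
  z <- as.numeric(scale(env$q01))
  expect_equal(unname(ab$cluster_target["A", ]), 10 * exp(z),
               tolerance = 1e-12)
  pa <- pfc_abundance(ab$protein_abundance, part)
  expect_equal(unname(pa["A", ]), 10 * exp(z), tolerance = 1e-10)
  # near-constant clusters fail the variance filter by construction
  expect_true(nzv_flag(ab$cluster_target["C", ]))
  # unknown driver is an error
  bad <- spec; bad$A$driver <- "nope"
  expect_error(generate_abundances(part, env, bad, seed = 1), "absent")
})

test_that("a snr-3 linked cluster correlates strongly with its driver", {
  env <- generate_env(n_samples = 93, n_quant = 4, n_qual = 0,
                      missing_fraction = 0, seed = 11)
  part <- tiny_partition(list(A = c("p1", "p2")))
  spec <- list(A = list(type = "linked", driver = "q01", effect = 0.6,
                        noise_sd = 0.2))
  ab <- generate_abundances(part, env, spec, seed = 12)
  expect_gt(abs(cor(ab$cluster_target["A", ], env$q01)), 0.8)
})

test_that("count generation inverts normalization exactly when noise is off", {
  set.seed(13)
  A <- matrix(rexp(20, 0.1), 4, 5,
              dimnames = list(sprintf("g%d", 1:4), sprintf("s%d", 1:5)))
  ct <- generate_counts(A, seed = 14)
  expect_equal(normalize_counts(ct), A, tolerance = 1e-12)
  # zero abundance -> zero count, noise or not
  A0 <- A; A0[1, ] <- 0
  ctp <- generate_counts(A0, poisson_noise = TRUE, seed = 15)
  expect_true(all(ctp$counts[1, ] == 0))
})

test_that("poisson counts concentrate around their expectation", {
  A <- matrix(1, 50, 20,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:20)))
  lengths <- setNames(rep(1000, 50), rownames(A))
  totals <- setNames(rep(1e9, 20), colnames(A))
  # expectation = 1 * 1000 * 1e9 / 1e9 = 1000 reads per cell
  ct <- generate_counts(A, lengths, totals, scale = 1e9,
                        poisson_noise = TRUE, seed = 16)
  # expectation 1000 per cell; +-10% for ~99% of cells
  frac_close <- mean(abs(ct$counts - 1000) <= 100)
  expect_gte(frac_close, 0.98)
})

test_that("the bundled simulator is deterministic and internally consistent", {
  s1 <- simulate_dataset(n_families = 8, n_linked = 3, n_noise = 3,
                         n_near_constant = 1, n_dark_families = 1,
                         n_samples = 25, seed = 17)
  s2 <- simulate_dataset(n_families = 8, n_linked = 3, n_noise = 3,
                         n_near_constant = 1, n_dark_families = 1,
                         n_samples = 25, seed = 17)
  expect_identical(s1$catalog$sequence, s2$catalog$sequence)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(as.data.frame(s1$env), as.data.frame(s2$env))
  # every cluster has a role
  expect_setequal(names(s1$truth$link_spec),
                  names(s1$truth$planted_families))
})
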