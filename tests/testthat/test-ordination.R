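mk_Y <- function(n, m, seed = 1) {
  set.seed(seed)
  Y <- matrix(rpois(n * m, 20) + 1, n, m,
              dimnames = list(sprintf("S%02d", 1:n), sprintf("F%02d", 1:m)))
  Y
}

test_that("a saturated constraint set explains all inertia", {
  Y <- mk_Y(6, 5)
  X <- env_table(data.frame(id = factor(rownames(Y)),
                            row.names = rownames(Y)))
  fit <- fit_cca(Y, X)
  expect_equal(fit$constrained_inertia, fit$total_inertia,
               tolerance = 1e-10)
})

test_that("eigenvalues and scores match the explicit eigenproblem oracle", {
  Y <- mk_Y(6, 5, seed = 4)
  X <- env_table(data.frame(x1 = c(1, 2, 3, 4, 5, 6) + rnorm(6, 0, 0.1),
                            x2 = c(2, 1, 4, 3, 6, 5),
                            row.names = rownames(Y)))
  fit <- fit_cca(Y, X)
  orc <- cca_oracle(Y, X)
  expect_equal(as.numeric(fit$eigenvalues),
               orc$eigenvalues[seq_along(fit$eigenvalues)],
               tolerance = 1e-8)
  expect_equal(fit$total_inertia, orc$total_inertia, tolerance = 1e-10)
  expect_equal(fit$constrained_inertia, orc$constrained_inertia,
               tolerance = 1e-10)
  # feature scores match the oracle's eigenvectors up to axis sign
  d <- sqrt(orc$eigenvalues)
  feat_orc <- orc$vectors / sqrt(orc$col_mass)
  feat_orc <- sweep(feat_orc, 2, d, "*")          # species scaling
  expect_equal(abs(unname(fit$feature_scores)), abs(feat_orc),
               tolerance = 1e-8)
})

test_that("eigenvalue invariants hold and sample relabeling is neutral", {
  for (seed in c(2, 9, 33)) {
    Y <- mk_Y(8, 7, seed)
    set.seed(seed + 100)
    X <- env_table(data.frame(a = rnorm(8), b = rnorm(8),
                              g = factor(sample(c("u", "v"), 8, TRUE)),
                              row.names = rownames(Y)))
    fit <- fit_cca(Y, X)
    ev <- as.numeric(fit$eigenvalues)
    expect_true(all(ev >= 0))
    expect_true(all(diff(ev) <= 1e-12))
    expect_equal(sum(ev), fit$constrained_inertia, tolerance = 1e-10)
    expect_lte(fit$constrained_inertia, fit$total_inertia + 1e-12)
    # consistent relabeling of samples leaves eigenvalues unchanged
    perm <- sample(nrow(Y))
    fit2 <- fit_cca(Y[perm, ], X[perm, , drop = FALSE])
    expect_equal(as.numeric(fit2$eigenvalues), ev, tolerance = 1e-10)
  }
})

test_that("eigenvalues agree with an independent CCA implementation", {
  skip_if_not_installed("vegan")
  Y <- mk_Y(10, 8, seed = 6)
  set.seed(7)
  X <- data.frame(a = rnorm(10), b = rnorm(10), row.names = rownames(Y))
  fit <- fit_cca(Y, env_table(X))
  vfit <- vegan::cca(Y ~ a + b, data = X)
  expect_equal(as.numeric(fit$eigenvalues),
               as.numeric(vfit$CCA$eig), tolerance = 1e-10)
  expect_equal(fit$total_inertia, vfit$tot.chi, tolerance = 1e-10)
})

test_that("a planted gradient dominates the first axis' biplot scores", {
  set.seed(15)
  n <- 20
  v <- sort(rnorm(n))
  decoys <- matrix(rnorm(n * 3), n, 3)
  Y <- t(vapply(1:10, function(j) exp((j / 5 - 1) * v) * 50,
                numeric(n)))
  Y <- t(Y)
  dimnames(Y) <- list(sprintf("S%02d", 1:n), sprintf("F%02d", 1:10))
  X <- env_table(data.frame(v = v, d1 = decoys[, 1], d2 = decoys[, 2],
                            d3 = decoys[, 3],
                            row.names = rownames(Y)))
  fit <- fit_cca(Y, X)
  b1 <- abs(fit$biplot_scores[, 1])
  expect_equal(names(which.max(b1)), "v")
  # sign convention: the dominant loading is positive
  expect_gt(fit$biplot_scores[which.max(b1), 1], 0)
})

test_that("degenerate ordination inputs are rejected or repaired", {
  Y <- mk_Y(6, 5)
  Y[, 3] <- 0
  X <- env_table(data.frame(a = rnorm(6), row.names = rownames(Y)))
  expect_error(fit_cca(Y, X), "zero-sum feature")
  Y2 <- mk_Y(6, 5)
  X2 <- env_table(data.frame(a = 1:6, b = (1:6) * 2,
                             row.names = rownames(Y2)))
  expect_warning(fit_cca(Y2, X2), "dependent")
})

test_that("permutation p-values: formula floor, planted signal, null calibration", {
  # minimum attainable p
  Y <- mk_Y(8, 6, seed = 5)
  set.seed(6)
  X <- env_table(data.frame(a = rnorm(8), row.names = rownames(Y)))
  pt <- cca_permutation_test(Y, X, n_perm = 999, seed = 3)
  expect_gte(pt$p_value, 1 / 1000)
  expect_error(cca_permutation_test(Y, X, n_perm = 0), "n_perm")

  # planted strong gradient
  set.seed(25)
  n <- 24
  v <- seq(-2, 2, length.out = n)
  Yg <- t(vapply(1:8, function(j) exp((j / 4 - 1) * v) * 40, numeric(n)))
  Yg <- t(Yg)
  dimnames(Yg) <- list(sprintf("S%02d", 1:n), sprintf("F%02d", 1:8))
  Xg <- env_table(data.frame(v = v, row.names = rownames(Yg)))
  expect_lte(cca_permutation_test(Yg, Xg, 199, seed = 8)$p_value, 0.005)
})

test_that("stepwise selection finds the driver and is a fixed point", {
  set.seed(31)
  n <- 30
  v <- rnorm(n)
  Y <- t(vapply(1:12, function(j) exp((j / 6 - 1) * v) * 30, numeric(n)))
  Y <- t(Y)
  dimnames(Y) <- list(sprintf("S%02d", 1:n), sprintf("F%02d", 1:12))
  X <- env_table(data.frame(v = v,
                            n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                            n4 = rnorm(n), n5 = rnorm(n),
                            row.names = rownames(Y)))
  sw <- cca_stepwise(Y, X)
  expect_true("v" %in% sw$selected)
  # rerunning from the converged set changes nothing
  sw2 <- cca_stepwise(Y, X[, sw$selected, drop = FALSE])
  expect_setequal(sw2$selected, sw$selected)

  # empty-model criterion matches the formula with k = 0
  std_Q <- local({
    P <- Y / sum(Y); r <- rowSums(P); cc <- colSums(P)
    (P - outer(r, cc)) / sqrt(outer(r, cc))
  })
  expect_equal(sw$trace$aic[1],
               n * log(sum(std_Q^2) / n) + 2, tolerance = 1e-10)
})

test_that("group barycenters equal per-group loop means and sds", {
  fs <- matrix(c(0.5, -1.0,
                 0, 0,
                 2, 2), 3, 2, byrow = TRUE,
               dimnames = list(c("f1", "f2", "f3"), c("CCA1", "CCA2")))
  bc <- group_barycenters(fs, list(single = "f1", pair = c("f2", "f3")),
                          min_size = 10)
  expect_equal(bc$mean_CCA1, c(0.5, 1))
  expect_equal(bc$mean_CCA2, c(-1, 1))
  expect_equal(bc$sd_CCA1, c(0, sd(c(0, 2))))
  expect_true(all(bc$small_group))

  set.seed(44)
  big <- matrix(rnorm(300), 100, 3,
                dimnames = list(sprintf("f%03d", 1:100),
                                paste0("CCA", 1:3)))
  groups <- replicate(100, sample(rownames(big), sample(1:8, 1)),
                      simplify = FALSE)
  names(groups) <- sprintf("g%03d", 1:100)
  bc2 <- group_barycenters(big, groups)
  for (k in sample(100, 20)) {
    g <- groups[[k]]
    expect_equal(bc2$mean_CCA2[k], mean(big[g, 2]), tolerance = 1e-12)
    if (length(g) > 1)
      expect_equal(bc2$sd_CCA3[k], sd(big[g, 3]), tolerance = 1e-12)
  }
  # the grand barycenter equals the column means of the score matrix
  all_bc <- group_barycenters(big, list(all = rownames(big)))
  expect_equal(c(all_bc$mean_CCA1, all_bc$mean_CCA2, all_bc$mean_CCA3),
               unname(colMeans(big)), tolerance = 1e-12)
  expect_error(group_barycenters(big, list(bad = "nope")), "unknown feature")
})
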