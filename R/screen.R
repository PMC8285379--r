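#' Near-zero-variance flag for an abundance (or any) vector
#'
#' In the default conjunctive mode a vector is flagged when BOTH hold:
#' the percentage of distinct values is below `unique_cut`, and the ratio
#' of the most common value's frequency to the second most common one's
#' exceeds `freq_cut`.  A vector with a single distinct value is always
#' flagged.  `mode = "either"` flags when either condition holds, for
#' sensitivity analysis.
#'
#' @param values vector of >= 2 values.
#' @param freq_cut frequency ratio cutoff (default 95/5 = 19).
#' @param unique_cut percent-unique cutoff (default 10).
#' @param mode `"both"` (conjunction, default) or `"either"`.
#' @return logical.
#' @export
nzv_flag <- function(values, freq_cut = 95 / 5, unique_cut = 10,
                     mode = c("both", "either")) {
  mode <- match.arg(mode)
  if (length(values) < 2) stop("need at least 2 values")
  tab <- sort(table(values), decreasing = TRUE)
  if (length(tab) == 1) return(TRUE)
  freq_ratio <- as.numeric(tab[1]) / as.numeric(tab[2])
  unique_pct <- length(tab) / length(values) * 100
  if (mode == "both") freq_ratio > freq_cut && unique_pct < unique_cut
  else freq_ratio > freq_cut || unique_pct < unique_cut
}

#' Default mtry for a random-forest regression
#'
#' The floored square root of the number of predictors — e.g. 7 for 52
#' environmental variables.
#'
#' @param n_predictors number of explanatory variables.
#' @return integer.
#' @export
default_mtry <- function(n_predictors) as.integer(floor(sqrt(n_predictors)))

#' Training-set size at a given fraction
#'
#' Rounds up, so 93 samples at 75% give 70 training samples.
#'
#' @param n_samples total samples.
#' @param train_fraction fraction assigned to training.
#' @return integer.
#' @export
train_size <- function(n_samples, train_fraction = 0.75)
  as.integer(ceiling(n_samples * train_fraction))

#' Configuration of the repeated random-forest screen
#'
#' Defaults mirror the screening protocol: 10 repeats on fresh 75/25
#' train/test splits, mtry tuned over 5..9 by 5-fold cross-validation
#' minimizing RMSE, 500 trees, and link thresholds of 0.25 (linked) and
#' 0.5 (highly linked) on the mean cross-validated R-squared.
#'
#' @param n_repeats train/test repeats (default 10).
#' @param train_fraction fraction of samples trained on (default 0.75).
#' @param n_folds cross-validation folds within the training set (5).
#' @param mtry_grid candidate mtry values (default 5:9).
#' @param n_trees trees per forest (default 500).
#' @param r2_link,r2_hle strict link thresholds on mean CV R-squared.
#' @param r2_method `"pearson"` (squared correlation, default) or
#'   `"sst"` (1 - SSE/SST).
#' @param seed integer seed for splits, folds, and forests.
#' @return a `screen_config` list.
#' @export
screen_config <- function(n_repeats = 10L, train_fraction = 0.75,
                          n_folds = 5L, mtry_grid = 5:9, n_trees = 500L,
                          r2_link = 0.25, r2_hle = 0.5,
                          r2_method = c("pearson", "sst"), seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_repeats >= 1,
            n_folds >= 2, all(mtry_grid >= 1), n_trees >= 1)
  structure(list(n_repeats = as.integer(n_repeats),
                 train_fraction = train_fraction,
                 n_folds = as.integer(n_folds),
                 mtry_grid = as.integer(sort(mtry_grid)),
                 n_trees = as.integer(n_trees),
                 r2_link = r2_link, r2_hle = r2_hle,
                 r2_method = match.arg(r2_method),
                 seed = as.integer(seed)),
            class = "screen_config")
}

r2_of <- function(pred, obs, method) {
  if (method == "pearson") {
    r2 <- squared_pearson(pred, obs)
    if (is.na(r2)) 0 else r2
  } else {
    sst <- sum((obs - mean(obs))^2)
    if (sst == 0) 0 else max(0, 1 - sum((obs - pred)^2) / sst)
  }
}

#' Screen one cluster's abundance against environmental predictors
#'
#' For each repeat: draw a train/test split; tune mtry over the grid by
#' `n_folds`-fold cross-validation on the training set, selecting the
#' value minimizing out-of-fold RMSE; refit the winning forest on the
#' full training set; record the out-of-fold R-squared at the winning
#' mtry, the test-set R-squared of the refit, its RMSE on the test set,
#' and the per-variable importance ranks (permutation importance,
#' rank 1 = most important, ties broken by variable order).  All
#' quantities are averaged over repeats.  A repeat whose training
#' response is constant contributes R-squared 0 and is flagged.
#'
#' @param y numeric abundance vector across samples.
#' @param X prepared (complete) [env_table()] of predictors; factor
#'   columns are passed to the forest as native categoricals.
#' @param cfg a [screen_config()].
#' @param pfc_id identifier echoed into the result.
#' @return a `screen_result` list: `summary` (one-row data frame with
#'   pfc_id, mean_cv_r2, mean_test_r2, mean_rmse, n_degenerate_repeats,
#'   category) and `importance_rank` (named per-variable mean rank).
#' @export
screen_pfc <- function(y, X, cfg = screen_config(), pfc_id = NA_integer_) {
  X <- as.data.frame(X)
  n <- length(y)
  stopifnot(nrow(X) == n, !anyNA(X), !anyNA(y))
  v <- ncol(X)
  grid <- cfg$mtry_grid[cfg$mtry_grid <= v]
  if (length(grid) == 0) grid <- default_mtry(v)
  n_train <- train_size(n, cfg$train_fraction)

  cv_r2 <- test_r2 <- rmse <- numeric(cfg$n_repeats)
  degenerate <- logical(cfg$n_repeats)
  rank_sum <- stats::setNames(numeric(v), colnames(X))

  with_seed(cfg$seed, {
    for (r in seq_len(cfg$n_repeats)) {
      train <- sort(sample.int(n, n_train))
      test <- setdiff(seq_len(n), train)
      ytr <- y[train]
      if (stats::sd(ytr) == 0) {
        degenerate[r] <- TRUE
        rank_sum <- rank_sum + (v + 1) / 2  # uninformative: mid rank
        next
      }
      folds <- sample(rep_len(seq_len(cfg$n_folds), n_train))
      oof <- matrix(NA_real_, n_train, length(grid))
      for (f in seq_len(cfg$n_folds)) {
        hold <- folds == f
        for (g in seq_along(grid)) {
          fit <- randomForest::randomForest(
            x = X[train[!hold], , drop = FALSE], y = ytr[!hold],
            mtry = grid[g], ntree = cfg$n_trees)
          oof[hold, g] <- stats::predict(fit, X[train[hold], , drop = FALSE])
        }
      }
      fold_rmse <- sqrt(colMeans((oof - ytr)^2))
      best <- which.min(fold_rmse)  # ties -> smallest mtry
      cv_r2[r] <- r2_of(oof[, best], ytr, cfg$r2_method)

      refit <- randomForest::randomForest(
        x = X[train, , drop = FALSE], y = ytr, mtry = grid[best],
        ntree = cfg$n_trees, importance = TRUE)
      pred <- stats::predict(refit, X[test, , drop = FALSE])
      test_r2[r] <- r2_of(pred, y[test], cfg$r2_method)
      rmse[r] <- sqrt(mean((pred - y[test])^2))
      imp <- randomForest::importance(refit, type = 1, scale = FALSE)[, 1]
      rank_sum <- rank_sum + rank(-imp, ties.method = "first")
    }
  })

  mean_cv <- mean(cv_r2)
  summary <- data.frame(
    pfc_id = pfc_id,
    mean_cv_r2 = mean_cv,
    mean_test_r2 = mean(test_r2),
    mean_rmse = mean(rmse),
    n_degenerate_repeats = sum(degenerate),
    category = classify_link(mean_cv, cfg),
    stringsAsFactors = FALSE)
  structure(list(summary = summary,
                 importance_rank = rank_sum / cfg$n_repeats,
                 config = cfg),
            class = "screen_result")
}

#' Link category from a mean cross-validated R-squared
#'
#' Strictly over 0.5: highly linked to environmental gradients (`"hle"`);
#' strictly over 0.25 (and at most 0.5): `"linked"`; otherwise `"none"`.
#'
#' @param mean_cv_r2 mean cross-validated R-squared.
#' @param cfg a [screen_config()] supplying the thresholds.
#' @return one of `"none"`, `"linked"`, `"hle"`.
#' @export
classify_link <- function(mean_cv_r2, cfg = screen_config()) {
  if (mean_cv_r2 > cfg$r2_hle) "hle"
  else if (mean_cv_r2 > cfg$r2_link) "linked"
  else "none"
}

#' Screen every cluster of an abundance matrix
#'
#' Applies the near-zero-variance filter, then [screen_pfc()] to each
#' surviving cluster with a per-cluster seed fanned out from the config
#' seed.
#'
#' @param pfc_abund cluster x sample abundance matrix.
#' @param X prepared [env_table()].
#' @param cfg a [screen_config()].
#' @return a `screen_table` list: `results` (data frame, one row per
#'   screened cluster), `importance` (cluster x variable mean-rank
#'   matrix), `nzv_removed` (IDs failing the variance filter).
#' @export
screen_pfcs <- function(pfc_abund, X, cfg = screen_config()) {
  pfc_abund <- as_abundance_matrix(pfc_abund)
  flagged <- apply(pfc_abund, 1, nzv_flag)
  keep <- rownames(pfc_abund)[!flagged]
  res <- vector("list", length(keep))
  imp <- matrix(NA_real_, length(keep), ncol(X),
                dimnames = list(keep, colnames(X)))
  for (i in seq_along(keep)) {
    cfg_i <- cfg
    cfg_i$seed <- stage_seed(cfg$seed, paste0("screen/", keep[i]))
    sr <- screen_pfc(pfc_abund[keep[i], ], X, cfg_i, pfc_id = keep[i])
    res[[i]] <- sr$summary
    imp[i, ] <- sr$importance_rank
  }
  results <- if (length(res)) do.call(rbind, res) else NULL
  structure(list(results = results, importance = imp,
                 nzv_removed = rownames(pfc_abund)[flagged],
                 config = cfg),
            class = "screen_table")
}

#' Aggregate variable importance over screened clusters
#'
#' A variable is a model's "best" predictor when it has the smallest mean
#' importance rank in that model (ties to the earlier variable).
#'
#' @param screen a `screen_table` from [screen_pfcs()].
#' @return data frame per variable: `times_rank1`, `times_top3`,
#'   `mean_rank`, `mean_r2_when_best`.
#' @export
aggregate_importance <- function(screen) {
  imp <- screen$importance
  r2 <- screen$results$mean_cv_r2
  v <- colnames(imp)
  best <- apply(imp, 1, which.min)
  in_top3 <- t(apply(imp, 1, function(row)
    seq_along(row) %in% order(row)[seq_len(min(3, length(row)))]))
  out <- data.frame(
    variable = v,
    times_rank1 = vapply(seq_along(v), function(j) sum(best == j), 0L),
    times_top3 = colSums(in_top3),
    mean_rank = colMeans(imp),
    mean_r2_when_best = vapply(seq_along(v), function(j) {
      sel <- best == j
      if (!any(sel)) NA_real_ else mean(r2[sel])
    }, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
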