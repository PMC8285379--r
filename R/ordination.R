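# Chi-square standardized residual matrix of a non-negative table plus
# the row/column weights; the shared core of CCA fitting.
chisq_standardize <- function(Y) {
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop("negative abundance in ordination response")
  rs <- rowSums(Y); cs <- colSums(Y)
  if (any(rs == 0))
    stop("zero-sum sample row: ", rownames(Y)[which(rs == 0)[1]])
  if (any(cs == 0))
    stop("zero-sum feature column: ", colnames(Y)[which(cs == 0)[1]])
  tot <- sum(Y)
  P <- Y / tot
  r <- rowSums(P); c <- colSums(P)
  Q <- (P - outer(r, c)) / sqrt(outer(r, c))
  list(Q = Q, r = r, c = c)
}

# Expand an env_table into a constraint matrix: qualitative variables are
# one-hot encoded dropping the reference level; returns column->variable map.
constraint_matrix <- function(X) {
  X <- as.data.frame(X)
  mm <- stats::model.matrix(~ ., data = X)
  assign <- attr(mm, "assign")
  keep <- assign != 0
  list(M = mm[, keep, drop = FALSE],
       variable = names(X)[assign[keep]])
}

#' Constrained correspondence analysis
#'
#' Canonical CCA: the response table is chi-square standardized, the
#' standardized residuals are projected (with sample weights equal to row
#' masses) onto the span of the explanatory variables, and the fitted
#' part is decomposed by SVD.  Qualitative variables are expanded to
#' indicator columns with the reference level dropped; linearly dependent
#' constraint columns are dropped with a warning.  Feature and site
#' scores are reported in species-focused scaling (scaling 2) by default:
#' feature scores carry the singular values, site scores (linear
#' combinations of the constraints) do not.  Each axis is oriented so
#' that its largest-magnitude biplot score is positive.
#'
#' @param Y samples x features non-negative abundance matrix.
#' @param X an [env_table()] of explanatory variables (complete).
#' @param scaling 1 (site-focused) or 2 (species-focused, default).
#' @return an `ordination_result` list: `eigenvalues`, `total_inertia`,
#'   `constrained_inertia`, `feature_scores`, `site_scores` (linear
#'   constraint scores), `wa_scores` (weighted averages of feature
#'   scores), `biplot_scores`, `row_weights`, plus bookkeeping used by
#'   the permutation test.
#' @export
fit_cca <- function(Y, X, scaling = 2) {
  Y <- as.matrix(Y)
  std <- chisq_standardize(Y)
  Q <- std$Q; r <- std$r; c <- std$c
  total_inertia <- sum(Q^2)

  cm <- constraint_matrix(X)
  M <- cm$M
  if (nrow(M) != nrow(Y)) stop("Y and X disagree on sample count")
  # weighted centering, then row-weighted design
  M <- sweep(M, 2, colSums(M * r))
  Mw <- M * sqrt(r)
  qrX <- qr(Mw)
  if (qrX$rank < ncol(Mw)) {
    dropped <- colnames(Mw)[qrX$pivot[(qrX$rank + 1):ncol(Mw)]]
    warning("dropping linearly dependent constraint column(s): ",
            paste(dropped, collapse = ", "))
  }
  Qfit <- qr.fitted(qrX, Q)
  sv <- svd(Qfit)
  tol <- max(dim(Qfit)) * max(sv$d, 0) * .Machine$double.eps
  pos <- sv$d > max(tol, sqrt(.Machine$double.eps) * max(sv$d, 1))
  d <- sv$d[pos]
  U <- sv$u[, pos, drop = FALSE]
  V <- sv$v[, pos, drop = FALSE]
  eig <- d^2
  naxes <- length(d)
  axes <- paste0("CCA", seq_len(naxes))

  # biplot scores: weighted correlation of constraints with the axes
  Mstd <- sweep(Mw, 2, sqrt(colSums(Mw^2)), "/")
  biplot <- crossprod(Mstd, U)
  flip <- vapply(seq_len(naxes), function(k) {
    b <- biplot[, k]
    sign(b[which.max(abs(b))]) < 0
  }, logical(1))
  if (any(flip)) {
    U[, flip] <- -U[, flip]
    V[, flip] <- -V[, flip]
    biplot[, flip] <- -biplot[, flip]
  }

  # back-transform to ordination coordinates
  site_lc <- (U / sqrt(r))
  feat <- V / sqrt(c)
  if (scaling == 2) {
    feat <- sweep(feat, 2, d, "*")
  } else {
    site_lc <- sweep(site_lc, 2, d, "*")
  }
  # weighted averages of feature scores give WA site scores
  Prof <- Y / rowSums(Y)
  wa <- Prof %*% (V / sqrt(c))
  if (scaling == 2) wa <- sweep(wa, 2, d, "*")

  dimnames(site_lc) <- list(rownames(Y), axes)
  dimnames(wa) <- list(rownames(Y), axes)
  dimnames(feat) <- list(colnames(Y), axes)
  dimnames(biplot) <- list(colnames(M), axes)
  names(eig) <- axes

  structure(list(eigenvalues = eig,
                 total_inertia = total_inertia,
                 constrained_inertia = sum(eig),
                 feature_scores = feat,
                 site_scores = site_lc,
                 wa_scores = wa,
                 biplot_scores = biplot,
                 biplot_variable = cm$variable,
                 row_weights = r,
                 rank = qrX$rank,
                 scaling = scaling),
            class = "ordination_result")
}

# constrained/total inertia ratio without scores; used by permutations
# and stepwise selection
cca_inertia_ratio <- function(Q, r, M) {
  M <- sweep(M, 2, colSums(M * r))
  Mw <- M * sqrt(r)
  qrX <- qr(Mw)
  list(constrained = sum(qr.fitted(qrX, Q)^2),
       total = sum(Q^2),
       k = qrX$rank)
}

#' Permutation test of a constrained ordination
#'
#' Permutes the sample rows of the explanatory table and recomputes the
#' constrained-to-total inertia ratio; the p-value is
#' `(1 + #permutations >= observed) / (1 + n_perm)`.
#'
#' @param Y samples x features non-negative matrix.
#' @param X an [env_table()].
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return list with `p_value`, `observed_ratio`, `n_perm`.
#' @export
cca_permutation_test <- function(Y, X, n_perm = 999, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  std <- chisq_standardize(as.matrix(Y))
  M <- constraint_matrix(X)$M
  obs <- cca_inertia_ratio(std$Q, std$r, M)
  obs_ratio <- obs$constrained / obs$total
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      Mp <- M[sample.int(nrow(M)), , drop = FALSE]
      p <- cca_inertia_ratio(std$Q, std$r, Mp)
      (p$constrained / p$total) >= obs_ratio
    }, logical(1)))
  })
  list(p_value = (1 + hits) / (1 + n_perm),
       observed_ratio = obs_ratio, n_perm = n_perm)
}

# AIC analogue for a constrained ordination with k fitted constraint
# columns: n*log(residual_inertia/n) + 2*(k+1)
cca_aic <- function(Q, r, X_sub) {
  n <- nrow(Q)
  if (is.null(X_sub) || ncol(X_sub) == 0) {
    resid <- sum(Q^2)
    k <- 0L
  } else {
    M <- constraint_matrix(X_sub)$M
    fit <- cca_inertia_ratio(Q, r, M)
    resid <- fit$total - fit$constrained
    k <- fit$k
  }
  n * log(resid / n) + 2 * (k + 1)
}

#' Bidirectional stepwise selection of ordination constraints
#'
#' Greedy forward-then-backward sweeps minimizing an AIC analogue for
#' constrained ordination, `n*log(residual_inertia/n) + 2*(k+1)` with `k`
#' the number of fitted constraint columns.  Starts from the empty model
#' and stops when no single addition or removal improves the criterion;
#' ties are broken by variable order, making the search deterministic.
#'
#' @param Y samples x features non-negative matrix.
#' @param X_full candidate [env_table()] (>= 2 variables).
#' @return list with `selected` (variable names in selection order),
#'   `aic` (criterion of the final model), `trace` (data frame of steps).
#' @export
cca_stepwise <- function(Y, X_full) {
  X_full <- as.data.frame(X_full)
  if (ncol(X_full) < 2) stop("need at least 2 candidate variables")
  std <- chisq_standardize(as.matrix(Y))
  Q <- std$Q; r <- std$r
  vars <- names(X_full)
  current <- character(0)
  cur_aic <- cca_aic(Q, r, NULL)
  trace <- data.frame(step = "start", variable = NA_character_,
                      aic = cur_aic, stringsAsFactors = FALSE)
  repeat {
    changed <- FALSE
    # forward
    candidates <- setdiff(vars, current)
    if (length(candidates)) {
      aics <- vapply(candidates, function(v)
        cca_aic(Q, r, X_full[, c(current, v), drop = FALSE]), numeric(1))
      if (min(aics) < cur_aic) {
        v <- candidates[which.min(aics)]
        current <- c(current, v)
        cur_aic <- min(aics)
        trace <- rbind(trace, data.frame(step = "add", variable = v,
                                         aic = cur_aic))
        changed <- TRUE
      }
    }
    # backward
    if (length(current)) {
      aics <- vapply(current, function(v)
        cca_aic(Q, r, X_full[, setdiff(current, v), drop = FALSE]),
        numeric(1))
      if (length(aics) && min(aics) < cur_aic) {
        v <- current[which.min(aics)]
        current <- setdiff(current, v)
        cur_aic <- min(aics)
        trace <- rbind(trace, data.frame(step = "drop", variable = v,
                                         aic = cur_aic))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(selected = current, aic = cur_aic, trace = trace)
}

#' Group barycenters in ordination space
#'
#' The barycenter of a group (a KEGG pathway, a phylum, ...) is the
#' per-axis arithmetic mean of its member features' scores, with the
#' (n-1)-denominator standard deviation as spread (0 for singletons).
#' A feature may belong to several groups.  Groups smaller than
#' `min_size` are flagged, never dropped.
#'
#' @param feature_scores features x axes score matrix.
#' @param membership named list: group -> character vector of features.
#' @param min_size flag threshold on group size (default 10).
#' @return data frame: group_id, n_members, small_group, then
#'   `mean_<axis>` and `sd_<axis>` columns.
#' @export
group_barycenters <- function(feature_scores, membership, min_size = 10L) {
  feature_scores <- as.matrix(feature_scores)
  unknown <- setdiff(unlist(membership, use.names = FALSE),
                     rownames(feature_scores))
  if (length(unknown))
    stop("membership names unknown feature: ", unknown[1])
  axes <- colnames(feature_scores)
  rows <- lapply(names(membership), function(g) {
    m <- feature_scores[membership[[g]], , drop = FALSE]
    mu <- colMeans(m)
    sdv <- if (nrow(m) == 1) stats::setNames(rep(0, ncol(m)), axes)
           else apply(m, 2, stats::sd)
    out <- data.frame(group_id = g, n_members = nrow(m),
                      small_group = nrow(m) < min_size,
                      stringsAsFactors = FALSE)
    for (a in axes) {
      out[[paste0("mean_", a)]] <- mu[[a]]
      out[[paste0("sd_", a)]] <- sdv[[a]]
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
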