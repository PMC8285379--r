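#' Curation parameters for environmental tables
#'
#' @param freq_cut frequency ratio above which the dominant value flags a
#'   near-zero-variance variable (default 95/5 = 19).
#' @param unique_cut percent of distinct values below which a variable may
#'   be flagged (default 10).
#' @param corr_cut absolute Pearson correlation above which one member of
#'   a quantitative pair is dropped (default 0.90).
#' @param k_impute neighbours used by [knn_impute()] (default 5).
#' @return a `prep_config` list.
#' @export
prep_config <- function(freq_cut = 95 / 5, unique_cut = 10,
                        corr_cut = 0.90, k_impute = 5L) {
  stopifnot(freq_cut > 0, unique_cut > 0, unique_cut <= 100,
            corr_cut > 0, k_impute >= 1)
  structure(list(freq_cut = freq_cut, unique_cut = unique_cut,
                 corr_cut = corr_cut, k_impute = as.integer(k_impute)),
            class = "prep_config")
}

#' Drop near-zero-variance and highly correlated environmental variables
#'
#' First every column (quantitative or qualitative) is tested with the
#' near-zero-variance rule of [nzv_flag()] (missing entries ignored).
#' Then quantitative pairs with |Pearson r| > `corr_cut` (pairwise
#' complete observations) are resolved greedily: the pair with the
#' largest |r| is examined first and the member with the larger mean
#' absolute correlation to all other quantitative variables is removed.
#' Qualitative variables are exempt from the correlation step.
#'
#' @param env an [env_table()].
#' @param cfg a [prep_config()].
#' @return list with `env` (filtered table) and `removed` (data frame:
#'   variable, reason).
#' @export
filter_variables <- function(env, cfg = prep_config()) {
  removed <- data.frame(variable = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  nzv <- vapply(env, function(col) {
    v <- col[!is.na(col)]
    nzv_flag(as.vector(v), freq_cut = cfg$freq_cut,
             unique_cut = cfg$unique_cut)
  }, logical(1))
  if (any(nzv)) {
    removed <- rbind(removed, data.frame(variable = names(env)[nzv],
                                         reason = "nzv",
                                         stringsAsFactors = FALSE))
    env <- env[, !nzv, drop = FALSE]
  }

  quant <- names(env)[is_quantitative(env)]
  if (length(quant) >= 2) {
    drop <- character(0)
    repeat {
      keep <- setdiff(quant, drop)
      if (length(keep) < 2) break
      cm <- suppressWarnings(
        stats::cor(env[, keep, drop = FALSE],
                   use = "pairwise.complete.obs"))
      cm[is.na(cm)] <- 0
      diag(cm) <- 0
      am <- abs(cm)
      if (max(am) <= cfg$corr_cut) break
      ij <- which(am == max(am), arr.ind = TRUE)[1, ]
      mean_abs <- rowMeans(am)
      # drop the member more correlated with everything else; ties keep
      # the earlier column
      pick <- if (mean_abs[ij[1]] >= mean_abs[ij[2]]) ij[1] else ij[2]
      drop <- c(drop, keep[pick])
    }
    if (length(drop)) {
      removed <- rbind(removed, data.frame(variable = drop, reason = "corr",
                                           stringsAsFactors = FALSE))
      env <- env[, setdiff(names(env), drop), drop = FALSE]
    }
  }
  class(env) <- c("env_table", "data.frame")
  list(env = env, removed = removed)
}

#' Scale and center quantitative variables
#'
#' Each quantitative column is transformed to mean 0 and standard
#' deviation 1 (n-1 denominator), with statistics computed over observed
#' entries only; missing cells stay missing.  Qualitative columns pass
#' through untouched.
#'
#' @param env an [env_table()].
#' @return the standardized table.
#' @export
scale_center <- function(env) {
  for (v in names(env)[is_quantitative(env)]) {
    x <- env[[v]]
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0)
      stop("zero-variance quantitative variable reached scaling: ", v)
    env[[v]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  env
}

#' k-nearest-neighbour imputation of missing quantitative cells
#'
#' The distance between two samples is the Euclidean distance over the
#' quantitative variables observed in both, normalized by the number of
#' shared variables (so samples with different missingness patterns stay
#' comparable).  Each missing cell is replaced by the mean of the
#' variable over the `k` nearest samples where it is observed; ties in
#' distance are broken by sample order.
#'
#' @param env a scaled [env_table()].
#' @param k neighbours (default 5).
#' @return the completed table.
#' @export
knn_impute <- function(env, k = 5L) {
  quant <- names(env)[is_quantitative(env)]
  X <- as.matrix(as.data.frame(env)[, quant, drop = FALSE])
  obs <- !is.na(X)
  short <- colSums(obs) < k
  if (any(short))
    stop("variable observed in fewer than k samples: ",
         quant[which(short)[1]])
  if (!anyNA(X)) return(env)
  n <- nrow(X)
  # pairwise normalized Euclidean distance over shared observed variables
  D <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- obs[i, ] & obs[j, ]
      if (!any(shared)) next
      d2 <- sum((X[i, shared] - X[j, shared])^2) / sum(shared)
      D[i, j] <- D[j, i] <- sqrt(d2)
    }
  }
  miss <- which(is.na(X), arr.ind = TRUE)
  for (r in seq_len(nrow(miss))) {
    i <- miss[r, 1]; v <- miss[r, 2]
    donors <- which(obs[, v] & seq_len(n) != i)
    if (length(donors) < k)
      stop("not enough donors to impute ", quant[v])
    ord <- donors[order(D[i, donors], donors)]
    X[i, v] <- mean(X[ord[seq_len(k)], v])
  }
  for (v in quant) env[[v]] <- X[, v]
  env
}

#' Full environmental-table preparation
#'
#' Filter near-zero-variance and correlated variables, scale/center, then
#' impute missing cells — the curation order used for gradient screening.
#'
#' @param env an [env_table()].
#' @param cfg a [prep_config()].
#' @return list with `env` (complete, standardized table) and `removed`.
#' @export
prepare_env <- function(env, cfg = prep_config()) {
  flt <- filter_variables(env, cfg)
  out <- knn_impute(scale_center(flt$env), k = cfg$k_impute)
  list(env = out, removed = flt$removed)
}
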