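# Independent oracles used across the suite.  Each is a deliberately
# naive implementation kept separate from the package's code paths.

# --- union-find connected components ---------------------------------
uf_components <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(nodes, find, "")
  comps <- split(nodes, roots)
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, `[[`, "", 1))]
}

# --- Smith-Waterman local alignment (Gotoh affine gaps) --------------
# cost of a gap of length L is open + ext * L, matching BLAST-style
# penalties.  Deterministic traceback preference: diagonal, then up
# (gap in b), then left (gap in a).
sw_oracle <- function(a, b, open = 11, ext = 1, mat = NULL) {
  if (is.null(mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    mat <- e$BLOSUM62
  }
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- E <- F_ <- matrix(0, n + 1, m + 1)
  E[] <- F_[] <- -Inf
  best <- 0; bi <- 0; bj <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(M[i, j - 1] - (open + ext), E[i, j - 1] - ext)
      F_[i, j] <- max(M[i - 1, j] - (open + ext), F_[i - 1, j] - ext)
      diag_ <- M[i - 1, j - 1] + mat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, diag_, E[i, j], F_[i, j])
      if (M[i, j] > best) { best <- M[i, j]; bi <- i; bj <- j }
    }
  }
  if (best <= 0) return(NULL)
  # traceback from (bi, bj) in the M layer
  i <- bi; j <- bj
  n_id <- 0; ncol_aln <- 0
  end_a <- i - 1; end_b <- j - 1
  state <- "M"
  repeat {
    if (state == "M") {
      if (M[i, j] == 0) break
      diag_ <- M[i - 1, j - 1] + mat[av[i - 1], bv[j - 1]]
      if (M[i, j] == diag_) {
        n_id <- n_id + (av[i - 1] == bv[j - 1])
        ncol_aln <- ncol_aln + 1
        i <- i - 1; j <- j - 1
      } else if (M[i, j] == F_[i, j]) state <- "F"
      else state <- "E"
    } else if (state == "E") {
      ncol_aln <- ncol_aln + 1
      if (E[i, j] == M[i, j - 1] - (open + ext)) state <- "M"
      j <- j - 1
    } else {
      ncol_aln <- ncol_aln + 1
      if (F_[i, j] == M[i - 1, j] - (open + ext)) state <- "M"
      i <- i - 1
    }
  }
  # aligned spans are positions i..end_a of a and j..end_b of b
  list(score = best,
       pident = n_id / ncol_aln * 100,
       cov_a = (end_a - i + 1) / n * 100,
       cov_b = (end_b - j + 1) / m * 100)
}

# --- explicit generalized-eigenproblem CCA oracle --------------------
# Forms the weighted projection and solves the eigenproblem of the
# cross-product of the fitted chi-square residuals directly.
cca_oracle <- function(Y, X) {
  Y <- as.matrix(Y)
  P <- Y / sum(Y)
  r <- rowSums(P); cc <- colSums(P)
  Q <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  mm <- stats::model.matrix(~ ., data = as.data.frame(X))[, -1, drop = FALSE]
  mm <- sweep(mm, 2, colSums(mm * r))
  Mw <- mm * sqrt(r)
  B <- solve(crossprod(Mw), crossprod(Mw, Q))
  Qfit <- Mw %*% B
  S <- crossprod(Qfit)
  ei <- eigen(S, symmetric = TRUE)
  pos <- ei$values > 1e-10 * max(ei$values, 1)
  list(eigenvalues = ei$values[pos],
       vectors = ei$vectors[, pos, drop = FALSE],
       total_inertia = sum(Q^2),
       constrained_inertia = sum(Qfit^2),
       col_mass = cc)
}

# --- exact Wilcoxon rank-sum enumeration -----------------------------
wilcox_exact_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(nx)])
  idx <- utils::combn(nx + ny, nx)
  ws <- apply(idx, 2, function(s) sum(ranks[s]))
  mu <- mean(ws)
  p <- min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
  p
}

# --- misc ------------------------------------------------------------
random_aa <- function(len) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                 "F","P","S","T","W","Y","V"), len, replace = TRUE),
        collapse = "")
}

mutate_aa <- function(seq, n_subs) {
  v <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(v), n_subs)
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
           "F","P","S","T","W","Y","V")
  for (p in pos) v[p] <- sample(setdiff(aas, v[p]), 1)
  paste(v, collapse = "")
}

tiny_partition <- function(clusters, singletons = character(0)) {
  structure(list(clusters = clusters, singletons = singletons),
            class = "pfc_partition")
}
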