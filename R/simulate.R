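#' Generate a synthetic protein catalog with planted homology families
#'
#' Each family grows from a random root sequence (length 80-400 aa) by
#' independent point substitutions at the requested expected per-site
#' rate; no indels are introduced, so within-family alignments keep 100%
#' coverage and the identity threshold is the active margin when the
#' network is built.  Members are assigned round-robin to MAGs.  Families
#' destined to be "dark" are left unannotated in both databases and drawn
#' exclusively from MAGs whose taxonomy is truncated at the phylum level;
#' other families carry a family-specific KEGG ortholog, pathway, and
#' eggNOG description, with per-protein annotation rates emulating sparse
#' real-world annotation.
#'
#' @param n_mags number of MAGs (in addition to `n_phylum_only_mags`).
#' @param n_families number of homology families.
#' @param family_size_range integer range of members per family.
#' @param divergence expected per-site substitution fraction in \[0, 0.6).
#' @param n_dark_families how many families are planted dark.
#' @param n_phylum_only_mags MAGs with taxonomy truncated at phylum.
#' @param kegg_rate,eggnog_rate per-protein annotation probabilities for
#'   non-dark families.
#' @param seed integer seed.
#' @return list with `catalog`, `taxonomy`, and `truth` (list with
#'   `planted_families` and `planted_dark`).
#' @export
generate_catalog <- function(n_mags = 10L, n_families = 20L,
                             family_size_range = c(2L, 6L),
                             divergence = 0.05,
                             n_dark_families = 0L,
                             n_phylum_only_mags = 2L,
                             kegg_rate = 0.5, eggnog_rate = 0.85,
                             seed = 1L) {
  stopifnot(divergence >= 0, divergence < 0.6,
            n_dark_families <= n_families)
  if (n_dark_families > 0 && n_phylum_only_mags < 1)
    stop("dark families need at least one phylum-only MAG")
  with_seed(seed, {
    mag_reg <- sprintf("MAG_%03d", seq_len(n_mags))
    mag_dark <- if (n_phylum_only_mags > 0)
      sprintf("MAGP_%03d", seq_len(n_phylum_only_mags)) else character(0)
    phyla <- sprintf("Phylum_%02d", 1:6)
    mk_rank <- function(pre, n) sprintf("%s_%02d", pre, sample.int(n, 1))
    tax_rows <- lapply(c(mag_reg, mag_dark), function(m) {
      truncated <- m %in% mag_dark
      data.frame(
        mag_id = m,
        domain = sample(c("Bacteria", "Archaea"), 1, prob = c(0.85, 0.15)),
        phylum = sample(phyla, 1),
        class = if (truncated) "unannotated" else mk_rank("Class", 8),
        order = if (truncated) "unannotated" else mk_rank("Order", 12),
        family = if (truncated) "unannotated" else mk_rank("Family", 16),
        genus = if (truncated) "unannotated" else mk_rank("Genus", 24),
        stringsAsFactors = FALSE)
    })
    tx <- do.call(rbind, tax_rows)
    taxonomy <- mag_taxonomy(tx$mag_id, tx$domain, tx$phylum, tx$class,
                             tx$order, tx$family, tx$genus)

    dark_fams <- if (n_dark_families > 0)
      seq_len(n_families) > (n_families - n_dark_families) else
      rep(FALSE, n_families)

    mutate_seq <- function(root, rate) {
      s <- strsplit(root, "")[[1]]
      hit <- stats::runif(length(s)) < rate
      if (any(hit))
        s[hit] <- vapply(s[hit], function(a)
          sample(setdiff(AA_ALPHABET20, a), 1), "")
      paste(s, collapse = "")
    }

    pid <- sid <- mid <- character(0)
    kid <- kpw <- egg <- list()
    fam_members <- vector("list", n_families)
    names(fam_members) <- sprintf("F%03d", seq_len(n_families))
    counter <- 0L
    for (f in seq_len(n_families)) {
      size <- sample(seq(family_size_range[1], family_size_range[2]), 1)
      len <- sample(80:400, 1)
      root <- paste(sample(AA_ALPHABET20, len, replace = TRUE),
                    collapse = "")
      ko <- sprintf("K%05d", f)
      pw <- sprintf("map%05d", (f - 1) %/% 3 + 1)
      en <- sprintf("eggnog description %03d", f)
      pool <- if (dark_fams[f]) mag_dark else mag_reg
      for (m in seq_len(size)) {
        counter <- counter + 1L
        id <- sprintf("P%05d", counter)
        pid <- c(pid, id)
        sid <- c(sid, mutate_seq(root, divergence))
        mid <- c(mid, pool[(m - 1L) %% length(pool) + 1L])
        annot_k <- !dark_fams[f] && stats::runif(1) < kegg_rate
        annot_e <- !dark_fams[f] && stats::runif(1) < eggnog_rate
        kid <- c(kid, list(if (annot_k) ko else character(0)))
        kpw <- c(kpw, list(if (annot_k) pw else character(0)))
        egg <- c(egg, list(if (annot_e) en else character(0)))
        fam_members[[f]] <- c(fam_members[[f]], id)
      }
    }
    catalog <- protein_catalog(pid, sid, mid,
                               3L * (nchar(sid) + 1L), kid, kpw, egg)
    list(catalog = catalog, taxonomy = taxonomy,
         truth = list(planted_families = fam_members,
                      planted_dark = names(fam_members)[dark_fams]))
  })
}

#' Generate a synthetic environmental table
#'
#' Quantitative variables are standard normal with requested pairwise
#' correlations (Cholesky construction); qualitative variables are
#' uniform over their levels; missingness is completely at random on
#' quantitative cells.
#'
#' @param n_samples samples (default 93, the regime of a typical global
#'   ocean metagenome panel).
#' @param n_quant,n_qual numbers of quantitative/qualitative variables.
#' @param qual_levels integer vector of level counts, recycled over the
#'   qualitative variables (default c(8, 4, 3, 2): province-like, ocean
#'   region, season moment, depth layer).
#' @param corr_pairs data frame (i, j, r) of requested correlations
#'   between quantitative variables i and j; `NULL` for independence.
#' @param missing_fraction MCAR missingness rate on quantitative cells,
#'   in \[0, 0.3\] (default 0.066).
#' @param seed integer seed.
#' @return an [env_table()] with variables q01.., f01.. .
#' @export
generate_env <- function(n_samples = 93L, n_quant = 10L, n_qual = 4L,
                         qual_levels = c(8L, 4L, 3L, 2L),
                         corr_pairs = NULL, missing_fraction = 0.066,
                         seed = 1L) {
  stopifnot(missing_fraction >= 0, missing_fraction <= 0.3)
  with_seed(seed, {
    R <- diag(n_quant)
    if (!is.null(corr_pairs)) {
      for (k in seq_len(nrow(corr_pairs))) {
        i <- corr_pairs$i[k]; j <- corr_pairs$j[k]
        R[i, j] <- R[j, i] <- corr_pairs$r[k]
      }
    }
    L <- tryCatch(chol(R), error = function(e)
      stop("requested correlation matrix is not positive definite"))
    Z <- matrix(stats::rnorm(n_samples * n_quant), n_samples, n_quant)
    Xq <- Z %*% L
    colnames(Xq) <- sprintf("q%02d", seq_len(n_quant))
    if (missing_fraction > 0) {
      Xq_full <- Xq
      drop <- stats::runif(length(Xq)) < missing_fraction
      Xq[drop] <- NA
      # keep at least 6 observed values per variable so imputation
      # always has donors
      for (j in seq_len(n_quant)) {
        if (sum(!is.na(Xq[, j])) < 6)
          Xq[seq_len(6), j] <- Xq_full[seq_len(6), j]
      }
    }
    df <- as.data.frame(Xq)
    if (n_qual > 0) {
      lv <- rep_len(qual_levels, n_qual)
      for (j in seq_len(n_qual)) {
        df[[sprintf("f%02d", j)]] <-
          factor(sample(sprintf("L%d", seq_len(lv[j])), n_samples,
                        replace = TRUE),
                 levels = sprintf("L%d", seq_len(lv[j])))
      }
    }
    rownames(df) <- sprintf("S%03d", seq_len(n_samples))
    env_table(df)
  })
}

#' Build a link specification for [generate_abundances()]
#'
#' Assigns cluster roles in order: the first `n_linked` clusters are
#' environment-linked (drivers cycled over the supplied variables), the
#' next `n_noise` are pure noise, the next `n_near_constant` are
#' near-constant; any remainder is noise.
#'
#' @param cluster_ids character vector of cluster identifiers.
#' @param drivers candidate driver variable names (cycled).
#' @param n_linked,n_noise,n_near_constant role counts.
#' @param effect log-scale effect size of a linked driver.
#' @param snr signal-to-noise ratio; noise_sd = effect / snr.
#' @return named list, one role spec per cluster.
#' @export
make_link_spec <- function(cluster_ids, drivers, n_linked = 20L,
                           n_noise = 20L, n_near_constant = 5L,
                           effect = 1, snr = 3) {
  n <- length(cluster_ids)
  stopifnot(n_linked + n_noise + n_near_constant <= n)
  roles <- rep("noise", n)
  roles[seq_len(n_linked)] <- "linked"
  if (n_noise > 0) roles[n_linked + seq_len(n_noise)] <- "noise"
  if (n_near_constant > 0)
    roles[n_linked + n_noise + seq_len(n_near_constant)] <- "near_constant"
  spec <- vector("list", n)
  names(spec) <- cluster_ids
  for (i in seq_len(n)) {
    spec[[i]] <- switch(roles[i],
      linked = list(type = "linked",
                    driver = drivers[(i - 1) %% length(drivers) + 1],
                    effect = effect, noise_sd = effect / snr),
      noise = list(type = "noise", noise_sd = effect),
      near_constant = list(type = "near_constant"))
  }
  spec
}

#' Generate protein abundances with planted environmental links
#'
#' Cluster-level target abundances follow the role spec: linked clusters
#' are log-linear in a quantitative driver (or carry per-level offsets of
#' a qualitative driver) plus Gaussian log-scale noise; noise clusters
#' are log-normal around the base; near-constant clusters take a single
#' value with two perturbed samples, so they fail the near-zero-variance
#' filter by construction.  The target is spread over member proteins by
#' a fixed multiplicative jitter normalized to mean 1, so the per-cluster
#' mean recovers the target exactly.
#'
#' @param partition a `pfc_partition` (typically planted families).
#' @param env an [env_table()] providing the drivers (complete for
#'   driver columns).
#' @param link_spec named list from [make_link_spec()].
#' @param base_abundance multiplicative base level (default 10).
#' @param jitter_sd log-sd of the member-protein jitter (default 0.05).
#' @param seed integer seed.
#' @return list with `protein_abundance` (protein x sample matrix),
#'   `cluster_target` (cluster x sample matrix), `link_spec`.
#' @export
generate_abundances <- function(partition, env, link_spec,
                                base_abundance = 10, jitter_sd = 0.05,
                                seed = 1L) {
  stopifnot(setequal(names(link_spec), names(partition$clusters)))
  n_s <- nrow(env)
  samples <- rownames(env)
  with_seed(seed, {
    target <- matrix(NA_real_, length(link_spec), n_s,
                     dimnames = list(names(partition$clusters), samples))
    for (cl in names(partition$clusters)) {
      sp <- link_spec[[cl]]
      target[cl, ] <- switch(sp$type,
        linked = {
          if (!sp$driver %in% names(env))
            stop("driver variable absent from env: ", sp$driver)
          z <- env[[sp$driver]]
          lin <- if (is.numeric(z)) {
            sp$effect * as.numeric(scale(z))
          } else {
            offs <- seq(-1, 1, length.out = nlevels(z)) * sp$effect
            offs[as.integer(z)]
          }
          base_abundance *
            exp(lin + stats::rnorm(n_s, 0, sp$noise_sd))
        },
        noise = base_abundance * exp(stats::rnorm(n_s, 0, sp$noise_sd)),
        near_constant = {
          # one perturbed sample: 2 unique values and a dominant mode,
          # so the near-zero-variance rule flags it for any n >= 21
          v <- rep(base_abundance, n_s)
          v[1] <- base_abundance * 2
          v
        },
        stop("unknown link type: ", sp$type))
    }
    prot_rows <- lapply(names(partition$clusters), function(cl) {
      members <- partition$clusters[[cl]]
      w <- exp(stats::rnorm(length(members), 0, jitter_sd))
      w <- w / mean(w)
      m <- outer(w, target[cl, ])
      rownames(m) <- members
      m
    })
    prot <- do.call(rbind, prot_rows)
    colnames(prot) <- samples
    list(protein_abundance = as_abundance_matrix(prot),
         cluster_target = target, link_spec = link_spec)
  })
}

#' Generate a raw count table from abundances
#'
#' Exact inverse of [normalize_counts()]:
#' `count = abundance * length_nt * total_reads / scale`, optionally
#' Poisson-resampled around that expectation.
#'
#' @param abundance protein/gene x sample abundance matrix.
#' @param length_nt named per-gene lengths; `NULL` draws 300..1200 nt.
#' @param total_reads named per-sample totals; `NULL` draws 1e7..5e7.
#' @param scale the normalization scale (default 1e9).
#' @param poisson_noise resample counts as Poisson? (default FALSE).
#' @param seed integer seed (used for drawn lengths/totals and noise).
#' @return a [count_table()].
#' @export
generate_counts <- function(abundance, length_nt = NULL, total_reads = NULL,
                            scale = 1e9, poisson_noise = FALSE, seed = 1L) {
  abundance <- as_abundance_matrix(abundance)
  with_seed(seed, {
    if (is.null(length_nt))
      length_nt <- stats::setNames(
        sample(300:1200, nrow(abundance), replace = TRUE),
        rownames(abundance))
    if (is.null(total_reads))
      total_reads <- stats::setNames(
        round(stats::runif(ncol(abundance), 1e7, 5e7)),
        colnames(abundance))
    counts <- abundance *
      outer(as.numeric(length_nt[rownames(abundance)]),
            as.numeric(total_reads[colnames(abundance)])) / scale
    if (poisson_noise) {
      counts[] <- stats::rpois(length(counts), counts)
    }
    count_table(counts, length_nt, total_reads)
  })
}

#' Generate a complete synthetic data set with planted ground truth
#'
#' Bundles [generate_catalog()], [generate_env()],
#' [generate_abundances()] (on the planted families) and
#' [generate_counts()] under one seed, fanned out per component.
#'
#' @param n_families,family_size_range,divergence,n_dark_families,n_mags
#'   passed to [generate_catalog()].
#' @param n_samples,n_quant,n_qual,missing_fraction passed to
#'   [generate_env()].
#' @param n_linked,n_noise,n_near_constant,effect,snr passed to
#'   [make_link_spec()]; defaults mirror the calibration design of 20
#'   linked, 20 noise, and 5 near-constant clusters over 93 samples.
#' @param poisson_noise Poisson-resample the counts?
#' @param seed master seed.
#' @return list: `catalog`, `taxonomy`, `truth`, `env`, `abundance`
#'   (output of [generate_abundances()]), `counts` (a [count_table()]).
#' @export
simulate_dataset <- function(n_families = 45L, family_size_range = c(2L, 5L),
                             divergence = 0.05, n_dark_families = 4L,
                             n_mags = 10L, n_samples = 93L, n_quant = 10L,
                             n_qual = 4L, missing_fraction = 0.066,
                             n_linked = 20L, n_noise = 20L,
                             n_near_constant = 5L, effect = 1, snr = 3,
                             poisson_noise = FALSE, seed = 1L) {
  gc_ <- generate_catalog(n_mags = n_mags, n_families = n_families,
                          family_size_range = family_size_range,
                          divergence = divergence,
                          n_dark_families = n_dark_families,
                          seed = stage_seed(seed, "catalog"))
  env <- generate_env(n_samples = n_samples, n_quant = n_quant,
                      n_qual = n_qual, missing_fraction = missing_fraction,
                      seed = stage_seed(seed, "env"))
  fams <- gc_$truth$planted_families
  part <- structure(list(clusters = fams, singletons = character(0)),
                    class = "pfc_partition")
  # drivers must be complete for the planted response: use an NA-free
  # copy of the env drivers (column means fill)
  env_drv <- env
  for (v in names(env_drv)[is_quantitative(env_drv)]) {
    x <- env_drv[[v]]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    env_drv[[v]] <- x
  }
  drivers <- c(names(env)[is_quantitative(env)][1:3],
               names(env)[!is_quantitative(env)][1])
  spec <- make_link_spec(names(fams), drivers, n_linked = n_linked,
                         n_noise = n_noise,
                         n_near_constant = n_near_constant,
                         effect = effect, snr = snr)
  ab <- generate_abundances(part, env_drv, spec,
                            seed = stage_seed(seed, "abundance"))
  ct <- generate_counts(ab$protein_abundance,
                        poisson_noise = poisson_noise,
                        seed = stage_seed(seed, "counts"))
  list(catalog = gc_$catalog, taxonomy = gc_$taxonomy,
       truth = c(gc_$truth, list(link_spec = spec)),
       env = env, abundance = ab, counts = ct,
       partition = part)
}
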