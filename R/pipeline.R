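#' Pipeline configuration
#'
#' Either `simulate` (a list of [simulate_dataset()] arguments) or
#' `inputs` (paths: `fasta`, `annotations`, `taxonomy`, `gene_lengths`
#' (optional), `hits` (optional; computed desk-scale when absent),
#' `counts`, `count_gene_lengths`, `sample_totals`, `env`,
#' `env_qualitative` (column names)) must be supplied.
#'
#' @param outdir output directory.
#' @param seed master seed; every stage derives its own seed from it.
#' @param simulate list of [simulate_dataset()] arguments, or `NULL`.
#' @param inputs list of input paths, or `NULL`.
#' @param id_threshold,cov_threshold,coverage_mode network thresholds
#'   (defaults 80 / 80 / mutual coverage).
#' @param scale count-normalization scale (default 1e9).
#' @param prep a [prep_config()].
#' @param screen a [screen_config()] (its seed is overridden by the
#'   master seed fan-out).
#' @param n_perm permutations for the ordination test (default 199).
#' @param use_stepwise run AIC stepwise selection before the final
#'   ordination? (default TRUE).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1L, simulate = NULL,
                            inputs = NULL, id_threshold = 80,
                            cov_threshold = 80,
                            coverage_mode = "both", scale = 1e9,
                            prep = prep_config(),
                            screen = screen_config(),
                            n_perm = 199L, use_stepwise = TRUE) {
  if (is.null(simulate) && is.null(inputs))
    stop("pipeline_config needs either 'simulate' or 'inputs'")
  structure(list(outdir = outdir, seed = as.integer(seed),
                 simulate = simulate, inputs = inputs,
                 id_threshold = id_threshold,
                 cov_threshold = cov_threshold,
                 coverage_mode = coverage_mode, scale = scale,
                 prep = prep, screen = screen,
                 n_perm = as.integer(n_perm),
                 use_stepwise = isTRUE(use_stepwise)),
            class = "pipeline_config")
}

stage_fail <- function(stage, e) {
  stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
       call. = FALSE)
}

#' Run the full inference pipeline
#'
#' input -> similarity network -> clusters -> scores -> abundances ->
#' environment preparation -> random-forest screen -> constrained
#' ordination, writing one TSV per result table into `config$outdir`.
#' Identical config + seed give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)

  ## ---- stage: input -------------------------------------------------
  res <- tryCatch({
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      sim_args$seed <- stage_seed(config$seed, "simulate")
      sim <- do.call(simulate_dataset, sim_args)
      env_qual <- names(sim$env)[!is_quantitative(sim$env)]
      list(catalog = sim$catalog, taxonomy = sim$taxonomy,
           counts = sim$counts, env = sim$env, hits = NULL, sim = sim)
    } else {
      inp <- config$inputs
      for (p in c("fasta", "annotations", "taxonomy", "counts",
                  "count_gene_lengths", "sample_totals", "env"))
        if (is.null(inp[[p]]) || !file.exists(inp[[p]]))
          stop("missing input file '", p, "'")
      pc <- read_protein_catalog(inp$fasta, inp$annotations, inp$taxonomy,
                                 inp$gene_lengths)
      ct <- read_count_table(inp$counts, inp$count_gene_lengths,
                             inp$sample_totals)
      env <- read_env_table(inp$env,
                            qualitative = inp$env_qualitative %||% character(0))
      list(catalog = pc$catalog, taxonomy = pc$taxonomy, counts = ct,
           env = env, hits_path = inp$hits, sim = NULL)
    }
  }, error = function(e) stage_fail("input", e))

  ## ---- stage: ssn ---------------------------------------------------
  ssn <- tryCatch({
    hits <- if (!is.null(res$hits_path)) {
      if (!file.exists(res$hits_path))
        stop("hits file not found: ", res$hits_path)
      read_hits(res$hits_path, res$catalog)
    } else {
      all_vs_all_hits(res$catalog)
    }
    graph <- filter_hits(hits, config$id_threshold, config$cov_threshold,
                         config$coverage_mode)
    part <- extract_pfcs(graph, res$catalog$protein_id)
    edges <- as.data.frame(graph$edges, stringsAsFactors = FALSE)
    write_tsv(edges, out("ssn_edges.tsv"))
    write_tsv(pfc_membership(part), out("pfc_membership.tsv"))
    write_tsv(data.frame(protein_id = part$singletons), out("singletons.tsv"))
    list(hits = hits, graph = graph, partition = part)
  }, error = function(e) stage_fail("ssn", e))

  ## ---- stage: scoring -----------------------------------------------
  scores <- tryCatch({
    sc <- pfc_scores(ssn$partition, res$catalog, res$taxonomy)
    write_tsv(as.data.frame(sc), out("pfc_scores.tsv"))
    sc
  }, error = function(e) stage_fail("scoring", e))

  ## ---- stage: quantify ----------------------------------------------
  quant <- tryCatch({
    prot_ab <- normalize_counts(res$counts, scale = config$scale)
    clus_ab <- pfc_abundance(prot_ab, ssn$partition)
    write_matrix_tsv(prot_ab, out("protein_abundance.tsv"),
                     id_col = "protein_id")
    write_matrix_tsv(clus_ab, out("pfc_abundance.tsv"), id_col = "pfc_id")
    dark <- as.character(scores$pfc_id[scores$is_dark])
    dark_test <- NULL
    if (length(dark) >= 2 && nrow(clus_ab) - length(dark) >= 2) {
      dark_test <- dark_abundance_test(clus_ab, dark)
      write_tsv(dark_test, out("dark_abundance_test.tsv"))
    }
    list(protein_abundance = prot_ab, pfc_abundance = clus_ab,
         dark_test = dark_test)
  }, error = function(e) stage_fail("quantify", e))

  ## ---- stage: env_prep ----------------------------------------------
  envp <- tryCatch({
    pe <- prepare_env(res$env, config$prep)
    write_env_table(pe$env, out("env_prepared.tsv"))
    write_tsv(pe$removed, out("env_removed.tsv"))
    pe
  }, error = function(e) stage_fail("env_prep", e))

  ## ---- stage: screen ------------------------------------------------
  screen <- tryCatch({
    cfg <- config$screen
    cfg$seed <- stage_seed(config$seed, "screen")
    st <- screen_pfcs(quant$pfc_abundance, envp$env, cfg)
    write_tsv(st$results, out("screen_results.tsv"))
    write_matrix_tsv(st$importance, out("screen_importance.tsv"),
                     id_col = "pfc_id")
    write_tsv(aggregate_importance(st), out("importance_summary.tsv"))
    write_tsv(data.frame(pfc_id = st$nzv_removed), out("nzv_removed.tsv"))
    st
  }, error = function(e) stage_fail("screen", e))

  ## ---- stage: ordination --------------------------------------------
  ord <- tryCatch({
    sel <- screen$results$pfc_id[screen$results$category == "hle"]
    if (length(sel) < 3)
      sel <- screen$results$pfc_id[
        screen$results$category %in% c("hle", "linked")]
    if (length(sel) < 3) {
      write_tsv(data.frame(note = "fewer than 3 environment-linked clusters; ordination skipped"),
                out("ordination_skipped.tsv"))
      NULL
    } else {
      Y <- t(quant$pfc_abundance[as.character(sel), , drop = FALSE])
      X <- envp$env
      if (config$use_stepwise) {
        sw <- cca_stepwise(Y, X)
        if (length(sw$selected) >= 1)
          X <- X[, sw$selected, drop = FALSE]
        write_tsv(sw$trace, out("ordination_stepwise.tsv"))
      }
      fit <- fit_cca(Y, X)
      perm <- cca_permutation_test(Y, X, n_perm = config$n_perm,
                                   seed = stage_seed(config$seed, "ordination"))
      write_tsv(data.frame(axis = names(fit$eigenvalues),
                           eigenvalue = as.numeric(fit$eigenvalues)),
                out("ordination_eigenvalues.tsv"))
      write_matrix_tsv(fit$feature_scores, out("ordination_feature_scores.tsv"),
                       id_col = "pfc_id")
      write_matrix_tsv(fit$site_scores, out("ordination_site_scores.tsv"),
                       id_col = "sample_id")
      write_matrix_tsv(fit$biplot_scores, out("ordination_biplot_scores.tsv"),
                       id_col = "constraint")
      write_tsv(data.frame(total_inertia = fit$total_inertia,
                           constrained_inertia = fit$constrained_inertia,
                           perm_p = perm$p_value, n_perm = perm$n_perm),
                out("ordination_summary.tsv"))
      list(fit = fit, perm = perm)
    }
  }, error = function(e) stage_fail("ordination", e))

  invisible(list(input = res, ssn = ssn, scores = scores, quantify = quant,
                 env_prep = envp, screen = screen, ordination = ord))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
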