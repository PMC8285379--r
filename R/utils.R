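# Seed fan-out: the master seed plus a stage-name hash gives each pipeline
# stage its own reproducible stream, so stages can be rerun independently.
stage_seed <- function(master_seed, stage) {
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 1000003
  as.integer((as.numeric(master_seed) + h * 1009) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

squared_pearson <- function(pred, obs) {
  if (length(pred) < 2 || stats::sd(pred) == 0 || stats::sd(obs) == 0)
    return(NA_real_)
  stats::cor(pred, obs)^2
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "", ...)
}

# matrices travel as TSV with a leading id column
write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
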