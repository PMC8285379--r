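AA_ALPHABET20 <- c("A","R","N","D","C","Q","E","G","H","I",
                   "L","K","M","F","P","S","T","W","Y","V")

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Construct a protein catalog
#'
#' A protein catalog is a data frame with one row per predicted protein:
#' its identifier, amino-acid sequence, source genome (MAG), gene length in
#' nucleotides, and annotation term sets (KEGG orthologs, KEGG pathways,
#' eggNOG descriptions) stored as list columns.  Proteins with empty
#' annotation sets are "unannotated", never missing rows.
#'
#' @param protein_id character vector of unique protein identifiers.
#' @param sequence amino-acid sequences (20-letter alphabet plus X).
#' @param mag_id source genome identifier per protein.
#' @param gene_length_nt gene length in nucleotides (>= 3).
#' @param kegg_ids,kegg_pathways,eggnog_terms list of character vectors
#'   (one per protein, possibly empty).
#' @return a `protein_catalog` data frame.
#' @export
protein_catalog <- function(protein_id, sequence, mag_id, gene_length_nt,
                            kegg_ids = NULL, kegg_pathways = NULL,
                            eggnog_terms = NULL) {
  n <- length(protein_id)
  empty <- replicate(n, character(0), simplify = FALSE)
  if (is.null(kegg_ids)) kegg_ids <- empty
  if (is.null(kegg_pathways)) kegg_pathways <- empty
  if (is.null(eggnog_terms)) eggnog_terms <- empty
  cat_df <- data.frame(protein_id = as.character(protein_id),
                       mag_id = as.character(mag_id),
                       gene_length_nt = as.integer(gene_length_nt),
                       sequence = as.character(sequence),
                       stringsAsFactors = FALSE)
  cat_df$kegg_ids <- kegg_ids
  cat_df$kegg_pathways <- kegg_pathways
  cat_df$eggnog_terms <- eggnog_terms
  class(cat_df) <- c("protein_catalog", "data.frame")
  validate_protein_catalog(cat_df)
}

validate_protein_catalog <- function(x) {
  if (anyDuplicated(x$protein_id))
    stop("duplicate protein_id in catalog: ",
         paste(unique(x$protein_id[duplicated(x$protein_id)]), collapse = ", "))
  if (any(x$gene_length_nt < 3L))
    stop("gene_length_nt must be >= 3")
  if (any(!nzchar(x$sequence)))
    stop("empty protein sequence in catalog")
  bad <- grepl(paste0("[^", paste(c(AA_ALPHABET20, "X"), collapse = ""), "]"),
               x$sequence)
  if (any(bad))
    stop("sequence with characters outside the amino-acid alphabet: ",
         paste(utils::head(x$protein_id[bad], 3), collapse = ", "))
  x
}

#' Construct a MAG taxonomy table
#'
#' One row per MAG with the six ranks domain..genus.  A rank may be
#' "unannotated" only if every lower rank is too (taxonomy is assigned
#' top-down from single-copy core genes).
#'
#' @param mag_id MAG identifiers.
#' @param domain,phylum,class,order,family,genus rank names or "unannotated".
#' @return a `mag_taxonomy` data frame.
#' @export
mag_taxonomy <- function(mag_id, domain, phylum = "unannotated",
                         class = "unannotated", order = "unannotated",
                         family = "unannotated", genus = "unannotated") {
  tx <- data.frame(mag_id = as.character(mag_id),
                   domain = as.character(domain),
                   phylum = as.character(phylum),
                   class = as.character(class),
                   order = as.character(order),
                   family = as.character(family),
                   genus = as.character(genus),
                   stringsAsFactors = FALSE)
  class(tx) <- c("mag_taxonomy", "data.frame")
  validate_mag_taxonomy(tx)
}

validate_mag_taxonomy <- function(x) {
  if (anyDuplicated(x$mag_id)) stop("duplicate mag_id in taxonomy")
  if (any(x$domain == "unannotated"))
    stop("domain rank must always be annotated")
  m <- as.matrix(x[, TAX_RANKS])
  for (i in seq_len(nrow(m))) {
    una <- m[i, ] == "unannotated"
    if (any(una) && !all(una[which(una)[1]:length(una)]))
      stop("rank 'unannotated' above an annotated rank for MAG ", x$mag_id[i])
  }
  x
}

#' Construct a similarity-hit table
#'
#' @param query_id,subject_id protein identifiers (no self hits).
#' @param pident percent identity in \[0, 100\].
#' @param cov_query,cov_subject percent of each sequence covered by the
#'   alignment, in \[0, 100\].
#' @return a `similarity_hits` data frame.
#' @export
similarity_hits <- function(query_id, subject_id, pident,
                            cov_query, cov_subject) {
  h <- data.frame(query_id = as.character(query_id),
                  subject_id = as.character(subject_id),
                  pident = as.numeric(pident),
                  cov_query = as.numeric(cov_query),
                  cov_subject = as.numeric(cov_subject),
                  stringsAsFactors = FALSE)
  if (any(h$query_id == h$subject_id)) stop("self-hit present in hit table")
  rng <- c(h$pident, h$cov_query, h$cov_subject)
  if (any(rng < 0 | rng > 100)) stop("pident/coverage outside [0, 100]")
  class(h) <- c("similarity_hits", "data.frame")
  h
}

#' Validate an abundance matrix
#'
#' An abundance matrix is a plain numeric matrix, features (proteins or
#' PFCs) in rows, samples in columns, with complete non-negative entries
#' and dimnames on both margins.
#'
#' @param x numeric matrix.
#' @return `x`, invisibly checked.
#' @export
as_abundance_matrix <- function(x) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("abundance matrix needs feature and sample names")
  if (anyNA(x)) stop("abundance matrix has missing entries")
  if (any(x < 0)) stop("abundance matrix has negative entries")
  storage.mode(x) <- "double"
  x
}

#' Construct an environment table
#'
#' Samples in rows (rownames), variables in columns.  Numeric columns are
#' quantitative (may contain NA before imputation); character columns are
#' coerced to factors and treated as qualitative.
#'
#' @param df data frame of environmental variables with sample rownames.
#' @return an `env_table` data frame.
#' @export
env_table <- function(df) {
  df <- as.data.frame(df)
  if (is.null(rownames(df)) || all(rownames(df) == as.character(seq_len(nrow(df)))))
    stop("env_table needs sample identifiers as rownames")
  for (j in seq_along(df)) {
    if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
    if (!is.numeric(df[[j]]) && !is.factor(df[[j]]))
      stop("column ", names(df)[j], " is neither quantitative nor qualitative")
    if (is.factor(df[[j]]) && anyNA(df[[j]]))
      stop("qualitative column ", names(df)[j], " has missing levels")
  }
  class(df) <- c("env_table", "data.frame")
  df
}

#' Which environment variables are quantitative?
#' @param env an `env_table`.
#' @return logical vector, one per column.
#' @export
is_quantitative <- function(env) vapply(env, is.numeric, logical(1))
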