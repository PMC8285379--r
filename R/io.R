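#' Read a protein catalog from FASTA plus annotation and taxonomy tables
#'
#' FASTA headers follow the compound convention `mag_id|protein_id`
#' (delimiter configurable).  The annotation TSV is keyed by `protein_id`
#' with columns `kegg_ids`, `kegg_pathways`, `eggnog_terms` holding
#' semicolon-separated term lists (empty string = unannotated).  Proteins
#' absent from the annotation table get empty annotation sets.  The
#' taxonomy TSV must cover every MAG referenced by the FASTA.
#'
#' @param fasta_path amino-acid FASTA file.
#' @param annotation_tsv_path per-protein annotation TSV; `NULL` for a
#'   fully unannotated catalog.
#' @param taxonomy_tsv_path per-MAG taxonomy TSV (columns mag_id,
#'   domain..genus).
#' @param gene_length_tsv_path optional TSV (protein_id, gene_length_nt);
#'   when absent, lengths default to 3*(aa length + 1) (codons + stop).
#' @param id_delim delimiter between mag_id and protein_id in headers.
#' @return list with elements `catalog` (a [protein_catalog()]) and
#'   `taxonomy` (a [mag_taxonomy()] table).
#' @export
read_protein_catalog <- function(fasta_path, annotation_tsv_path = NULL,
                                 taxonomy_tsv_path = NULL,
                                 gene_length_tsv_path = NULL,
                                 id_delim = "|") {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  headers <- names(seqs)
  parts <- strsplit(headers, id_delim, fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("FASTA header not in 'mag_id", id_delim, "protein_id' form: ",
         headers[which(lengths(parts) != 2)[1]])
  mag_id <- vapply(parts, `[[`, "", 1)
  protein_id <- vapply(parts, `[[`, "", 2)
  if (anyDuplicated(protein_id))
    stop("duplicate protein_id in FASTA: ",
         protein_id[duplicated(protein_id)][1])

  len_nt <- 3L * (Biostrings::width(seqs) + 1L)
  if (!is.null(gene_length_tsv_path)) {
    lt <- read_tsv(gene_length_tsv_path)
    idx <- match(protein_id, lt$protein_id)
    if (anyNA(idx)) stop("gene length missing for protein ",
                         protein_id[which(is.na(idx))[1]])
    len_nt <- as.integer(lt$gene_length_nt[idx])
  }

  split_terms <- function(x) {
    x[is.na(x)] <- ""
    lapply(strsplit(x, ";", fixed = TRUE),
           function(v) v[nzchar(v)])
  }
  n <- length(protein_id)
  kid <- kpw <- egg <- replicate(n, character(0), simplify = FALSE)
  if (!is.null(annotation_tsv_path)) {
    an <- read_tsv(annotation_tsv_path,
                   colClasses = "character")
    if (nrow(an) > 0) {
      idx <- match(protein_id, an$protein_id)
      hit <- !is.na(idx)
      kid[hit] <- split_terms(an$kegg_ids[idx[hit]])
      kpw[hit] <- split_terms(an$kegg_pathways[idx[hit]])
      egg[hit] <- split_terms(an$eggnog_terms[idx[hit]])
    }
  }

  cat_df <- protein_catalog(protein_id, as.character(seqs), mag_id, len_nt,
                            kid, kpw, egg)

  taxonomy <- NULL
  if (!is.null(taxonomy_tsv_path)) {
    tx <- read_tsv(taxonomy_tsv_path, colClasses = "character")
    taxonomy <- mag_taxonomy(tx$mag_id, tx$domain, tx$phylum, tx$class,
                             tx$order, tx$family, tx$genus)
    missing_mag <- setdiff(unique(mag_id), taxonomy$mag_id)
    if (length(missing_mag))
      stop("taxonomy row missing for MAG(s): ",
           paste(missing_mag, collapse = ", "))
  }
  list(catalog = cat_df, taxonomy = taxonomy)
}

#' Read pairwise hits from BLAST/DIAMOND tabular output
#'
#' Consumes the 12-column tabular dialect (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore).  Per-side
#' coverages are derived from alignment length and the catalog's sequence
#' lengths as `length / seq_length * 100`.  Self hits are dropped and
#' reciprocal duplicates collapsed to one undirected hit keeping the
#' maximum percent identity.
#'
#' @param tabular_path path to the tabular hit file (no header).
#' @param catalog a [protein_catalog()] supplying sequence lengths.
#' @return a [similarity_hits()] data frame.
#' @export
read_hits <- function(tabular_path, catalog) {
  raw <- tryCatch(
    utils::read.table(tabular_path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE,
                      col.names = c("qseqid", "sseqid", "pident", "length",
                                    "mismatch", "gapopen", "qstart", "qend",
                                    "sstart", "send", "evalue", "bitscore"),
                      colClasses = c("character", "character", rep("numeric", 10))),
    error = function(e) stop("malformed hit table ", tabular_path, ": ",
                             conditionMessage(e)))
  if (ncol(raw) != 12) stop("expected 12 tabular columns, got ", ncol(raw))
  bad <- which(is.na(raw$pident) | is.na(raw$length))
  if (length(bad)) stop("malformed hit row at line ", bad[1])

  keep <- raw$qseqid != raw$sseqid
  raw <- raw[keep, , drop = FALSE]
  if (nrow(raw) == 0)
    return(similarity_hits(character(0), character(0), numeric(0),
                           numeric(0), numeric(0)))

  seq_len_aa <- nchar(catalog$sequence)
  names(seq_len_aa) <- catalog$protein_id
  unknown <- setdiff(unique(c(raw$qseqid, raw$sseqid)), names(seq_len_aa))
  if (length(unknown))
    stop("hit references protein absent from catalog: ", unknown[1])

  cov_q <- raw$length / seq_len_aa[raw$qseqid] * 100
  cov_s <- raw$length / seq_len_aa[raw$sseqid] * 100

  # undirected pair key; keep the best-identity hit per pair
  a <- pmin(raw$qseqid, raw$sseqid)
  b <- pmax(raw$qseqid, raw$sseqid)
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -raw$pident)
  first <- !duplicated(key[ord])
  sel <- ord[first]

  similarity_hits(raw$qseqid[sel], raw$sseqid[sel], raw$pident[sel],
                  pmin(cov_q[sel], 100), pmin(cov_s[sel], 100))
}

#' Write a protein catalog's FASTA and side tables
#'
#' Inverse of [read_protein_catalog()]: emits the FASTA (headers
#' `mag_id|protein_id`), the annotation TSV (semicolon-joined term sets),
#' the gene-length TSV and, when given, the taxonomy TSV.
#'
#' @param catalog a [protein_catalog()].
#' @param taxonomy a [mag_taxonomy()] or `NULL`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_protein_catalog <- function(catalog, taxonomy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "proteins.faa")
  seqs <- Biostrings::AAStringSet(catalog$sequence)
  names(seqs) <- paste(catalog$mag_id, catalog$protein_id, sep = "|")
  Biostrings::writeXStringSet(seqs, fasta, width = 80L)

  join <- function(l) vapply(l, paste, "", collapse = ";")
  ann <- data.frame(protein_id = catalog$protein_id,
                    kegg_ids = join(catalog$kegg_ids),
                    kegg_pathways = join(catalog$kegg_pathways),
                    eggnog_terms = join(catalog$eggnog_terms),
                    stringsAsFactors = FALSE)
  ann_path <- file.path(dir, "annotations.tsv")
  write_tsv(ann, ann_path)

  len_path <- file.path(dir, "gene_lengths.tsv")
  write_tsv(data.frame(protein_id = catalog$protein_id,
                       gene_length_nt = catalog$gene_length_nt), len_path)

  out <- c(fasta = fasta, annotations = ann_path, gene_lengths = len_path)
  if (!is.null(taxonomy)) {
    tax_path <- file.path(dir, "taxonomy.tsv")
    write_tsv(as.data.frame(taxonomy), tax_path)
    out <- c(out, taxonomy = tax_path)
  }
  out
}

#' Read and write environment tables
#'
#' The TSV carries samples in rows (first column `sample_id`); a companion
#' `#types` comment is avoided by declaring qualitative columns explicitly.
#'
#' @param path TSV path.
#' @param qualitative character vector naming the qualitative columns.
#' @return an [env_table()].
#' @export
read_env_table <- function(path, qualitative = character(0)) {
  df <- read_tsv(path)
  rownames(df) <- df$sample_id
  df$sample_id <- NULL
  for (v in qualitative) df[[v]] <- factor(df[[v]])
  for (v in setdiff(names(df), qualitative)) df[[v]] <- as.numeric(df[[v]])
  env_table(df)
}

#' @rdname read_env_table
#' @param env an [env_table()].
#' @export
write_env_table <- function(env, path) {
  df <- data.frame(sample_id = rownames(env), as.data.frame(env),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read and write count tables
#'
#' A count table is a list with `counts` (genes x samples matrix),
#' `length_nt` (named per-gene vector) and `total_reads` (named per-sample
#' vector of total sequenced reads, mapped + unmapped).
#'
#' @param counts_path genes x samples TSV (first column `gene_id`).
#' @param lengths_path TSV (gene_id, length_nt).
#' @param totals_path TSV (sample_id, total_reads).
#' @return a `count_table` list.
#' @export
read_count_table <- function(counts_path, lengths_path, totals_path) {
  counts <- read_matrix_tsv(counts_path)
  lt <- read_tsv(lengths_path)
  tt <- read_tsv(totals_path)
  length_nt <- stats::setNames(as.numeric(lt$length_nt), lt$gene_id)
  total_reads <- stats::setNames(as.numeric(tt$total_reads), tt$sample_id)
  count_table(counts, length_nt, total_reads)
}

#' @rdname read_count_table
#' @param ct a `count_table` list.
#' @param dir output directory.
#' @export
write_count_table <- function(ct, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cp <- file.path(dir, "counts.tsv")
  write_matrix_tsv(ct$counts, cp, id_col = "gene_id")
  lp <- file.path(dir, "gene_lengths.tsv")
  write_tsv(data.frame(gene_id = names(ct$length_nt),
                       length_nt = ct$length_nt), lp)
  tp <- file.path(dir, "sample_totals.tsv")
  write_tsv(data.frame(sample_id = names(ct$total_reads),
                       total_reads = ct$total_reads), tp)
  c(counts = cp, gene_lengths = lp, sample_totals = tp)
}

#' Assemble a count table
#'
#' @param counts non-negative genes x samples matrix (fractional counts
#'   from probabilistic read assignment are allowed).
#' @param length_nt named per-gene length vector (nucleotides, > 0).
#' @param total_reads named per-sample total sequenced reads (> 0).
#' @return a `count_table` list.
#' @export
count_table <- function(counts, length_nt, total_reads) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (!all(rownames(counts) %in% names(length_nt)))
    stop("length_nt missing for some genes")
  if (!all(colnames(counts) %in% names(total_reads)))
    stop("total_reads missing for some samples")
  if (any(total_reads[colnames(counts)] <= 0)) stop("non-positive sample total")
  structure(list(counts = counts,
                 length_nt = length_nt[rownames(counts)],
                 total_reads = total_reads[colnames(counts)]),
            class = "count_table")
}
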