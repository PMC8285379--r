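#' Length- and sequencing-depth-normalized gene abundance
#'
#' `abundance[g, s] = count[g, s] / (length_nt[g] * total_reads[s]) * scale`.
#' Unlike TPM, the denominator uses the *total sequenced* reads of the
#' sample (mapped + unmapped), which keeps abundances comparable across
#' environmental samples whose mapping rates differ widely.  The default
#' scale of 1e9 plays the role TPM's 1e6 plays for within-tissue data.
#' Gene lengths are in nucleotides.
#'
#' @param ct a [count_table()].
#' @param scale multiplicative scale factor (default 1e9).
#' @return protein/gene x sample abundance matrix.
#' @export
normalize_counts <- function(ct, scale = 1e9) {
  stopifnot(inherits(ct, "count_table"))
  len <- ct$length_nt
  tot <- ct$total_reads
  if (any(is.na(len) | len <= 0))
    stop("non-positive gene length for gene ",
         rownames(ct$counts)[which(is.na(len) | len <= 0)[1]])
  if (any(is.na(tot) | tot <= 0))
    stop("non-positive read total for sample ",
         colnames(ct$counts)[which(is.na(tot) | tot <= 0)[1]])
  ab <- ct$counts / outer(as.numeric(len), as.numeric(tot)) * scale
  as_abundance_matrix(ab)
}

#' Mean abundance per cluster
#'
#' The abundance of a PFC in a sample is the arithmetic mean of its member
#' proteins' abundances in that sample.
#'
#' @param protein_abundance protein x sample abundance matrix.
#' @param part a `pfc_partition`.
#' @return cluster x sample abundance matrix (rownames = cluster IDs).
#' @export
pfc_abundance <- function(protein_abundance, part) {
  protein_abundance <- as_abundance_matrix(protein_abundance)
  missing <- setdiff(unlist(part$clusters, use.names = FALSE),
                     rownames(protein_abundance))
  if (length(missing))
    stop("cluster member absent from abundance matrix: ", missing[1])
  rows <- vapply(part$clusters, function(members)
    colMeans(protein_abundance[members, , drop = FALSE]),
    numeric(ncol(protein_abundance)))
  out <- t(rows)
  rownames(out) <- names(part$clusters)
  as_abundance_matrix(out)
}
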