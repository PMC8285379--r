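#' Functional homogeneity of a protein cluster
#'
#' With N_prot the number of member proteins (annotated or not) and
#' N_annot the number of unique annotation terms carried by the members,
#' the score is 1 when a single unique term is shared, 1 - N_annot/N_prot
#' when several distinct terms occur (floored at 0 so multi-term proteins
#' cannot push it negative), and missing (`NA`) when no member carries any
#' term in the database under consideration.
#'
#' @param annotation_terms_per_protein list with one (possibly empty)
#'   character vector of terms per member protein.
#' @return a score in \[0, 1\], or `NA_real_` when the cluster is fully
#'   unannotated in this database.
#' @export
functional_homogeneity <- function(annotation_terms_per_protein) {
  n_prot <- length(annotation_terms_per_protein)
  if (n_prot < 2) stop("a PFC has at least 2 proteins; got ", n_prot)
  terms <- unique(unlist(annotation_terms_per_protein, use.names = FALSE))
  terms <- terms[!is.na(terms) & nzchar(terms)]
  n_annot <- length(terms)
  if (n_annot == 0) return(NA_real_)
  if (n_annot == 1) return(1)
  max(0, 1 - n_annot / n_prot)
}

#' Per-rank taxonomy profile of a cluster
#'
#' For each rank phylum..genus: is the cluster associated with a single
#' taxon among its members annotated at that rank (`NA` when no member
#' is), and how many members are annotated there.  Also reports whether
#' the cluster mixes the Archaea and Bacteria domains.
#'
#' @param member_mags character vector of member MAG IDs (one per protein).
#' @param taxonomy a [mag_taxonomy()] table covering those MAGs.
#' @return list with `ranks` (data frame: rank, single_taxon,
#'   n_annotated_proteins) and `mixes_domains` (logical).
#' @export
taxonomy_profile <- function(member_mags, taxonomy) {
  idx <- match(member_mags, taxonomy$mag_id)
  if (anyNA(idx))
    stop("MAG without taxonomy: ", member_mags[which(is.na(idx))[1]])
  sub <- taxonomy[idx, , drop = FALSE]
  ranks <- setdiff(TAX_RANKS, "domain")
  single <- logical(length(ranks))
  n_ann <- integer(length(ranks))
  for (i in seq_along(ranks)) {
    vals <- sub[[ranks[i]]]
    ann <- vals != "unannotated"
    n_ann[i] <- sum(ann)
    single[i] <- if (n_ann[i] == 0) NA else length(unique(vals[ann])) == 1
  }
  doms <- unique(sub$domain)
  list(ranks = data.frame(rank = ranks, single_taxon = single,
                          n_annotated_proteins = n_ann,
                          stringsAsFactors = FALSE),
       mixes_domains = all(c("Archaea", "Bacteria") %in% doms))
}

#' Score every cluster of a partition
#'
#' Computes, per PFC: size, functional homogeneity in the KEGG and eggNOG
#' databases, a homogeneity tag (`low_05` / `low_08` when the score falls
#' below 0.5 / 0.8 in *both* databases; tagging never excludes a cluster),
#' per-rank taxonomy homogeneity, and the dark flag (see
#' [classify_dark()]).
#'
#' @param part a `pfc_partition` from [extract_pfcs()].
#' @param catalog a [protein_catalog()].
#' @param taxonomy a [mag_taxonomy()] table.
#' @return a `pfc_scores` data frame, one row per cluster.
#' @export
pfc_scores <- function(part, catalog, taxonomy) {
  row_of <- stats::setNames(seq_len(nrow(catalog)), catalog$protein_id)
  score_one <- function(members) {
    ri <- row_of[members]
    f_kegg <- functional_homogeneity(catalog$kegg_ids[ri])
    f_egg <- functional_homogeneity(catalog$eggnog_terms[ri])
    prof <- taxonomy_profile(catalog$mag_id[ri], taxonomy)
    tag <- homogeneity_tag(f_kegg, f_egg)
    dark <- classify_dark(f_kegg, f_egg, catalog$mag_id[ri], taxonomy)
    st <- prof$ranks$single_taxon
    names(st) <- paste0("single_", prof$ranks$rank)
    na_ <- prof$ranks$n_annotated_proteins
    names(na_) <- paste0("n_annot_", prof$ranks$rank)
    c(list(n_prot = length(members), f_hom_kegg = f_kegg,
           f_hom_eggnog = f_egg, homogeneity_tag = tag,
           mixes_domains = prof$mixes_domains, is_dark = dark),
      as.list(st), as.list(na_))
  }
  rows <- lapply(part$clusters, score_one)
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out <- cbind(data.frame(pfc_id = as.integer(names(part$clusters))), out)
  rownames(out) <- NULL
  class(out) <- c("pfc_scores", "data.frame")
  out
}

homogeneity_tag <- function(f_kegg, f_eggnog) {
  defined <- c(f_kegg, f_eggnog)
  defined <- defined[!is.na(defined)]
  if (length(defined) < 2) return("ok")
  if (all(defined < 0.5)) return("low_05")
  if (all(defined < 0.8)) return("low_08")
  "ok"
}

#' Is a cluster "dark"?
#'
#' Dark clusters carry no functional annotation in either database and no
#' member has taxonomy below the phylum level (class..genus all
#' unannotated).
#'
#' @param f_hom_kegg,f_hom_eggnog homogeneity scores (`NA` = database
#'   fully unannotated for this cluster).
#' @param member_mags member MAG IDs.
#' @param taxonomy a [mag_taxonomy()] table.
#' @return logical.
#' @export
classify_dark <- function(f_hom_kegg, f_hom_eggnog, member_mags, taxonomy) {
  if (!is.na(f_hom_kegg) || !is.na(f_hom_eggnog)) return(FALSE)
  idx <- match(member_mags, taxonomy$mag_id)
  sub <- taxonomy[idx, c("class", "order", "family", "genus"), drop = FALSE]
  all(as.matrix(sub) == "unannotated")
}

#' Compare dark-cluster abundances with all other clusters, per sample
#'
#' For each sample, a two-sided Wilcoxon rank-sum test of the dark
#' clusters' abundances against all other clusters' abundances, with
#' group medians.  A degenerate sample whose values are all identical is
#' reported with p = 1 and flagged.
#'
#' @param pfc_abundance cluster x sample abundance matrix.
#' @param dark_ids rownames of the dark clusters.
#' @return data frame, one row per sample: `p_value`, `dark_median`,
#'   `other_median`, `degenerate`.
#' @export
dark_abundance_test <- function(pfc_abundance, dark_ids) {
  pfc_abundance <- as_abundance_matrix(pfc_abundance)
  dark_ids <- as.character(dark_ids)
  if (!all(dark_ids %in% rownames(pfc_abundance)))
    stop("dark cluster absent from abundance matrix")
  other_ids <- setdiff(rownames(pfc_abundance), dark_ids)
  if (length(dark_ids) < 2 || length(other_ids) < 2)
    stop("need at least 2 dark and 2 non-dark clusters")
  res <- lapply(colnames(pfc_abundance), function(s) {
    d <- pfc_abundance[dark_ids, s]
    o <- pfc_abundance[other_ids, s]
    degenerate <- length(unique(c(d, o))) == 1
    p <- if (degenerate) 1 else
      suppressWarnings(stats::wilcox.test(d, o, alternative = "two.sided",
                                          exact = NULL)$p.value)
    data.frame(sample_id = s, p_value = p,
               dark_median = stats::median(d),
               other_median = stats::median(o),
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
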