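#' Build a sequence similarity network from filtered hits
#'
#' An edge joins two proteins when the hit between them reaches both the
#' identity threshold and the coverage threshold.  The classic 80/80 rule
#' never states which side's coverage it constrains; the default here is
#' the conservative mutual-coverage reading (both sides must reach the
#' threshold), switchable to `"query"` or `"either"` for sensitivity
#' checks.  Comparisons are inclusive (>=).
#'
#' @param hits a [similarity_hits()] table.
#' @param id_threshold percent identity threshold in (0, 100].
#' @param cov_threshold percent coverage threshold in (0, 100].
#' @param coverage_mode one of `"both"`, `"query"`, `"either"`.
#' @return an `ssn_graph`: list with `edges` (two-column character matrix
#'   of unordered pairs) and `nodes` (sorted protein IDs with >= 1 edge).
#' @export
filter_hits <- function(hits, id_threshold = 80, cov_threshold = 80,
                        coverage_mode = c("both", "query", "either")) {
  coverage_mode <- match.arg(coverage_mode)
  stopifnot(id_threshold > 0, id_threshold <= 100,
            cov_threshold > 0, cov_threshold <= 100)
  cov_ok <- switch(coverage_mode,
                   both = pmin(hits$cov_query, hits$cov_subject) >= cov_threshold,
                   query = hits$cov_query >= cov_threshold,
                   either = pmax(hits$cov_query, hits$cov_subject) >= cov_threshold)
  keep <- hits$pident >= id_threshold & cov_ok
  a <- pmin(hits$query_id[keep], hits$subject_id[keep])
  b <- pmax(hits$query_id[keep], hits$subject_id[keep])
  dup <- duplicated(paste(a, b, sep = "\r"))
  edges <- cbind(a[!dup], b[!dup])
  colnames(edges) <- c("protein_a", "protein_b")
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges)))),
            class = "ssn_graph")
}

#' Extract protein functional clusters from a similarity network
#'
#' Connected components with at least two proteins become PFCs; every
#' other catalog protein is a singleton.  Clusters are numbered 1..k in
#' the lexicographic order of their smallest member ID, which makes the
#' numbering deterministic.
#'
#' @param graph an `ssn_graph` from [filter_hits()].
#' @param all_proteins character vector of every catalog protein ID
#'   (a superset of the graph's nodes).
#' @return a `pfc_partition`: list with `clusters` (list of sorted member
#'   ID vectors, names "1".."k") and `singletons` (sorted ID vector).
#' @export
extract_pfcs <- function(graph, all_proteins) {
  all_proteins <- as.character(all_proteins)
  if (!all(graph$nodes %in% all_proteins))
    stop("graph contains proteins absent from the catalog")
  if (nrow(graph$edges) == 0) {
    part <- list(clusters = stats::setNames(list(), character(0)),
                 singletons = sort(all_proteins))
  } else {
    g <- igraph::graph_from_edgelist(graph$edges, directed = FALSE)
    comp <- igraph::components(g)
    member_of <- split(igraph::V(g)$name, comp$membership)
    member_of <- lapply(member_of, sort)
    # components from an edge list always have >= 2 members
    ord <- order(vapply(member_of, `[[`, "", 1))
    clusters <- member_of[ord]
    names(clusters) <- as.character(seq_along(clusters))
    part <- list(clusters = clusters,
                 singletons = sort(setdiff(all_proteins, unlist(clusters))))
  }
  class(part) <- "pfc_partition"
  validate_pfc_partition(part, all_proteins)
}

validate_pfc_partition <- function(part, all_proteins) {
  members <- unlist(part$clusters, use.names = FALSE)
  if (anyDuplicated(members)) stop("clusters are not disjoint")
  if (any(lengths(part$clusters) < 2)) stop("cluster with fewer than 2 members")
  covered <- c(members, part$singletons)
  if (length(covered) != length(all_proteins) ||
      !setequal(covered, all_proteins))
    stop("clusters plus singletons do not partition the catalog")
  part
}

#' Membership table of a PFC partition
#' @param part a `pfc_partition`.
#' @return data frame (protein_id, pfc_id), singletons excluded.
#' @export
pfc_membership <- function(part) {
  data.frame(protein_id = unlist(part$clusters, use.names = FALSE),
             pfc_id = rep(as.integer(names(part$clusters)),
                          lengths(part$clusters)),
             stringsAsFactors = FALSE)
}

#' Desk-scale pairwise local alignment
#'
#' Smith-Waterman local alignment of two amino-acid sequences (BLOSUM62,
#' affine gaps, open 11 / extend 1 by default), reported in the same terms
#' as a tabular search hit: percent identity over alignment columns and
#' per-side coverage of the aligned span.  Intended for small catalogs
#' where no external all-vs-all search output is available.
#'
#' @param seq_a,seq_b amino-acid strings.
#' @param id_a,id_b identifiers used in the returned hit.
#' @param substitution_matrix name of a Biostrings substitution matrix.
#' @param gap_opening,gap_extension affine gap penalties (positive costs).
#' @return a one-row [similarity_hits()] table, or `NULL` when no local
#'   alignment scores above zero.
#' @export
align_pair <- function(seq_a, seq_b, id_a = "a", id_b = "b",
                       substitution_matrix = "BLOSUM62",
                       gap_opening = 11, gap_extension = 1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  mat <- get(utils::data(list = substitution_matrix,
                         package = "Biostrings",
                         envir = environment()))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_opening, gapExtension = gap_extension)
  if (Biostrings::score(pa) <= 0) return(NULL)
  ncol_aln <- nchar(as.character(Biostrings::alignedPattern(pa)))
  pident <- Biostrings::nmatch(pa) / ncol_aln * 100
  span_a <- Biostrings::width(Biostrings::pattern(pa))
  span_b <- Biostrings::width(Biostrings::subject(pa))
  similarity_hits(id_a, id_b, pident,
                  span_a / nchar(seq_a) * 100,
                  span_b / nchar(seq_b) * 100)
}

#' All-vs-all hits for a small catalog
#'
#' Runs [align_pair()] over every unordered protein pair; a fallback for
#' desk-scale inputs in place of an external all-vs-all search.
#'
#' @param catalog a [protein_catalog()].
#' @inheritParams align_pair
#' @return a [similarity_hits()] table.
#' @export
all_vs_all_hits <- function(catalog, substitution_matrix = "BLOSUM62",
                            gap_opening = 11, gap_extension = 1) {
  n <- nrow(catalog)
  out <- vector("list", n * (n - 1) / 2)
  k <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      h <- align_pair(catalog$sequence[i], catalog$sequence[j],
                      catalog$protein_id[i], catalog$protein_id[j],
                      substitution_matrix, gap_opening, gap_extension)
      if (!is.null(h)) {
        k <- k + 1
        out[[k]] <- h
      }
    }
  }
  if (k == 0)
    return(similarity_hits(character(0), character(0), numeric(0),
                           numeric(0), numeric(0)))
  do.call(rbind, out[seq_len(k)])
}
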