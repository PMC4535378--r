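#' Classify LTR sequences into families (80-80-80 rule)
#'
#' Builds the graph whose edges join LTR pairs with global-alignment
#' identity at least `id_threshold` over at least `cov_threshold` of the
#' shorter LTR, and returns its single-linkage connected components as
#' families. Families are numbered 1..n by descending member count, ties
#' broken by the lexicographically smallest member id.
#'
#' @param ltr_seqs named character vector of LTR sequences (names are
#'   member ids; defaults to `seq1..seqN`).
#' @param id_threshold minimum pairwise identity (default 0.80).
#' @param cov_threshold minimum aligned fraction of the shorter LTR
#'   (default 0.80).
#' @return Data frame with columns `member_id`, `family_index`, and
#'   attribute `n_families`.
#' @export
assign_families <- function(ltr_seqs, id_threshold = 0.80,
                            cov_threshold = 0.80) {
  n <- length(ltr_seqs)
  if (n < 1) stop("need >= 1 sequence")
  ids <- names(ltr_seqs)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_len(n))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (n > 1) {
    pairs <- combn(n, 2)
    keep <- apply(pairs, 2, function(ij) {
      aln <- align_pair_global(ltr_seqs[ij[1]], ltr_seqs[ij[2]])
      aln$identity >= id_threshold && .alignment_coverage(aln) >= cov_threshold
    })
    if (any(keep))
      g <- igraph::add_edges(g, as.vector(pairs[, keep, drop = FALSE]))
  }
  comp <- igraph::components(g)$membership
  # order components by size desc, then smallest member id
  size <- tabulate(comp)
  min_id <- vapply(seq_along(size), function(k) min(ids[comp == k]),
                   character(1))
  ord <- order(-size, min_id)
  rank <- match(comp, ord)
  out <- data.frame(member_id = ids, family_index = rank,
                    stringsAsFactors = FALSE)
  attr(out, "n_families") <- length(size)
  out
}

#' Standardized retrotransposon family name
#'
#' Builds names of the form `RLC_<host><lineage>_<index>` (Copia) or
#' `RLG_<host><lineage>_<index>` (Gypsy), e.g. `RLC_egAle_1`.
#'
#' @param superfamily `"Copia"` or `"Gypsy"`.
#' @param host_code two-letter host code (e.g. `"eg"`).
#' @param lineage lineage label (e.g. `"Ale"`).
#' @param index family number.
#' @return Character family name.
#' @export
name_family <- function(superfamily, host_code, lineage, index) {
  prefix <- switch(superfamily, Copia = "RLC", Gypsy = "RLG",
                   stop("unknown superfamily: ", superfamily))
  paste0(prefix, "_", host_code, lineage, "_", index)
}

#' Assign a lineage by nearest reference
#'
#' The query (typically a reverse-transcriptase fragment) is compared to a
#' labeled reference panel by global alignment and K2P distance; the
#' lineage of the nearest panel member is returned. Distances beyond
#' `ceiling`, or saturated against all references, give `"unclassified"`.
#' Ties are resolved to the first panel member in input order and flagged
#' ambiguous.
#'
#' @param query DNA string.
#' @param panel named character vector of reference sequences; names are
#'   lineage labels.
#' @param ceiling maximum K2P distance for a confident call (default 0.6).
#' @return List with `lineage`, `distance`, `nearest` (panel index),
#'   `ambiguous`.
#' @export
assign_lineage <- function(query, panel, ceiling = 0.6) {
  if (length(panel) < 1) stop("panel must be non-empty")
  if (is.null(names(panel))) stop("panel members must be labeled with lineages")
  dist <- vapply(panel, function(ref) {
    dv <- k2p_distance(align_pair_global(query, ref))
    if (dv$saturated) NA_real_ else dv$K
  }, numeric(1))
  if (all(is.na(dist)))
    return(list(lineage = "unclassified", distance = NA_real_,
                nearest = NA_integer_, ambiguous = FALSE))
  dmin <- min(dist, na.rm = TRUE)
  hits <- which(!is.na(dist) & dist == dmin)
  if (dmin > ceiling)
    return(list(lineage = "unclassified", distance = dmin,
                nearest = hits[1], ambiguous = length(hits) > 1))
  list(lineage = names(panel)[hits[1]], distance = dmin, nearest = hits[1],
       ambiguous = length(hits) > 1)
}
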