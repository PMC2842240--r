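# Resolution metrics: from consensus trees to per-clade-per-year fractions.

#' Count resolved nodes of a consensus tree
#'
#' A "resolved node" is a nontrivial unrooted bipartition retained at the
#' consensus threshold; a fully resolved n-leaf unrooted tree therefore
#' scores n - 3 and a star tree scores 0.
#'
#' @param consensus A `consensus_tree` from [majority_consensus()].
#' @return Integer count.
#' @export
count_resolved <- function(consensus) {
  stopifnot(inherits(consensus, "consensus_tree"))
  length(consensus$splits)
}

#' Clade resolution normalised by described diversity
#'
#' Divides the resolved-node count by the node count of a fully bifurcating
#' tree of all *described* species in the clade, N - 2. Because resolved
#' nodes are unrooted splits (max N - 3), perfect resolution of a fully
#' sampled clade scores (N - 3)/(N - 2), slightly below 1.
#'
#' @param resolved Resolved node count.
#' @param n_described Described species count N (>= 3).
#' @return Fraction resolved.
#' @export
clade_resolution <- function(resolved, n_described) {
  if (n_described < 3) stopf("need N_described >= 3 (got %s)", n_described)
  resolved / (n_described - 2)
}

#' Pooled resolution across clades
#'
#' Sum of resolved nodes over clades divided by the summed denominators
#' (N_described - 2); the pooled value for one year, as used for the
#' all-clades accumulation curve.
#'
#' @param records Data frame of resolution records sharing a `year`, with
#'   columns `N_described` and `resolved_50`/`resolved_95`.
#' @param level `"50"` or `"95"` bootstrap support level.
#' @return Pooled fraction.
#' @export
pool_resolution <- function(records, level = c("50", "95")) {
  level <- match.arg(level)
  if (nrow(records) == 0L) stopf("no records to pool")
  if (length(unique(records$year)) != 1L)
    stopf("pooled records must share a year")
  col <- paste0("resolved_", level)
  sum(records[[col]]) / sum(records$N_described - 2)
}

#' Single-gene resolution
#'
#' For single-gene trees the denominator is the number of taxa actually in
#' the tree minus two (sampled, not described, diversity).
#'
#' @param consensus A `consensus_tree` (or a resolved-node count).
#' @param n_taxa Number of taxa in the tree (>= 4).
#' @return Fraction resolved.
#' @export
single_gene_resolution <- function(consensus, n_taxa) {
  if (n_taxa < 4) stopf("need >= 4 taxa (got %s)", n_taxa)
  resolved <- if (inherits(consensus, "consensus_tree"))
    count_resolved(consensus) else consensus
  resolved / (n_taxa - 2)
}
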