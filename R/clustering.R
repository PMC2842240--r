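#' Parameters for single-linkage gene clustering
#'
#' Mirrors the contract of all-against-all similarity clustering: two records
#' are linked when their ends-free alignment reaches `min_identity` percent
#' identity and covers at least `min_coverage` of each (or either) sequence's
#' full length; clusters are the connected components of the link graph.
#' A shared-k-mer prefilter (word length `word_length`) skips pairs that
#' cannot plausibly align.
#'
#' @param min_coverage Minimum aligned fraction of a sequence (default 0.25).
#' @param min_identity Minimum percent identity over aligned columns
#'   (default 75).
#' @param require_both If `TRUE` (default) both sequences must meet the
#'   coverage bound; otherwise either suffices.
#' @param word_length Exact-match seed word length in bp for the prefilter.
#' @return A `clustering_params` list.
#' @export
clustering_params <- function(min_coverage = 0.25, min_identity = 75,
                              require_both = TRUE, word_length = 11L) {
  if (min_coverage <= 0 || min_coverage > 1)
    stopf("min_coverage must lie in (0, 1]")
  if (min_identity <= 0 || min_identity > 100)
    stopf("min_identity must lie in (0, 100]")
  structure(list(min_coverage = min_coverage, min_identity = min_identity,
                 require_both = isTRUE(require_both),
                 word_length = as.integer(word_length)),
            class = "clustering_params")
}

unit_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

# Ends-free global alignment of two sequence strings under unit costs.
# Returns the two full-length gapped rows plus match/column bookkeeping.
ends_free_align <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "overlap", substitutionMatrix = unit_submat(),
    gapOpening = 0, gapExtension = 1)
  pa <- as.character(Biostrings::pattern(aln))
  sa <- as.character(Biostrings::subject(aln))
  ps <- Biostrings::nchar(aln) # columns in aligned region
  p_rng <- c(Biostrings::start(Biostrings::pattern(aln)),
             Biostrings::end(Biostrings::pattern(aln)))
  s_rng <- c(Biostrings::start(Biostrings::subject(aln)),
             Biostrings::end(Biostrings::subject(aln)))
  la <- substr(a, 1L, p_rng[1L] - 1L)
  lb <- substr(b, 1L, s_rng[1L] - 1L)
  ra <- substr(a, p_rng[2L] + 1L, nchar(a))
  rb <- substr(b, s_rng[2L] + 1L, nchar(b))
  a_full <- paste0(strrep("-", nchar(lb)), la, pa, ra, strrep("-", nchar(rb)))
  b_full <- paste0(lb, strrep("-", nchar(la)), sa, strrep("-", nchar(ra)), rb)
  list(a = a_full, b = b_full,
       n_match = Biostrings::nmatch(aln), n_cols = ps,
       a_range = p_rng, b_range = s_rng)
}

#' Pairwise similarity of two sequence records
#'
#' Aligns two nucleotide sequences globally with free end gaps under unit
#' match/mismatch/gap costs and reports percent identity over the aligned
#' columns (end gaps excluded) plus the coverage of each sequence (aligned
#' region length over full length). The measure is symmetric.
#'
#' @param a,b Nucleotide sequence strings (or single-row record data frames
#'   with a `sequence` column).
#' @return Named numeric vector: `identity` (percent), `coverage_a`,
#'   `coverage_b` (fractions).
#' @export
pair_similarity <- function(a, b) {
  if (is.data.frame(a)) a <- a$sequence[1L]
  if (is.data.frame(b)) b <- b$sequence[1L]
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  # Canonical input order guarantees exact symmetry even when the optimal
  # alignment is tied.
  swap <- b < a
  if (swap) { tmp <- a; a <- b; b <- tmp }
  al <- ends_free_align(a, b)
  idty <- if (al$n_cols > 0) 100 * al$n_match / al$n_cols else 0
  cov_a <- (al$a_range[2L] - al$a_range[1L] + 1L) / nchar(a)
  cov_b <- (al$b_range[2L] - al$b_range[1L] + 1L) / nchar(b)
  if (al$a_range[2L] < al$a_range[1L]) cov_a <- 0
  if (al$b_range[2L] < al$b_range[1L]) cov_b <- 0
  if (swap) c(identity = idty, coverage_a = cov_b, coverage_b = cov_a)
  else c(identity = idty, coverage_a = cov_a, coverage_b = cov_b)
}

# k-mer sets for the prefilter.
kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(seq)
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' Cluster records into putative single-gene groups
#'
#' Builds the pairwise link graph under `params` (identity and coverage
#' thresholds on ends-free alignments, with a shared-k-mer prefilter) and
#' returns its connected components — single-linkage clusters. Cluster ids
#' are assigned in order of each component's smallest accession, making the
#' output deterministic.
#'
#' @param records Filtered records data frame.
#' @param params A [clustering_params()].
#' @return A list of clusters, each a list with `id`, `members` (records
#'   data frame) and `year` (`NA` until [slice_by_year()]).
#' @export
cluster_records <- function(records, params = clustering_params()) {
  stopifnot(inherits(params, "clustering_params"))
  n <- nrow(records)
  if (n == 0L) return(list())
  ord <- order(records$accession)
  records <- records[ord, , drop = FALSE]
  kmers <- lapply(records$sequence, kmer_set, k = params$word_length)
  # Union-find short circuit: single linkage only needs connectivity, so a
  # pair already joined through earlier links never needs aligning.
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  edges <- list(); ne <- 0L
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        if (find(i) == find(j)) next
        if (!any(kmers[[i]] %in% kmers[[j]])) next
        sim <- pair_similarity(records$sequence[i], records$sequence[j])
        covs <- sim[c("coverage_a", "coverage_b")]
        cov_ok <- if (params$require_both) all(covs >= params$min_coverage)
                  else any(covs >= params$min_coverage)
        if (sim[["identity"]] >= params$min_identity && cov_ok) {
          ne <- ne + 1L
          edges[[ne]] <- c(i, j)
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (ne > 0)
    g <- igraph::add_edges(g, unlist(edges))
  comp <- igraph::components(g)$membership
  groups <- split(seq_len(n), comp)
  first_acc <- vapply(groups, function(ix) min(records$accession[ix]), "")
  groups <- groups[order(first_acc)]
  lapply(seq_along(groups), function(k) {
    m <- records[groups[[k]], , drop = FALSE]
    rownames(m) <- NULL
    list(id = sprintf("G%03d", k), members = m, year = NA_integer_)
  })
}

#' Restrict clusters to records deposited by a given year
#'
#' Keeps, in every cluster, only the members deposited on or before
#' 31 December of `year`. Empty clusters are dropped; cluster ids are stable
#' across years so yearly slices nest.
#'
#' @param clusters Output of [cluster_records()].
#' @param year Cutoff year.
#' @param years Configured analysis years; slicing outside this range is an
#'   error.
#' @return Sliced cluster list.
#' @export
slice_by_year <- function(clusters, year, years = 1993:2008) {
  if (!year %in% years)
    stopf("year %d outside configured range %d-%d", year, min(years),
          max(years))
  out <- lapply(clusters, function(cl) {
    keep <- cl$members$year <= year
    if (!any(keep)) return(NULL)
    cl$members <- cl$members[keep, , drop = FALSE]
    rownames(cl$members) <- NULL
    cl$year <- as.integer(year)
    cl
  })
  out[!vapply(out, is.null, TRUE)]
}

#' Deduplicate a cluster to one record per species
#'
#' Keeps the longest sequence per species; length ties are broken by the
#' lexicographically smallest accession.
#'
#' @param cluster A single cluster (list with `members`).
#' @return The cluster with deduplicated `members`.
#' @export
dedup_longest <- function(cluster) {
  m <- cluster$members
  if (nrow(m) > 1L) {
    ord <- order(m$species, -m$length, m$accession)
    m <- m[ord, , drop = FALSE]
    m <- m[!duplicated(m$species), , drop = FALSE]
    m <- m[order(m$accession), , drop = FALSE]
    rownames(m) <- NULL
  }
  cluster$members <- m
  cluster
}
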