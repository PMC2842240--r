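# Independent oracles and tiny fixture builders used across the suite.

# Minimal record data frame; sequences default to distinct random-ish strings.
make_records <- function(accession, species, sequence,
                         clade = "CladeA",
                         year = 2000L,
                         class_flag = "ok") {
  n <- length(accession)
  data.frame(
    accession = accession,
    species = rep_len(species, n),
    clade = rep_len(clade, n),
    date = sprintf("%d-06-15", rep_len(year, n)),
    year = as.integer(rep_len(year, n)),
    sequence = sequence,
    class_flag = rep_len(class_flag, n),
    length = nchar(sequence),
    hybrid = grepl(" x ", rep_len(species, n), fixed = TRUE),
    stringsAsFactors = FALSE)
}

random_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Brute-force single-linkage clustering: boolean transitive closure of the
# pairwise link matrix (no union-find, no graph library).
oracle_single_linkage <- function(link) {
  n <- nrow(link)
  reach <- link | diag(n) > 0
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  # components as membership ids
  memb <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (memb[i] == 0L) {
      next_id <- next_id + 1L
      memb[reach[i, ]] <- next_id
    }
  }
  memb
}

# All tips below a node, by direct edge-matrix traversal (independent of
# ape's bipartition machinery).
oracle_tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, oracle_tips_under, tree = tree))
}

# Is the leaf set `side` a nontrivial split of unrooted `tree`?  Root at the
# first leaf not in `side`; then `side` is a split iff some internal node's
# descendant tip set equals it.
oracle_is_split <- function(tree, side) {
  labs <- tree$tip.label
  out <- setdiff(labs, side)
  if (length(side) < 2L || length(out) < 2L) return(FALSE)
  rt <- ape::root(tree, outgroup = out[1L], resolve.root = TRUE)
  ntip <- length(rt$tip.label)
  internal <- unique(rt$edge[, 1L])
  for (nd in internal) {
    if (setequal(oracle_tips_under(rt, nd), side)) return(TRUE)
  }
  FALSE
}

# Exhaustive majority-consensus oracle: enumerate every canonical leaf
# subset, count trees in which it is a split, apply the retention rule.
oracle_consensus_splits <- function(trees, threshold) {
  labs <- sort(trees[[1L]]$tip.label)
  ref <- labs[1L]
  others <- setdiff(labs, ref)
  n <- length(others)
  kept <- character(0)
  for (mask in seq_len(2^n - 1L)) {
    side <- others[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
    if (length(side) < 2L || length(side) > length(labs) - 2L) next
    cnt <- sum(vapply(trees, oracle_is_split, TRUE, side = side))
    freq <- cnt / length(trees)
    if (freq > 0.5 && freq >= threshold)
      kept <- c(kept, paste(sort(side), collapse = "|"))
  }
  sort(kept)
}

splits_as_keys <- function(consensus) {
  sort(vapply(consensus$splits, function(s) paste(sort(s), collapse = "|"),
              ""))
}

# Expected p-distance between two sequences separated by `d` substitutions
# per site under the two-parameter model, by numeric matrix exponential of
# the normalised rate matrix (independent of the simulator).
oracle_expected_pdist <- function(d, kappa, bf = rep(0.25, 4)) {
  Q <- matrix(1, 4, 4) # order A, C, G, T; transitions A<->G, C<->T
  Q[1, 3] <- Q[3, 1] <- kappa
  Q[2, 4] <- Q[4, 2] <- kappa
  Q <- Q * rep(bf, each = 4)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(bf * diag(Q))
  Q <- Q / scale
  e <- eigen(Q)
  P <- e$vectors %*% diag(exp(e$values * d)) %*% solve(e$vectors)
  1 - sum(bf * diag(Re(P)))
}

# Exhaustive unit-cost ends-free pairwise alignment score/width oracle for
# tiny strings: dynamic programme written independently of Biostrings.
oracle_nw_endsfree <- function(a, b) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  S <- matrix(-Inf, n + 1L, m + 1L)
  S[1L, ] <- 0; S[, 1L] <- 0 # free leading end gaps
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      S[i + 1L, j + 1L] <- max(
        S[i, j] + ifelse(A[i] == B[j], 1, -1),
        S[i, j + 1L] - 1,
        S[i + 1L, j] - 1)
    }
  }
  max(S[n + 1L, ], S[, m + 1L]) # free trailing end gaps
}

# Small dense world used by several integration tests.
dense_world <- function(seed, n_clades = 3L, years = 1999:2004,
                        n_loci = 2L, sp = c(8L, 10L), intensity_top = 0.5) {
  cfg <- world_config(
    n_clades = n_clades, species_per_clade = sp, n_loci = n_loci,
    locus_length = 250L, years = years,
    intensity = matrix(rep(seq(0.1, intensity_top, length.out = length(years)),
                           each = n_clades), n_clades, length(years)),
    hybrid_rate = 0.01, misspell_rate = 0.02, unsuitable_rate = 0.02,
    model_rate = 0, seed = seed)
  generate_world(cfg)
}
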