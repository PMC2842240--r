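# Tree estimation, bootstrap profiles, majority-rule consensus,
# taxon-instability scoring and rogue pruning.

# Uncorrected p-distances over shared non-missing sites.  Pairs sharing
# fewer than `min_shared` comparable sites are unreliable and get
# 1.25 x the maximum observed finite distance (missing-data contract).
pdistance_matrix <- function(mat, min_shared = 20L) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  ok <- matrix(mat %in% c("A", "C", "G", "T"), nrow = n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- ok[i, ] & ok[j, ]
      ns <- sum(shared)
      if (ns < min_shared) {
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        d[i, j] <- d[j, i] <- sum(mat[i, shared] != mat[j, shared]) / ns
      }
    }
  }
  if (anyNA(d)) {
    mx <- suppressWarnings(max(d, na.rm = TRUE))
    if (!is.finite(mx) || mx == 0) mx <- 0.8
    d[is.na(d)] <- 1.25 * mx
  }
  d
}

infer_tree_nj <- function(mat, min_shared = 20L) {
  d <- pdistance_matrix(mat, min_shared)
  tr <- ape::nj(stats::as.dist(d))
  # collapse internal edges of (numerically) zero or negative length: NJ
  # resolves distance ties arbitrarily and such edges carry no signal
  tr <- ape::di2multi(tr, tol = 1e-8)
  ape::unroot(tr)
}

infer_tree_parsimony <- function(mat, min_shared = 20L) {
  dat <- phangorn::phyDat(mat, type = "DNA")
  start <- phangorn::random.addition(dat)
  tr <- suppressMessages(phangorn::optim.parsimony(
    start, dat, rearrangements = "NNI", trace = 0))
  tr$edge.length <- NULL
  ape::unroot(ape::multi2di(tr))
}

tree_engine <- function(engine = c("nj", "parsimony")) {
  engine <- match.arg(engine)
  switch(engine, nj = infer_tree_nj, parsimony = infer_tree_parsimony)
}

#' Bootstrap tree profile from a supermatrix
#'
#' Resamples supermatrix columns with replacement (whole columns, so cells
#' stay attached to their partition of origin) and infers one unrooted tree
#' per replicate with the chosen engine: `"nj"` (neighbor joining on
#' p-distances over shared non-missing sites; default) or `"parsimony"`
#' (random-addition start refined by NNI hill climbing).
#'
#' @param sm A `supermatrix` with at least 4 species.
#' @param n_replicates Number of bootstrap replicates (default 100).
#' @param seed RNG seed; profiles are deterministic given the seed.
#' @param engine `"nj"` or `"parsimony"`.
#' @param min_shared Minimum shared sites for a reliable pairwise distance.
#' @return A `bootstrap_profile`: list with `trees` (list of `phylo`),
#'   `n_replicates`, `seed`, `engine`.
#' @export
bootstrap_trees <- function(sm, n_replicates = 100L, seed = 1L,
                            engine = c("nj", "parsimony"),
                            min_shared = 20L) {
  stopifnot(inherits(sm, "supermatrix"))
  if (nrow(sm$matrix) < 4L)
    stopf("need >= 4 species for tree inference (got %d)", nrow(sm$matrix))
  engine <- match.arg(engine)
  infer <- tree_engine(engine)
  trees <- with_seed(seed, lapply(seq_len(n_replicates), function(r) {
    cols <- sample.int(sm$width, sm$width, replace = TRUE)
    infer(sm$matrix[, cols, drop = FALSE], min_shared)
  }))
  structure(list(trees = trees, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), engine = engine),
            class = "bootstrap_profile")
}

# Canonical nontrivial splits of an unrooted tree, as "|"-joined sorted
# label strings of the side NOT containing the reference leaf.
tree_splits <- function(tree, ref = NULL) {
  labs <- tree$tip.label
  if (is.null(ref)) ref <- min(labs)
  n <- length(labs)
  pp <- ape::prop.part(tree)
  out <- character(0)
  for (part in pp) {
    side <- labs[part]
    if (ref %in% side) side <- setdiff(labs, side)
    k <- length(side)
    if (k >= 2L && k <= n - 2L)
      out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

# Tally canonical splits across trees sharing a leaf set.
count_splits <- function(trees) {
  ref <- min(trees[[1L]]$tip.label)
  tab <- new.env(parent = emptyenv())
  for (tr in trees) {
    for (s in tree_splits(tr, ref)) {
      tab[[s]] <- (tab[[s]] %||% 0L) + 1L
    }
  }
  keys <- ls(tab)
  stats::setNames(vapply(keys, function(k) tab[[k]], 0L), keys)
}

# Assemble a tree from pairwise-compatible splits; supports become internal
# node labels.
splits_to_tree <- function(leaves, splits, support) {
  fmt <- function(x) formatC(x, digits = 3, format = "g")
  build <- function(members, idx) {
    if (!length(idx)) {
      inner <- paste(sprintf("'%s'", members), collapse = ",")
      return(inner)
    }
    sets <- lapply(idx, function(i) splits[[i]])
    maximal <- idx[vapply(seq_along(idx), function(a) {
      !any(vapply(seq_along(idx), function(b) {
        a != b && all(sets[[a]] %in% sets[[b]])
      }, TRUE))
    }, TRUE)]
    parts <- vapply(maximal, function(i) {
      inside <- setdiff(idx, i)
      inside <- inside[vapply(inside, function(j)
        all(splits[[j]] %in% splits[[i]]), TRUE)]
      paste0("(", build(splits[[i]], inside), ")", fmt(support[i]))
    }, "")
    loose <- setdiff(members, unlist(splits[maximal]))
    paste(c(parts, sprintf("'%s'", loose)), collapse = ",")
  }
  txt <- paste0("(", build(leaves, seq_along(splits)), ");")
  tr <- ape::read.tree(text = txt)
  tr$tip.label <- gsub("^'|'$", "", tr$tip.label)
  ape::unroot(tr)
}

#' Majority-rule bootstrap consensus
#'
#' Tallies nontrivial bipartitions across the replicate trees and retains a
#' split when its frequency exceeds 1/2 and is at least `threshold`
#' (strict majority avoids incompatible exactly-50% splits; the 95% rule is
#' inclusive). Trees on different leaf sets are restricted to the shared
#' leaves (at least 4 required).
#'
#' @param profile A `bootstrap_profile` (or plain list of `phylo` trees).
#' @param threshold Retention threshold as a fraction (0.5 or 0.95 in
#'   standard use).
#' @return A `consensus_tree`: list with `tree` (`phylo`, supports as node
#'   labels), `splits` (list of leaf-name vectors), `support` (exact
#'   count/n fractions), `threshold`, `n_trees`.
#' @export
majority_consensus <- function(profile, threshold = 0.5) {
  trees <- if (inherits(profile, "bootstrap_profile")) profile$trees
           else profile
  if (!length(trees)) stopf("empty tree profile")
  shared <- Reduce(intersect, lapply(trees, `[[`, "tip.label"))
  if (length(shared) < 4L)
    stopf("fewer than 4 leaves shared across the profile")
  trees <- lapply(trees, function(tr) {
    if (length(tr$tip.label) > length(shared))
      ape::keep.tip(tr, shared) else tr
  })
  counts <- count_splits(trees)
  freq <- counts / length(trees)
  keep <- freq > 0.5 & freq >= threshold
  splits <- lapply(strsplit(names(freq)[keep], "|", fixed = TRUE), identity)
  support <- unname(freq[keep])
  ord <- order(-lengths(splits))
  splits <- splits[ord]; support <- support[ord]
  tree <- splits_to_tree(sort(shared), splits, support)
  structure(list(tree = tree, splits = splits, support = support,
                 threshold = threshold, n_trees = length(trees)),
            class = "consensus_tree")
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat(sprintf(
    "consensus_tree: %d leaves, %d resolved splits at threshold %.2f\n",
    length(x$tree$tip.label), length(x$splits), x$threshold))
  invisible(x)
}

#' Taxon instability across a tree profile
#'
#' Scores how erratically each taxon moves between replicate trees: for
#' every pair of trees (x, y) and every other taxon j shared by both, the
#' term |D(t,j;x) - D(t,j;y)| / (D(t,j;x) + D(t,j;y))^2 is accumulated,
#' where D is the nodal (edge-count) path distance between leaves; the sum
#' is normalised by the number of valid (pair, j) terms. Stable taxa score
#' 0; taxa alternating between distant attachment points score highest.
#'
#' @param profile A `bootstrap_profile` or list of trees (>= 2).
#' @return Named numeric vector of scores; taxa present in fewer than two
#'   trees get `NA`.
#' @export
taxon_instability <- function(profile) {
  trees <- if (inherits(profile, "bootstrap_profile")) profile$trees
           else profile
  if (length(trees) < 2L) stopf("need >= 2 trees for instability")
  all_taxa <- sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  dmats <- lapply(trees, function(tr) {
    tr <- ape::unroot(tr)
    tr$edge.length <- rep(1, nrow(tr$edge))
    ntip <- length(tr$tip.label)
    D <- ape::dist.nodes(tr)[seq_len(ntip), seq_len(ntip)]
    dimnames(D) <- list(tr$tip.label, tr$tip.label)
    D
  })
  num <- stats::setNames(rep(0, length(all_taxa)), all_taxa)
  cnt <- stats::setNames(rep(0L, length(all_taxa)), all_taxa)
  nt <- length(trees)
  for (x in seq_len(nt - 1L)) {
    for (y in (x + 1L):nt) {
      shared <- intersect(rownames(dmats[[x]]), rownames(dmats[[y]]))
      if (length(shared) < 3L) next
      Dx <- dmats[[x]][shared, shared]
      Dy <- dmats[[y]][shared, shared]
      M <- abs(Dx - Dy) / (Dx + Dy)^2
      diag(M) <- 0
      num[shared] <- num[shared] + rowSums(M)
      cnt[shared] <- cnt[shared] + length(shared) - 1L
    }
  }
  in_trees <- table(unlist(lapply(trees, `[[`, "tip.label")))
  score <- num / pmax(cnt, 1L)
  score[all_taxa %in% names(in_trees)[in_trees < 2L] | cnt == 0L] <- NA_real_
  score
}

#' Prune the least stable (rogue) taxa from a supermatrix
#'
#' Removes the `floor(fraction * n_species)` highest-instability species
#' (ties: higher raw score first, then name order) and rebuilds the
#' supermatrix bookkeeping on the remaining rows.
#'
#' @param sm A `supermatrix`.
#' @param profile Bootstrap profile used to score instability (typically a
#'   preliminary analysis of `sm`).
#' @param fraction Fraction of taxa to prune; the two standard stringencies
#'   are 0.05 and 0.10.
#' @return List with `matrix` (pruned `supermatrix`) and `pruned`
#'   (character vector of removed species).
#' @export
prune_rogues <- function(sm, profile, fraction = 0.05) {
  stopifnot(inherits(sm, "supermatrix"), fraction >= 0, fraction < 1)
  n <- nrow(sm$matrix)
  k <- floor(fraction * n)
  if (k == 0L) return(list(matrix = sm, pruned = character(0)))
  if (n - k < 4L) stopf("pruning %d of %d species leaves fewer than 4", k, n)
  score <- taxon_instability(profile)
  score <- score[rownames(sm$matrix)]
  score[is.na(score)] <- -Inf
  ord <- order(-score, names(score))
  pruned <- names(score)[ord][seq_len(k)]
  keep <- setdiff(rownames(sm$matrix), pruned)
  pruned_sm <- new_supermatrix(sm$matrix[keep, , drop = FALSE],
                               sm$partitions)
  list(matrix = pruned_sm, pruned = pruned)
}
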