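# Bootstrap profiles, majority-rule consensus, instability, rogue pruning.

# Clean high-signal matrix: sequences evolved on a known tree with deep
# divergences; returns the supermatrix and the true tree.
signal_matrix <- function(seed, n_taxa = 8L, len = 800L, depth = 0.5) {
  withr::with_seed(seed, {
    tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
    h <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * depth / h
    seqs <- phyloprogress:::simulate_locus(tr, len, kappa = 2,
                                           base_freqs = rep(0.25, 4),
                                           rate = 1)
    mat <- do.call(rbind, strsplit(unname(seqs), ""))
    rownames(mat) <- names(seqs)
    parts <- data.frame(cluster = "G001", start = 0L, end = len)
    list(sm = phyloprogress:::new_supermatrix(mat, parts),
         tree = ape::unroot(tr))
  })
}

test_that("bootstrap profiles are deterministic and need four species", {
  sig <- signal_matrix(1)
  p1 <- bootstrap_trees(sig$sm, n_replicates = 10, seed = 42)
  p2 <- bootstrap_trees(sig$sm, n_replicates = 10, seed = 42)
  expect_identical(lapply(p1$trees, ape::write.tree),
                   lapply(p2$trees, ape::write.tree))
  p3 <- bootstrap_trees(sig$sm, n_replicates = 10, seed = 43)
  expect_false(identical(lapply(p1$trees, ape::write.tree),
                         lapply(p3$trees, ape::write.tree)))
  tiny <- sig$sm
  tiny$matrix <- tiny$matrix[1:3, , drop = FALSE]
  expect_error(bootstrap_trees(tiny, 5, 1), "4 species")
})

test_that("a zero-variation matrix yields no supported splits", {
  mat <- matrix("A", nrow = 6, ncol = 100,
                dimnames = list(sprintf("Gen sp%02d", 1:6), NULL))
  sm <- phyloprogress:::new_supermatrix(
    mat, data.frame(cluster = "G001", start = 0L, end = 100L))
  prof <- bootstrap_trees(sm, n_replicates = 20, seed = 1)
  cons <- majority_consensus(prof, 0.5)
  expect_identical(count_resolved(cons), 0L)
})

test_that("clean deep-divergence matrices reproduce the true topology", {
  sig <- signal_matrix(7)
  prof <- bootstrap_trees(sig$sm, n_replicates = 20, seed = 5)
  rf <- vapply(prof$trees, function(tr)
    phangorn::RF.dist(tr, sig$tree), 0)
  expect_true(all(rf == 0))
})

test_that("identical binary trees give n-3 splits at support 1", {
  tr <- withr::with_seed(3, ape::rtree(6, tip.label = sprintf("t%d", 1:6)))
  prof <- rep(list(ape::unroot(tr)), 100)
  cons <- majority_consensus(prof, 0.5)
  expect_identical(count_resolved(cons), 3L)
  expect_true(all(cons$support == 1.0))
  # consensus topology equals the input tree
  expect_equal(phangorn::RF.dist(cons$tree, tr), 0, ignore_attr = TRUE)
})

test_that("the 50% rule is strict and the 95% rule inclusive", {
  # 60/100 trees contain split {t1,t2}; the rest pair t1 with t3
  t_a <- ape::read.tree(text = "((t1,t2),(t3,t4),(t5,t6));")
  t_b <- ape::read.tree(text = "((t1,t3),(t2,t4),(t5,t6));")
  prof <- c(rep(list(t_a), 60), rep(list(t_b), 40))
  # canonical split keys name the side away from the lowest-sorting leaf, so
  # the {t1,t2} split is keyed by its complement
  k12 <- "t3|t4|t5|t6"
  c50 <- majority_consensus(prof, 0.5)
  keys50 <- splits_as_keys(c50)
  expect_true(k12 %in% keys50)
  c95 <- majority_consensus(prof, 0.95)
  expect_false(k12 %in% splits_as_keys(c95))
  # {t5,t6} appears in all trees: retained at both levels
  expect_true("t5|t6" %in% keys50)
  expect_true("t5|t6" %in% splits_as_keys(c95))
  # exactly 50/100 would fail the strict rule
  prof5050 <- c(rep(list(t_a), 50), rep(list(t_b), 50))
  expect_false(k12 %in% splits_as_keys(majority_consensus(prof5050, 0.5)))
  # supports are exact replicate fractions
  expect_equal(sort(c50$support), c(0.6, 0.6, 1.0))
})

test_that("consensus equals exhaustive split enumeration on random profiles", {
  for (seed in c(2, 11, 29)) {
    prof <- withr::with_seed(seed, lapply(1:10, function(i)
      ape::unroot(ape::rtree(7, tip.label = sprintf("t%d", 1:7)))))
    for (thr in c(0.5, 0.95)) {
      cons <- majority_consensus(prof, thr)
      expect_identical(splits_as_keys(cons),
                       oracle_consensus_splits(prof, thr))
    }
  }
})

test_that("95% consensus splits nest within 50% splits", {
  sig <- signal_matrix(19, n_taxa = 10L, len = 300L, depth = 0.3)
  prof <- bootstrap_trees(sig$sm, n_replicates = 30, seed = 9)
  s50 <- splits_as_keys(majority_consensus(prof, 0.5))
  s95 <- splits_as_keys(majority_consensus(prof, 0.95))
  expect_true(all(s95 %in% s50))
})

test_that("total split support cannot exceed trees x (n - 3)", {
  prof <- withr::with_seed(4, lapply(1:15, function(i)
    ape::unroot(ape::rtree(8, tip.label = sprintf("t%d", 1:8)))))
  counts <- phyloprogress:::count_splits(prof)
  expect_lte(sum(counts), 15 * (8 - 3))
})

test_that("instability is zero for constant profiles, order-invariant", {
  tr <- withr::with_seed(8, ape::unroot(ape::rtree(6)))
  prof <- rep(list(tr), 5)
  sc <- taxon_instability(prof)
  expect_true(all(sc == 0))
  # alternating attachment: rogue taxon R scores highest
  t1 <- ape::read.tree(text = "((R,A),(B,(C,(D,E))));")
  t2 <- ape::read.tree(text = "(A,(B,(C,(D,(E,R)))));")
  prof2 <- list(t1, t1, t2, t2)
  sc2 <- taxon_instability(prof2)
  expect_identical(names(which.max(sc2)), "R")
  # invariant to profile order
  sc3 <- taxon_instability(rev(prof2))
  expect_equal(sc2, sc3)
})

test_that("rogue pruning removes floor(fraction x n) by instability rank", {
  sig <- signal_matrix(21, n_taxa = 40L, len = 150L, depth = 0.4)
  prof <- bootstrap_trees(sig$sm, n_replicates = 10, seed = 2)
  pr <- prune_rogues(sig$sm, prof, fraction = 0.05)
  expect_length(pr$pruned, 2L) # floor(0.05 * 40)
  expect_identical(nrow(pr$matrix$matrix), 38L)
  pr10 <- prune_rogues(sig$sm, prof, fraction = 0.10)
  expect_length(pr10$pruned, 4L)
  # fraction 0 is the identity
  pr0 <- prune_rogues(sig$sm, prof, fraction = 0)
  expect_identical(pr0$matrix, sig$sm)
  expect_length(pr0$pruned, 0L)
  # pruning below 4 species errors
  small <- signal_matrix(22, n_taxa = 4L, len = 100L)
  profs <- bootstrap_trees(small$sm, n_replicates = 5, seed = 3)
  expect_error(prune_rogues(small$sm, profs, fraction = 0.25), "fewer than 4")
})

test_that("a planted rogue is pruned in at least 90% of seeds", {
  hits <- vapply(1:10, function(seed) {
    sig <- signal_matrix(100 + seed, n_taxa = 20L, len = 400L, depth = 0.4)
    sm <- sig$sm
    # plant a rogue the way real ones arise: a sparse row (40 visible sites,
    # rest missing) with half its visible sites randomised, so replicates
    # disagree about its attachment
    rogue <- rownames(sm$matrix)[1L]
    row <- sm$matrix[rogue, ]
    sm$matrix[rogue, ] <- withr::with_seed(seed, {
      keep <- sample(sm$width, 40)
      out <- rep("?", sm$width)
      out[keep] <- row[keep]
      rnd <- sample(keep, 20)
      out[rnd] <- sample(c("A", "C", "G", "T"), 20, replace = TRUE)
      out
    })
    sm <- phyloprogress:::new_supermatrix(sm$matrix, sm$partitions)
    prof <- bootstrap_trees(sm, n_replicates = 30, seed = seed)
    pr <- prune_rogues(sm, prof, fraction = 0.05) # floor(.05*20) = 1 taxon
    rogue %in% pr$pruned
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
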