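---
title: "Measuring phylogenetic progress with automated supermatrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring phylogenetic progress with automated supermatrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloprogress)
```

## The question and the procedure

Public sequence archives accumulate data far faster than any curated
phylogenetic resource, which makes them the natural place to ask: *how much
of the tree of life is resolved, and how fast is that fraction growing?*
`phyloprogress` implements an automated supermatrix pipeline that answers
this per clade and per deposition year:

1. **Records and filters.** Sequence records (FASTA plus a metadata sidecar)
   are filtered to 100–5000 bp (inclusive bounds), stripped of unsuitable
   sequence classes (microsatellites, repetitive elements, suspected
   paralogs), of hybrid-named records not assignable to a single species,
   and of model organisms — species whose total record count in the archive
   exceeds a threshold, since such data come overwhelmingly from genome and
   resequencing projects. Name variants are standardized to canonical
   binomials through an alias table; names resolving to more than one
   canonical species are dropped as ambiguous. Rejections carry exactly one
   reason, assigned in the fixed order length → class → hybrid →
   model organism, so rejection reports are deterministic.
2. **Analysis clades.** Clades are chosen by drawing a sampled species at
   random and walking rootward to the largest containing clade with fewer
   than 500 sampled species; draws overlapping an already selected clade are
   rejected, so the accepted clades are pairwise disjoint. The cutoff keeps
   matrices tractable and within-clade divergence alignable.
3. **Gene clusters.** Within a clade, records are clustered into putative
   single-gene groups by single-linkage clustering: two records are linked
   when their ends-free pairwise alignment reaches 75% identity and covers
   at least 25% of *each* sequence; clusters are connected components of the
   link graph. A shared 11-mer prefilter skips pairs that cannot plausibly
   align, and — because single linkage only needs connectivity — pairs
   already joined through earlier links are never aligned.
4. **Yearly slices.** Each cluster is restricted to records deposited by 31
   December of year *y*, for every analysis year, giving nested cumulative
   datasets. Within each slice, one record per species is kept — the
   longest, ties broken by smallest accession.
5. **Supermatrix.** Clusters are aligned by deterministic progressive
   merging (guide order: decreasing length, then accession) against the
   running column consensus under unit costs; merging only inserts gap
   columns, so ungapping any row recovers its input sequence. The retained
   set iterates two rules to a fixed point: a cluster needs at least four
   species and must share at least four species with another retained
   cluster. Retained clusters are concatenated with `?` filling partitions
   that lack a species.
6. **Trees.** One hundred bootstrap replicates resample supermatrix columns
   with replacement; each replicate is analysed with a pluggable engine
   (default: neighbor joining on p-distances over shared non-missing sites;
   a parsimony engine with random-addition starts and NNI refinement is
   also provided). A preliminary profile scores per-taxon instability, the
   5% (or 10%) least stable taxa are pruned, and a final profile yields 50%
   and 95% majority-rule consensus trees.
7. **Resolution.** A "resolved node" is a nontrivial unrooted bipartition
   retained by the consensus rule. Clade resolution divides the resolved
   count by N − 2, where N is the number of *described* species in the
   clade (from checklists), so undersampling caps attainable resolution.
   Pooling across clades sums resolved nodes over summed denominators.
   Single-gene analyses instead divide by the number of sampled taxa minus
   two.
8. **Trends.** Pooled yearly resolution is fit by ordinary least squares
   with linear and quadratic terms; the quadratic gain is tested with the
   nested F statistic ((RSS₁ − RSS₂)/1)/(RSS₂/(n − 3)) on F(1, n − 3).
   Projections scan fitted values (capped at 1) year by year to the first
   year a target is met. A multiple regression of clade resolution on
   proportion of species sampled, clade size, characters per species and
   dataset density — all z-standardized so coefficients are comparable —
   identifies which dataset features matter most.

## The synthetic archive

Real archives cannot be downloaded inside a test suite, and they carry no
ground truth. `generate_world()` therefore builds a fully known "archive
world": a three-level taxonomy with described diversities, one pure-birth
(Yule) tree per clade rescaled to a target root-to-tip depth, per-locus
sequences evolved under a two-parameter (HKY-class) substitution model, and
deposited records drawn per (species, locus, year) with clade- and
year-specific intensity. Records are end-truncated fragments (uniform
fraction of the locus, anchored at a random end), which exercises the
aligner and the coverage rules without simulating indels.

### Defaults and why

* **Years 1993–2008** — the era spanning the rise of routine public
  sequence deposition; slicing is cumulative by year.
* **Deposition intensity** — no quantitative description of archive
  sampling skew exists, so the default is an increasing-by-year ramp
  (0.01 → 0.15 per species-locus-year) scaled per clade by a 0.4–1.6
  gradient. This emulates the two salient features: data accumulate faster
  over time, and effort is uneven across clades.
* **Contaminants** — hybrids ("Genus spA x Genus spB" names) at 1% of
  records, misspelled names (with alias-table truth) at 2%,
  unsuitable-class records at 2%, and model organisms at a 0.5% per-species
  rate with 60 records each. The archive rates are unpublished; these
  values make every filter rule exercise real work without dominating the
  data. The model-organism record count pairs with a `model_threshold` of
  50 in desk-scale filter policies (the production default of 10,000
  mirrors archive-scale counts).
* **Tree depth 0.2 subs/site, kappa 2, equal base frequencies** — shallow
  family-level divergence; locus rate multipliers default to a geometric
  2 → 0.5 spread creating a fast-mitochondrial/slow-nuclear contrast.
* **Fragments ≥ 60% of locus length** — short enough to exercise coverage
  logic, long enough that same-locus fragments overlap detectably.

Worlds used in specific validations choose their own conditions where the
default would change what is being measured. Two matter:

* *Multi-clade validation worlds* (the 100-clade × 16-year grid and the
  10-clade sampling-gradient worlds) use tree depth 0.1 and fragments
  ≥ 80%: with small clades and 150–200 bp loci, deeper divergence pushes
  the short fragment overlaps between distant congeners below the 75%
  identity rule and loci fragment into subclade clusters, leaving nothing
  to assemble. The clustering thresholds themselves are never altered.
* *High-signal recovery matrices* floor internal branch lengths at 0.05
  subs/site over 1200 bp: a pure-birth tree can contain near-zero internal
  edges, and no finite alignment resolves a zero-length edge — such
  matrices are not high-signal by construction.

### What the generator does not emulate

No indels (alignment is exercised only through end truncation), no
rate-across-sites heterogeneity, no gene duplication (so "paralog" records
exist only as class flags), no resubmissions or date revisions, and no
correlation between contamination and clade identity. Passing tests
demonstrate that the pipeline machinery is correct and that its qualitative
behaviour (sampling effort drives resolution) is as expected — not that the
aligner or engines match production tools on hard real-world alignments.

## Numerical choices and degenerate inputs

* **Consensus retention** is strict at 50% (> 0.5) to exclude mutually
  incompatible exactly-50% splits, and inclusive at 95% (≥ 0.95).
  Support values are exact replicate fractions.
* **Resolved nodes are unrooted splits**, so a fully resolved, fully
  sampled clade scores (N − 3)/(N − 2) < 1. Bipartitions are the only
  support-bearing objects in a bootstrap consensus; the one-node difference
  from a rooted-node convention is accepted and documented.
* **Instability** is the mean over tree pairs (x, y) and shared third taxa
  j of |D(t,j;x) − D(t,j;y)| / (D(t,j;x) + D(t,j;y))², with D the nodal
  (edge-count) distance on the unrooted trees. Instability indices vary
  across tools and the widely used implementations do not document a single
  formula; this nodal form is the package's definition. Taxa in fewer than
  two trees score `NA`.
* **NJ missing-data contract**: pairs sharing fewer than 20 comparable
  sites receive 1.25 × the maximum observed finite distance. Internal
  edges of zero (or negative) estimated length are collapsed before split
  counting — NJ resolves exact ties arbitrarily, and such edges carry no
  signal (an invariant matrix yields a star, not an input-order artifact).
* **Tie-breaks** are total and documented: dedup (longest, then smallest
  accession), rogue ranking (higher score, then species name), alignment
  guide order (longer, then accession), top-5 gene lists (larger value,
  then gene id), consensus component choice (more species, more clusters,
  smallest cluster id).
* **Degenerate inputs**: fewer than 4 species refuse tree inference;
  N_described < 3 refuses resolution; a perfect linear fit reports the
  quadratic-improvement p-value as 1; zero-intensity worlds refuse to
  generate; empty cluster sets yield "no supermatrix this year" rather
  than errors.
* **Projection** starts its scan at the last observed year (a target
  already met returns that year), caps fitted proportions at 1, and
  returns `NA` ("not reached") for trends decreasing at the last year or
  targets unmet by the horizon (default 2100).

## Design choices where the procedure was open

* **Fixed-point semantics** for the ≥4-species/≥4-overlap rule: dropping a
  cluster can orphan its only partner, so the two rules iterate until
  stable. If survivors split into several connected overlap components,
  the component with the most species is kept — one connected analysis,
  as supermatrix practice expects.
* **Non-overlap of selected clades** is enforced by rejection sampling:
  a draw landing inside or above an accepted clade is discarded.
* **"Partial regression coefficients"** are standardized betas: comparing
  effect magnitudes across predictors with different units is only
  meaningful on the standardized scale.
* **Engine choice** sits behind one interface; distance-based inference is
  the default because desk-scale validation needs thousands of replicate
  trees, and the bootstrap/consensus/pruning contract is engine-agnostic.
* **Model-organism counts** are computed on the pre-filter record pool per
  species, matching counts "in the archive" rather than in the filtered
  subset.

## Problem sizes

Validation runs use worlds of 1–10 clades × 5–20 species × 2–4 loci of
150–500 bp over 6–16 years, with 10–30 bootstrap replicates; the
grid-arithmetic check enumerates the full 100 × 16 grid at 5 replicates.
Parameter-recovery simulations use 200 regression seeds (n = 100,
σ = 0.05), 200 trend seeds (16-point series) and 40 topology seeds
(8 taxa, 1200 bp). These sizes keep the whole suite in the minutes range
while leaving each statistical bound (≥ 90%, ≥ 95% recovery) comfortably
testable.

## A worked example

```{r example, eval = FALSE}
cfg <- world_config(n_clades = 4, species_per_clade = c(8L, 12L),
                    n_loci = 3, locus_length = 300, years = 1998:2005,
                    seed = 7)
world <- generate_world(cfg)

run <- run_pipeline(world, run_config(
  years = 1998:2005, clades = sprintf("C%02d", 1:4),
  policy = filter_policy(model_threshold = 50),
  n_bootstrap = 100, seed = 11))

report <- report_run(run)
report$pooled          # pooled yearly accumulation curve
report$trend_50        # quadratic trend + nested-F improvement test
report$regression      # dataset-feature regression (given >= 6 clades)
```

## Known limitations

The internal aligner is a consensus-guided progressive merger adequate for
end-truncated fragments of a common locus; it is not a general multiple
aligner. Distance and parsimony engines are desk-scale; neither reproduces
the search behaviour of production parsimony software. Single-gene
rankings require ≥ 20 informative clusters per clade, which synthetic
worlds only reach when configured with many loci. Saturating (sigmoidal)
growth is deliberately not fitted; polynomial projections are
extrapolations and should be read as such.
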