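# End-to-end orchestration of the per-clade-per-year supermatrix grid.

#' Configuration for a pipeline run
#'
#' @param years Analysis years, ascending (default 1993:2008); clusters are
#'   sliced cumulatively at each year.
#' @param clades Explicit analysis clade ids, or `NULL` to select
#'   `n_clades` non-overlapping clades with [select_clades()].
#' @param n_clades Number of clades to select when `clades` is `NULL`.
#' @param max_sampled Sampled-species cutoff for clade selection.
#' @param policy A [filter_policy()].
#' @param clust A [clustering_params()].
#' @param min_species,min_overlap Cluster informativeness rules for
#'   [select_informative()].
#' @param n_bootstrap Bootstrap replicates for both the preliminary
#'   (rogue-scoring) and final analyses (default 100).
#' @param prune_fraction Rogue pruning stringency, 0.05 or 0.10 (default
#'   0.05).
#' @param engine Tree engine, `"nj"` or `"parsimony"`.
#' @param thresholds Consensus thresholds (fixed at 0.5 and 0.95).
#' @param gene_analyses Also run final-year single-gene analyses (needed for
#'   [rank_genes()]); default `FALSE`.
#' @param min_genes Gene-count cutoff for a clade to qualify for ranking.
#' @param seed Run seed; fanned out to deterministic per-slot seeds.
#' @return A `run_config` list.
#' @export
run_config <- function(years = 1993:2008, clades = NULL, n_clades = 10L,
                       max_sampled = 500L, policy = filter_policy(),
                       clust = clustering_params(), min_species = 4L,
                       min_overlap = 4L, n_bootstrap = 100L,
                       prune_fraction = 0.05,
                       engine = c("nj", "parsimony"),
                       thresholds = c(0.5, 0.95), gene_analyses = FALSE,
                       min_genes = 20L, seed = 1L) {
  years <- as.integer(years)
  if (any(diff(years) <= 0L)) stopf("years must be ascending")
  if (!prune_fraction %in% c(0, 0.05, 0.10))
    stopf("prune_fraction must be 0, 0.05 or 0.10")
  structure(list(years = years, clades = clades,
                 n_clades = as.integer(n_clades),
                 max_sampled = as.integer(max_sampled), policy = policy,
                 clust = clust, min_species = as.integer(min_species),
                 min_overlap = as.integer(min_overlap),
                 n_bootstrap = as.integer(n_bootstrap),
                 prune_fraction = prune_fraction,
                 engine = match.arg(engine), thresholds = thresholds,
                 gene_analyses = isTRUE(gene_analyses),
                 min_genes = as.integer(min_genes),
                 seed = as.integer(seed)), class = "run_config")
}

# Analyse one (clade, year) slot from pre-built cluster alignments.
# Returns a list(status, record) where record is a ResolutionRecord row.
analyse_slot <- function(clade, year, clusters, alignments, n_described,
                         config) {
  sliced <- slice_by_year(clusters, year, config$years)
  if (!length(sliced)) return(list(status = "skipped", reason = "no_data"))
  sliced <- lapply(sliced, dedup_longest)
  alns <- lapply(sliced, function(cl)
    subset_alignment(alignments[[cl$id]], cl$members$accession))
  retained <- select_informative(alns, config$min_species,
                                 config$min_overlap)
  if (!length(retained))
    return(list(status = "skipped", reason = "no_informative_set"))
  sm <- concatenate_alignments(retained)
  if (nrow(sm$matrix) < 4L)
    return(list(status = "skipped", reason = "too_few_species"))
  seed_pre <- slot_seed(config$seed, clade, year, "prelim")
  seed_fin <- slot_seed(config$seed, clade, year, "final")
  prelim <- bootstrap_trees(sm, config$n_bootstrap, seed_pre, config$engine)
  n <- nrow(sm$matrix)
  k <- floor(config$prune_fraction * n)
  if (k > 0L && n - k >= 4L) {
    pr <- prune_rogues(sm, prelim, config$prune_fraction)
    sm_final <- pr$matrix
    pruned <- pr$pruned
  } else {
    sm_final <- sm
    pruned <- character(0)
  }
  profile <- bootstrap_trees(sm_final, config$n_bootstrap, seed_fin,
                             config$engine)
  cons50 <- majority_consensus(profile, config$thresholds[1L])
  cons95 <- majority_consensus(profile, config$thresholds[2L])
  r50 <- count_resolved(cons50)
  r95 <- count_resolved(cons95)
  rec <- data.frame(
    clade = clade, year = year, N_described = n_described,
    n_sampled = nrow(sm_final$matrix),
    resolved_50 = r50, resolved_95 = r95,
    resolution_50 = clade_resolution(r50, n_described),
    resolution_95 = clade_resolution(r95, n_described),
    density = sm_final$density,
    characters_per_species = sm_final$characters_per_species,
    width = sm_final$width, n_pruned = length(pruned),
    stringsAsFactors = FALSE)
  list(status = "built", record = rec, consensus50 = cons50,
       consensus95 = cons95, retained = retained)
}

#' Run the full supermatrix pipeline over a clade-year grid
#'
#' Reads (or takes) a record archive, applies the inclusion filters and name
#' standardization, selects or accepts analysis clades, clusters each
#' clade's records into genes, aligns clusters, and then enumerates every
#' (clade, year) slot: the clusters are sliced at the year, deduplicated,
#' screened for the informative overlapping set, concatenated, analysed by
#' preliminary bootstrap + rogue pruning + final bootstrap, and scored as
#' 50%/95% consensus resolution. Slots without data or without an
#' informative cluster set are recorded as skipped; per-slot failures are
#' caught and logged. The run is fully deterministic given `config$seed`.
#'
#' @param world A `synthetic_world`, a directory written by [write_world()],
#'   or a list with `records`, `taxonomy`, `species`, `aliases`.
#' @param config A [run_config()].
#' @return A `pipeline_run`: list with `resolution` (ResolutionRecord table),
#'   `slots` (clade, year, status, reason), `clade_info` (described/sampled
#'   counts and final-year proportions), `gene_table` (when
#'   `config$gene_analyses`), `rejections`, `manifest`, `config`.
#' @export
run_pipeline <- function(world, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(world)) world <- read_world(world)
  records <- world$records
  taxonomy <- world$taxonomy
  species_table <- world$species
  aliases <- world$aliases %||%
    data.frame(variant = character(), canonical = character())

  flt <- filter_records(records, config$policy)
  std <- standardize_names(flt$kept, aliases)
  kept <- std$records
  rejections <- rbind(
    flt$rejected[, c("accession", "reason")],
    std$dropped[, c("accession", "reason")])

  clades <- config$clades
  if (is.null(clades)) {
    clades <- select_clades(taxonomy, species_table, unique(kept$species),
                            config$n_clades, config$max_sampled,
                            seed = config$seed)
    clades <- as.character(clades)
  }

  described <- stats::setNames(taxonomy$described_species, taxonomy$clade)
  res_rows <- list()
  slot_rows <- list()
  gene_rows <- list()
  clade_info <- list()
  final_year <- max(config$years)

  for (clade in clades) {
    members <- if (clade %in% taxonomy$clade)
      clade_species(taxonomy, species_table, clade) else clade
    n_desc <- if (clade %in% names(described)) described[[clade]] else 1
    crecs <- kept[kept$species %in% members, , drop = FALSE]
    clusters <- cluster_records(crecs, config$clust)
    alignments <- lapply(clusters, function(cl) align_cluster(cl))
    names(alignments) <- vapply(clusters, `[[`, "", "id")
    clade_info[[clade]] <- data.frame(
      clade = clade, N_described = n_desc,
      n_with_data = length(unique(crecs$species)),
      prop_sampled = length(unique(crecs$species)) / n_desc,
      n_records = nrow(crecs), n_clusters = length(clusters),
      stringsAsFactors = FALSE)
    for (year in config$years) {
      out <- tryCatch(
        analyse_slot(clade, year, clusters, alignments, n_desc, config),
        error = function(e) list(status = "failed",
                                 reason = conditionMessage(e)))
      slot_rows[[length(slot_rows) + 1L]] <- data.frame(
        clade = clade, year = year, status = out$status,
        reason = out$reason %||% "", stringsAsFactors = FALSE)
      if (out$status == "built") {
        res_rows[[length(res_rows) + 1L]] <- out$record
        if (config$gene_analyses && year == final_year) {
          gene_rows[[length(gene_rows) + 1L]] <-
            analyse_genes(clade, out$retained, config)
        }
      }
    }
  }

  resolution <- if (length(res_rows)) do.call(rbind, res_rows) else
    data.frame(clade = character(), year = integer(),
               N_described = numeric(), n_sampled = integer(),
               resolved_50 = integer(), resolved_95 = integer(),
               resolution_50 = numeric(), resolution_95 = numeric(),
               density = numeric(), characters_per_species = numeric(),
               width = integer(), n_pruned = integer())
  slots <- do.call(rbind, slot_rows)
  if (all(slots$status == "failed"))
    stopf("all %d slots failed; first error: %s", nrow(slots),
          slots$reason[1L])
  gene_table <- if (length(gene_rows)) do.call(rbind, gene_rows) else NULL
  manifest <- list(
    seed = config$seed, years = config$years, clades = clades,
    n_slots = nrow(slots),
    n_built = sum(slots$status == "built"),
    n_skipped = sum(slots$status == "skipped"),
    n_failed = sum(slots$status == "failed"),
    n_records_in = nrow(records), n_records_kept = nrow(kept),
    n_rejected = nrow(rejections),
    package_version = as.character(utils::packageVersion("phyloprogress")))
  structure(list(resolution = resolution, slots = slots,
                 clade_info = do.call(rbind, clade_info),
                 gene_table = gene_table, rejections = rejections,
                 manifest = manifest, config = config),
            class = "pipeline_run")
}

# Final-year single-gene analyses for one clade: each retained cluster
# alignment is analysed alone and scored with the sampled-taxa denominator.
analyse_genes <- function(clade, retained, config) {
  rows <- lapply(retained, function(a) {
    sp <- unique(unname(a$species))
    if (length(sp) < 4L) return(NULL)
    sm <- concatenate_alignments(list(a))
    profile <- bootstrap_trees(sm, config$n_bootstrap,
                               slot_seed(config$seed, clade, a$id, "gene"),
                               config$engine)
    cons <- majority_consensus(profile, config$thresholds[1L])
    data.frame(clade = clade, gene = a$id, n_taxa = length(sp),
               resolution = single_gene_resolution(cons, length(sp)),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' @export
print.pipeline_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "pipeline_run: %d slots (%d built, %d skipped, %d failed), %d clades\n",
    m$n_slots, m$n_built, m$n_skipped, m$n_failed, length(m$clades)))
  invisible(x)
}

#' Write a pipeline run to a directory
#'
#' Emits `resolution.tsv`, `slots.tsv`, `clade_info.tsv`, `rejections.tsv`,
#' optional `gene_table.tsv`, and `manifest.json`. Output is byte-identical
#' across reruns with the same seed.
#'
#' @param run A `pipeline_run`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(run$resolution, "resolution.tsv")
  wt(run$slots, "slots.tsv")
  wt(run$clade_info, "clade_info.tsv")
  wt(run$rejections, "rejections.tsv")
  if (!is.null(run$gene_table)) wt(run$gene_table, "gene_table.tsv")
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Summarise a pipeline run
#'
#' Produces the standard progress report: the pooled yearly accumulation
#' curve (all clades pooled), per-clade resolution curves, the final-year
#' dataset-characteristics table, quadratic trend fits to the pooled 50%
#' and 95% curves with the nested-F improvement test, projections of the
#' year each pooled curve reaches `target`, and (given >= 6 clades) the
#' dataset-feature regression. When the run carries single-gene analyses a
#' gene ranking is included.
#'
#' @param run A `pipeline_run`.
#' @param target Projection target for pooled resolution (default 0.95).
#' @param horizon Projection horizon year (default 2100).
#' @return A `progress_report` list with elements `pooled`, `by_clade`,
#'   `characteristics`, `trend_50`, `trend_95`, `projection_50`,
#'   `projection_95`, `regression`, `ranking`, `slot_summary`.
#' @export
report_run <- function(run, target = 0.95, horizon = 2100) {
  stopifnot(inherits(run, "pipeline_run"))
  res <- run$resolution
  years <- sort(unique(res$year))
  pooled <- do.call(rbind, lapply(years, function(y) {
    ry <- res[res$year == y, , drop = FALSE]
    data.frame(year = y, n_clades = nrow(ry),
               pooled_50 = pool_resolution(ry, "50"),
               pooled_95 = pool_resolution(ry, "95"))
  }))
  by_clade <- res[order(res$clade, res$year),
                  c("clade", "year", "resolution_50", "resolution_95")]
  final_year <- max(run$config$years)
  chars <- res[res$year == final_year,
               c("clade", "n_sampled", "width", "density",
                 "characters_per_species", "resolution_50",
                 "resolution_95")]
  trend_50 <- trend_95 <- projection_50 <- projection_95 <- NULL
  if (!is.null(pooled) && nrow(pooled) >= 4L) {
    trend_50 <- fit_trend(pooled$year, pooled$pooled_50, order = 2)
    trend_95 <- fit_trend(pooled$year, pooled$pooled_95, order = 2)
    projection_50 <- project_trend(trend_50, target, final_year, horizon)
    projection_95 <- project_trend(trend_95, target, final_year, horizon)
  }
  regression <- NULL
  if (!is.null(run$clade_info) && nrow(chars) >= 6L) {
    tab <- merge(run$clade_info[, c("clade", "N_described", "prop_sampled")],
                 chars, by = "clade")
    tab <- data.frame(prop_sampled = tab$prop_sampled,
                      clade_size = tab$N_described,
                      chars_per_species = tab$characters_per_species,
                      density = tab$density,
                      resolution = tab$resolution_50)
    regression <- tryCatch(feature_regression(tab), error = function(e) NULL)
  }
  ranking <- if (!is.null(run$gene_table))
    rank_genes(run$gene_table, run$config$min_genes) else NULL
  structure(list(pooled = pooled, by_clade = by_clade,
                 characteristics = chars, trend_50 = trend_50,
                 trend_95 = trend_95, projection_50 = projection_50,
                 projection_95 = projection_95, regression = regression,
                 ranking = ranking,
                 slot_summary = table(run$slots$status)),
            class = "progress_report")
}

#' @export
print.progress_report <- function(x, ...) {
  cat("progress_report\n")
  if (!is.null(x$pooled) && nrow(x$pooled)) {
    last <- x$pooled[nrow(x$pooled), ]
    cat(sprintf("  final pooled resolution: %.3f (50%%), %.3f (95%%)\n",
                last$pooled_50, last$pooled_95))
  }
  if (!is.null(x$trend_50))
    cat(sprintf("  pooled 50%% trend r^2 = %.3f (quadratic)\n",
                x$trend_50$r_squared))
  if (!is.null(x$projection_50))
    cat(sprintf("  projected target year (50%%): %s\n",
                ifelse(is.na(x$projection_50), "not reached",
                       x$projection_50)))
  invisible(x)
}
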