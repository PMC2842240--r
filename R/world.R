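#' Configuration for a synthetic sequence archive
#'
#' Builds and validates the parameter set for [generate_world()], which
#' emulates a public nucleotide archive at desk scale: a clade hierarchy with
#' described species diversities, one true (pure-birth) tree per clade,
#' several loci with heterogeneous substitution rates, clade- and year-biased
#' deposition intensities over an era of annual submissions, and the common
#' contaminant classes that real archives carry (hybrid names, misspelled
#' names, unsuitable sequence classes, model-organism oversampling).
#'
#' @param n_clades Number of analysis clades to simulate.
#' @param species_per_clade Either a length-2 integer range (species counts
#'   drawn uniformly per clade) or a vector of length `n_clades`.
#' @param n_loci Number of loci ("genes") per clade.
#' @param locus_rates Per-locus substitution-rate multipliers (positive).
#'   Default spans a fast-mitochondrial to slow-nuclear contrast,
#'   geometrically spaced from 2 down to 0.5.
#' @param locus_length Ungapped length in bp of each locus (recycled).
#' @param locus_weights Relative deposition weight per locus (recycled);
#'   values > 1 emulate markers favoured by the community.
#' @param years Deposition years, strictly increasing (default 1993:2008).
#' @param intensity `n_clades x length(years)` matrix of per-(species, locus)
#'   per-year deposition probabilities. The default is an increasing-by-year
#'   ramp (0.01 to 0.15) scaled per clade by a 0.4 to 1.6 gradient, emulating
#'   uneven research effort across clades.
#' @param kappa Transition/transversion rate ratio of the two-parameter
#'   (HKY-class) substitution model.
#' @param base_freqs Equilibrium base frequencies (A, C, G, T), summing to 1.
#' @param tree_depth Root-to-tip depth of each true tree in expected
#'   substitutions per site (before locus rate multipliers).
#' @param frag_min Deposited sequences are end-truncated fragments covering a
#'   uniform fraction in `[frag_min, 1]` of the locus.
#' @param hybrid_rate,misspell_rate,unsuitable_rate Per-record contamination
#'   probabilities in `[0, 1]`.
#' @param model_rate Per-species probability of being a model organism.
#' @param model_records Total records deposited for each model organism
#'   (default 60; pair with a commensurate `model_threshold` in
#'   [filter_policy()]).
#' @param seed Integer RNG seed; identical configs and seeds yield
#'   byte-identical worlds.
#' @return An object of class `world_config` (a validated list).
#' @seealso [generate_world()], [write_world()]
#' @export
world_config <- function(n_clades = 10,
                         species_per_clade = c(8L, 20L),
                         n_loci = 4,
                         locus_rates = NULL,
                         locus_length = 500,
                         locus_weights = 1,
                         years = 1993:2008,
                         intensity = NULL,
                         kappa = 2,
                         base_freqs = rep(0.25, 4),
                         tree_depth = 0.2,
                         frag_min = 0.6,
                         hybrid_rate = 0.01,
                         misspell_rate = 0.02,
                         unsuitable_rate = 0.02,
                         model_rate = 0.005,
                         model_records = 60,
                         seed = 1L) {
  n_clades <- as.integer(n_clades)
  n_loci <- as.integer(n_loci)
  if (n_clades < 1L) stopf("n_clades must be >= 1")
  if (n_loci < 1L) stopf("n_loci must be >= 1")
  years <- as.integer(years)
  if (length(years) < 1L || any(diff(years) <= 0L))
    stopf("years must be strictly increasing")
  if (is.null(locus_rates))
    locus_rates <- if (n_loci == 1L) 1 else
      2 * (0.25^(seq_len(n_loci) - 1L) ^ (1 / (n_loci - 1L)))
  locus_rates <- rep_len(locus_rates, n_loci)
  if (any(locus_rates < 0)) stopf("locus_rates must be >= 0")
  locus_length <- rep_len(as.integer(locus_length), n_loci)
  if (any(locus_length < 1L)) stopf("locus_length must be positive")
  locus_weights <- rep_len(locus_weights, n_loci)
  if (any(locus_weights < 0)) stopf("locus_weights must be >= 0")
  if (is.null(intensity)) {
    clade_scale <- if (n_clades == 1L) 1 else
      seq(0.4, 1.6, length.out = n_clades)
    intensity <- clade_scale %o% seq(0.01, 0.15, length.out = length(years))
  }
  intensity <- as.matrix(intensity)
  if (!all(dim(intensity) == c(n_clades, length(years))))
    stopf("intensity must be an n_clades x n_years matrix")
  if (any(intensity < 0)) stopf("intensity must be nonnegative")
  probs <- c(hybrid_rate, misspell_rate, unsuitable_rate, model_rate)
  if (any(probs < 0 | probs > 1))
    stopf("contaminant rates must lie in [0, 1]")
  if (length(base_freqs) != 4L || abs(sum(base_freqs) - 1) > 1e-8 ||
      any(base_freqs < 0))
    stopf("base_freqs must be 4 nonnegative values summing to 1")
  if (kappa <= 0) stopf("kappa must be positive")
  if (tree_depth < 0) stopf("tree_depth must be nonnegative")
  if (frag_min <= 0 || frag_min > 1) stopf("frag_min must lie in (0, 1]")
  spc <- as.integer(species_per_clade)
  if (!length(spc) %in% c(2L, n_clades))
    stopf("species_per_clade must be a range or one value per clade")
  if (any(spc < 3L)) stopf("each clade needs at least 3 species")
  structure(list(
    n_clades = n_clades, species_per_clade = spc, n_loci = n_loci,
    locus_rates = locus_rates, locus_length = locus_length,
    locus_weights = locus_weights, years = years, intensity = intensity,
    kappa = kappa, base_freqs = base_freqs, tree_depth = tree_depth,
    frag_min = frag_min, hybrid_rate = hybrid_rate,
    misspell_rate = misspell_rate, unsuitable_rate = unsuitable_rate,
    model_rate = model_rate, model_records = as.integer(model_records),
    seed = as.integer(seed)), class = "world_config")
}

# Pure-birth tree rescaled so the maximum root-to-tip path equals `depth`
# expected substitutions per site.
simulate_true_tree <- function(n_species, depth) {
  tr <- ape::rphylo(n_species, birth = 1, death = 0)
  h <- max(ape::node.depth.edgelength(tr))
  if (h > 0 && depth > 0) tr$edge.length <- tr$edge.length * depth / h
  else tr$edge.length <- tr$edge.length * 0
  tr
}

# Evolve one locus along `tree` under the two-parameter model and return a
# named character vector of uppercase sequences.
simulate_locus <- function(tree, len, kappa, base_freqs, rate) {
  if (rate == 0) {
    anc <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                  prob = base_freqs)
    seqs <- rep(chars_to_seq(anc), length(tree$tip.label))
    names(seqs) <- tree$tip.label
    return(seqs)
  }
  dat <- phangorn::simSeq(tree, l = len,
                          Q = c(1, kappa, 1, 1, kappa, 1),
                          bf = base_freqs, rate = rate)
  m <- toupper(as.character(dat))
  seqs <- apply(m, 1L, paste, collapse = "")
  names(seqs) <- rownames(m)
  seqs
}

misspell_name <- function(name) {
  # Perturb the epithet: duplicate one interior letter.  Deterministic given
  # the RNG state; never collides with canonical "Gxx spNNN" names.
  parts <- strsplit(name, " ", fixed = TRUE)[[1L]]
  ep <- parts[length(parts)]
  i <- sample.int(nchar(ep), 1L)
  ep2 <- paste0(substr(ep, 1L, i), substr(ep, i, nchar(ep)))
  paste(c(parts[-length(parts)], ep2), collapse = " ")
}

#' Generate a synthetic sequence archive with a known truth channel
#'
#' Simulates the "world" behind a public sequence archive: a three-level
#' taxonomy (root, two supergroups, `n_clades` clades) with described species
#' counts; one binary pure-birth tree per clade; per-locus sequences evolved
#' under an HKY-class model; and deposited records — end-truncated fragments
#' with accessions, deposition dates and contaminant injections — emitted
#' with per-clade-per-year intensity. All truth (taxonomy, trees, locus
#' assignment, canonical names) is retained so downstream inference can be
#' validated against it.
#'
#' @param config A [world_config()].
#' @return An object of class `synthetic_world`: a list with elements
#'   `taxonomy` (data frame: clade, parent, described_species), `species`
#'   (species to clade map), `trees` (named list of `phylo`), `records`
#'   (data frame of deposited records, including the `species_true` truth
#'   column), `aliases` (misspelling to canonical map) and `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  if (sum(config$intensity) == 0 && config$model_rate == 0)
    stopf("total sampling intensity is zero: nothing to generate")
  with_seed(config$seed, generate_world_impl(config))
}

generate_world_impl <- function(config) {
  nc <- config$n_clades
  clades <- sprintf("C%02d", seq_len(nc))
  n_sp <- if (length(config$species_per_clade) == nc) {
    config$species_per_clade
  } else {
    r <- config$species_per_clade
    r[1L] + sample.int(r[2L] - r[1L] + 1L, nc, replace = TRUE) - 1L
  }
  super <- ifelse(seq_len(nc) <= ceiling(nc / 2), "SuperA", "SuperB")
  taxonomy <- rbind(
    data.frame(clade = "Root", parent = NA_character_,
               described_species = sum(n_sp)),
    data.frame(clade = unique(super), parent = "Root",
               described_species = as.numeric(tapply(n_sp, super, sum)[unique(super)])),
    data.frame(clade = clades, parent = super, described_species = n_sp))

  species <- data.frame(
    species = unlist(lapply(seq_len(nc), function(i)
      sprintf("G%s sp%03d", sub("^C", "", clades[i]), seq_len(n_sp[i])))),
    clade = rep(clades, n_sp), stringsAsFactors = FALSE)

  trees <- vector("list", nc); names(trees) <- clades
  locus_seqs <- vector("list", nc); names(locus_seqs) <- clades
  for (i in seq_len(nc)) {
    tr <- simulate_true_tree(n_sp[i], config$tree_depth)
    tr$tip.label <- species$species[species$clade == clades[i]][
      as.integer(sub("^t", "", tr$tip.label))]
    trees[[i]] <- tr
    locus_seqs[[i]] <- lapply(seq_len(config$n_loci), function(l)
      simulate_locus(tr, config$locus_length[l], config$kappa,
                     config$base_freqs, config$locus_rates[l]))
  }

  # Deposition: Bernoulli per (species, locus, year) with clade-year
  # intensity times the locus weight, capped at 1.
  rec <- list(); k <- 0L
  years <- config$years
  for (i in seq_len(nc)) {
    sp_i <- species$species[species$clade == clades[i]]
    for (s in seq_along(sp_i)) {
      for (l in seq_len(config$n_loci)) {
        p <- pmin(1, config$intensity[i, ] * config$locus_weights[l])
        hit <- which(stats::runif(length(years)) < p)
        for (y in hit) {
          k <- k + 1L
          rec[[k]] <- list(clade = clades[i], species = sp_i[s],
                           locus = l, year = years[y])
        }
      }
    }
  }
  records <- if (k) {
    data.frame(clade = vapply(rec, `[[`, "", "clade"),
               species_true = vapply(rec, `[[`, "", "species"),
               locus = vapply(rec, function(r) as.integer(r$locus), 0L),
               year = vapply(rec, function(r) as.integer(r$year), 0L),
               stringsAsFactors = FALSE)
  } else {
    data.frame(clade = character(), species_true = character(),
               locus = integer(), year = integer())
  }

  # Model organisms: inflate one species' record pool far past the filter
  # threshold, mimicking genome/resequencing projects.
  is_model <- stats::runif(nrow(species)) < config$model_rate
  for (s in which(is_model)) {
    extra <- config$model_records
    records <- rbind(records, data.frame(
      clade = rep(species$clade[s], extra),
      species_true = rep(species$species[s], extra),
      locus = rep(1L, extra),
      year = sample(years, extra, replace = TRUE)))
  }

  n <- nrow(records)
  if (n > 0) {
    ord <- order(records$clade, records$species_true, records$locus,
                 records$year)
    records <- records[ord, , drop = FALSE]
    records$accession <- sprintf("A%06d", seq_len(n))
    doy <- sample.int(365L, n, replace = TRUE)
    records$date <- format(as.Date(doy - 1L,
                                   origin = paste0(records$year, "-01-01")))
    # End-truncated fragments of the species' true locus sequence.
    frac <- stats::runif(n, config$frag_min, 1)
    from_start <- stats::runif(n) < 0.5
    records$sequence <- vapply(seq_len(n), function(r) {
      full <- locus_seqs[[records$clade[r]]][[records$locus[r]]][
        records$species_true[r]]
      len <- max(1L, as.integer(round(frac[r] * nchar(full))))
      if (from_start[r]) substr(full, 1L, len)
      else substr(full, nchar(full) - len + 1L, nchar(full))
    }, "")
    records$length <- nchar(records$sequence)

    # Contaminants.  Each record draws at most one contamination type so the
    # truth channel stays unambiguous.
    u <- stats::runif(n)
    p1 <- config$hybrid_rate
    p2 <- p1 + config$misspell_rate
    p3 <- p2 + config$unsuitable_rate
    records$class_flag <- ifelse(u >= p2 & u < p3,
                                 sample(c("microsatellite", "repetitive"),
                                        n, replace = TRUE), "ok")
    records$species <- records$species_true
    aliases <- data.frame(variant = character(), canonical = character())
    for (r in which(u < p1)) {
      mates <- setdiff(species$species[species$clade == records$clade[r]],
                       records$species_true[r])
      if (!length(mates)) next
      records$species[r] <- paste(records$species_true[r], "x",
                                  sample(mates, 1L))
    }
    for (r in which(u >= p1 & u < p2)) {
      v <- misspell_name(records$species_true[r])
      records$species[r] <- v
      aliases <- rbind(aliases, data.frame(
        variant = v, canonical = records$species_true[r]))
    }
    aliases <- unique(aliases)
  } else {
    records$accession <- character(); records$date <- character()
    records$sequence <- character(); records$length <- integer()
    records$class_flag <- character(); records$species <- character()
    aliases <- data.frame(variant = character(), canonical = character())
  }
  records <- records[, c("accession", "species", "species_true", "clade",
                         "date", "year", "locus", "class_flag", "length",
                         "sequence")]
  rownames(records) <- NULL
  structure(list(taxonomy = taxonomy, species = species, trees = trees,
                 records = records, aliases = aliases, config = config),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "synthetic_world: %d clades, %d species, %d loci, %d records (%d-%d)\n",
    x$config$n_clades, nrow(x$species), x$config$n_loci, nrow(x$records),
    min(x$config$years), max(x$config$years)))
  invisible(x)
}

#' Write a synthetic world to plain-text archive files
#'
#' Emits one FASTA per clade plus tab-separated metadata, taxonomy, species,
#' alias and truth tables, and one Newick file per true tree. The layout
#' round-trips losslessly through [read_world()] and the
#' [read_records()]/[read_taxonomy()] readers.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "trees"), showWarnings = FALSE)
  md <- world$records[, c("accession", "species", "clade", "date", "locus",
                          "class_flag")]
  names(md)[names(md) == "locus"] <- "locus_truth"
  utils::write.table(md, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(world$taxonomy, file.path(dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(world$species, file.path(dir, "species.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(world$aliases, file.path(dir, "aliases.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(world$records[, c("accession", "species_true")],
                     file.path(dir, "truth_records.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tips <- setdiff(world$taxonomy$clade,
                  world$taxonomy$parent[!is.na(world$taxonomy$parent)])
  for (cl in tips) {
    rr <- world$records[world$records$clade == cl, , drop = FALSE]
    ss <- Biostrings::DNAStringSet(rr$sequence)
    names(ss) <- rr$accession
    Biostrings::writeXStringSet(ss, file.path(dir,
                                              sprintf("records_%s.fasta", cl)))
    if (cl %in% names(world$trees))
      ape::write.tree(world$trees[[cl]],
                      file.path(dir, "trees", paste0(cl, ".nwk")))
  }
  invisible(dir)
}

#' Read back a synthetic world directory
#'
#' @param dir Directory written by [write_world()].
#' @return A list with `taxonomy`, `species`, `aliases`, `records`
#'   (metadata joined with sequences) and `trees`.
#' @export
read_world <- function(dir) {
  taxonomy <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  species <- utils::read.delim(file.path(dir, "species.tsv"),
                               stringsAsFactors = FALSE)
  aliases <- utils::read.delim(file.path(dir, "aliases.tsv"),
                               stringsAsFactors = FALSE)
  fas <- list.files(dir, pattern = "^records_.*\\.fasta$", full.names = TRUE)
  records <- read_records(fas, file.path(dir, "metadata.tsv"), taxonomy)
  treefiles <- list.files(file.path(dir, "trees"), pattern = "\\.nwk$",
                          full.names = TRUE)
  trees <- lapply(treefiles, ape::read.tree)
  names(trees) <- sub("\\.nwk$", "", basename(treefiles))
  list(taxonomy = taxonomy, species = species, aliases = aliases,
       records = records, trees = trees)
}
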