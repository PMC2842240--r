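#' Read a taxonomy table
#'
#' Reads a tab-separated clade hierarchy with described species counts
#' (columns `clade`, `parent`, `described_species`). Described counts come
#' from taxonomic checklists and may exceed the number of species with any
#' sequence deposited.
#'
#' @param path TSV file path.
#' @return A data frame of class `taxonomy_table`, one row per clade, with a
#'   single root (empty/NA parent).
#' @export
read_taxonomy <- function(path) {
  tx <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric"))
  if (!all(c("clade", "parent", "described_species") %in% names(tx)))
    stopf("taxonomy file must have clade, parent, described_species columns")
  tx$parent[tx$parent == ""] <- NA_character_
  roots <- is.na(tx$parent)
  if (sum(roots) != 1L) stopf("taxonomy must have exactly one root")
  if (anyDuplicated(tx$clade)) stopf("duplicate clade ids in taxonomy")
  bad <- !is.na(tx$parent) & !tx$parent %in% tx$clade
  if (any(bad)) stopf("unknown parent clade: %s", tx$parent[bad][1L])
  class(tx) <- c("taxonomy_table", "data.frame")
  tx
}

#' Read sequence records from FASTA plus a metadata sidecar
#'
#' Joins FASTA entries (ids = accessions) with a tab-separated metadata table
#' (`accession`, `species`, `clade`, `date`, optional `locus_truth`,
#' `class_flag`). Sequences are uppercased; hybrid records are recognised by
#' the " x " infix in the species name; unknown clades and accessions missing
#' from the metadata raise errors naming the offender.
#'
#' @param fasta One or more FASTA paths.
#' @param metadata Metadata TSV path.
#' @param taxonomy A [read_taxonomy()] table used to validate clade ids.
#' @return A data frame of records: accession, species, clade, date, year,
#'   length, sequence, class_flag, hybrid (+ locus_truth when present).
#' @export
read_records <- function(fasta, metadata, taxonomy) {
  md <- utils::read.delim(metadata, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("accession", "species", "clade", "date")
  if (!all(need %in% names(md)))
    stopf("metadata must have columns: %s", paste(need, collapse = ", "))
  seqs <- do.call(c, lapply(fasta, Biostrings::readDNAStringSet))
  if (is.null(seqs)) seqs <- Biostrings::DNAStringSet()
  ids <- sub("\\s.*$", "", names(seqs))
  missing_md <- setdiff(ids, md$accession)
  if (length(missing_md))
    stopf("no metadata row for accession %s", missing_md[1L])
  md <- md[match(ids, md$accession), , drop = FALSE]
  bad <- !md$clade %in% taxonomy$clade
  if (any(bad))
    stopf("record %s has unknown clade '%s'", md$accession[bad][1L],
          md$clade[bad][1L])
  out <- data.frame(
    accession = md$accession,
    species = md$species,
    clade = md$clade,
    date = md$date,
    year = as.integer(substr(md$date, 1L, 4L)),
    sequence = toupper(as.character(seqs)),
    class_flag = if ("class_flag" %in% names(md)) md$class_flag else "ok",
    stringsAsFactors = FALSE)
  out$length <- nchar(out$sequence)
  if (any(out$length == 0L))
    stopf("record %s has an empty sequence", out$accession[out$length == 0L][1L])
  out$hybrid <- grepl(" x ", out$species, fixed = TRUE)
  if ("locus_truth" %in% names(md))
    out$locus_truth <- as.integer(md$locus_truth)
  rownames(out) <- NULL
  out
}

#' Record inclusion policy
#'
#' Length bounds are inclusive: records between `min_len` and `max_len` bp
#' pass. Species whose total record count in the input pool exceeds
#' `model_threshold` are treated as model organisms and excluded wholesale,
#' since archive data for such species is dominated by genome and
#' resequencing projects rather than phylogenetics.
#'
#' @param min_len,max_len Inclusive length bounds in bp (defaults 100, 5000).
#' @param model_threshold Records-per-species cutoff above which a species is
#'   excluded as a model organism (default 10000; scale down for synthetic
#'   worlds).
#' @param excluded_flags Sequence-class flags deemed unsuitable for
#'   phylogenetics.
#' @param exclude_hybrids Drop records not assignable to a single species.
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(min_len = 100L, max_len = 5000L,
                          model_threshold = 10000L,
                          excluded_flags = c("microsatellite", "repetitive",
                                             "paralog_suspect",
                                             "other_unsuitable"),
                          exclude_hybrids = TRUE) {
  if (min_len <= 0 || min_len > max_len)
    stopf("need 0 < min_len <= max_len")
  structure(list(min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 model_threshold = as.integer(model_threshold),
                 excluded_flags = excluded_flags,
                 exclude_hybrids = isTRUE(exclude_hybrids)),
            class = "filter_policy")
}

#' Apply inclusion filters to records
#'
#' Partitions records into kept and rejected sets. Each rejection carries
#' exactly one reason, assigned by the first matching rule in fixed order:
#' `length`, `class`, `hybrid`, `model_organism`. Model-organism counts are
#' computed on the full input pool per species, before any other filter.
#'
#' @param records Records data frame from [read_records()].
#' @param policy A [filter_policy()].
#' @return List with `kept` (records) and `rejected` (records plus `reason`).
#' @export
filter_records <- function(records, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  n <- nrow(records)
  if (n == 0L)
    return(list(kept = records,
                rejected = cbind(records, reason = character(0))))
  pool <- table(records$species)
  model_sp <- names(pool)[pool > policy$model_threshold]
  reason <- rep(NA_character_, n)
  bad_len <- records$length < policy$min_len | records$length > policy$max_len
  reason[is.na(reason) & bad_len] <- "length"
  reason[is.na(reason) & records$class_flag %in% policy$excluded_flags] <-
    "class"
  if (policy$exclude_hybrids)
    reason[is.na(reason) & records$hybrid] <- "hybrid"
  reason[is.na(reason) & records$species %in% model_sp] <- "model_organism"
  keep <- is.na(reason)
  rejected <- records[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  rownames(rejected) <- NULL
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, rejected = rejected)
}

#' Standardize species names against an alias table
#'
#' Replaces name variants (misspellings, alternative spellings) by their
#' canonical species names, following alias chains to a fixed point. Records
#' whose name maps to more than one canonical species are dropped with
#' reason `ambiguous`; alias cycles raise an error.
#'
#' @param records Records data frame.
#' @param aliases Data frame with columns `variant`, `canonical`.
#' @return List with `records` (names canonicalised) and `dropped`
#'   (ambiguous records, with `reason`).
#' @export
standardize_names <- function(records, aliases) {
  if (nrow(records) == 0L || nrow(aliases) == 0L) {
    dropped <- records[0, , drop = FALSE]
    dropped$reason <- character(0)
    return(list(records = records, dropped = dropped))
  }
  dup <- unique(aliases$variant[duplicated(aliases$variant)])
  ambiguous_variants <- character(0)
  for (v in dup) {
    tg <- unique(aliases$canonical[aliases$variant == v])
    if (length(tg) > 1L) ambiguous_variants <- c(ambiguous_variants, v)
  }
  amap <- aliases[!aliases$variant %in% ambiguous_variants, , drop = FALSE]
  lookup <- stats::setNames(amap$canonical, amap$variant)
  resolve <- function(name) {
    seen <- character(0)
    while (name %in% names(lookup)) {
      if (name %in% seen) stopf("alias cycle involving '%s'", name)
      seen <- c(seen, name)
      name <- unname(lookup[[name]])
    }
    name
  }
  amb <- records$species %in% ambiguous_variants
  out <- records[!amb, , drop = FALSE]
  out$species <- vapply(out$species, resolve, "", USE.NAMES = FALSE)
  dropped <- records[amb, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- "ambiguous"
  else dropped$reason <- character(0)
  rownames(out) <- NULL
  rownames(dropped) <- NULL
  list(records = out, dropped = dropped)
}

# Number of sampled species (>=1 record) under each taxonomy node, plus a
# per-species count of 1/0 handled implicitly by the caller.
sampled_counts <- function(taxonomy, species_table, sampled_species) {
  sampled_species <- unique(sampled_species)
  sampled_species <- sampled_species[sampled_species %in%
                                     species_table$species]
  direct <- table(species_table$clade[species_table$species %in%
                                      sampled_species])
  counts <- stats::setNames(rep(0, nrow(taxonomy)), taxonomy$clade)
  counts[names(direct)] <- as.numeric(direct)
  # Push counts rootward; taxonomy rows are few, iterate to fixed point.
  kids <- split(taxonomy$clade, taxonomy$parent)
  total <- function(node) {
    ch <- kids[[node]]
    counts[[node]] + if (is.null(ch)) 0 else sum(vapply(ch, total, 0))
  }
  vapply(taxonomy$clade, total, 0)
}

ancestor_chain <- function(taxonomy, clade) {
  chain <- clade
  parent <- stats::setNames(taxonomy$parent, taxonomy$clade)
  while (!is.na(parent[[chain[length(chain)]]]))
    chain <- c(chain, parent[[chain[length(chain)]]])
  chain
}

#' Select non-overlapping analysis clades
#'
#' Repeats the sampling rule used to pick analysis clades: draw a sampled
#' species uniformly at random, then walk rootward to the largest ancestor
#' containing it that still holds fewer than `max_sampled` sampled species
#' (species with at least one record). If even the species' own clade is at
#' or above the cutoff, the species itself is selected. A draw landing inside
#' or above an already selected clade is discarded (rejection sampling), so
#' the accepted clades are pairwise disjoint.
#'
#' @param taxonomy A [read_taxonomy()] table.
#' @param species_table Data frame `species`, `clade` mapping species to
#'   their (tip-level) clade.
#' @param sampled_species Character vector of species with >= 1 record.
#' @param n_clades Number of clades requested.
#' @param max_sampled Sampled-species cutoff (default 500).
#' @param seed RNG seed; selection is deterministic given the seed.
#' @return Character vector of selected clade ids (species names when the
#'   walk stops at tip level), with attribute `shortfall` giving how many
#'   requested clades could not be found (warned about when positive).
#' @export
select_clades <- function(taxonomy, species_table, sampled_species,
                          n_clades, max_sampled = 500L, seed = 1L) {
  n_clades <- as.integer(n_clades)
  counts <- sampled_counts(taxonomy, species_table, sampled_species)
  pool <- intersect(unique(sampled_species), species_table$species)
  with_seed(seed, {
    pool <- sample(pool)
    selected <- character(0)
    covered <- character(0)   # species covered by accepted clades
    chosen_chains <- list()
    for (sp in pool) {
      clade0 <- species_table$clade[species_table$species == sp][1L]
      chain <- ancestor_chain(taxonomy, clade0)
      ok <- c(1L, which(counts[chain] < max_sampled) + 1L) # 1 = species level
      full_chain <- c(sp, chain)
      pick <- full_chain[max(ok)]
      members <- if (pick == sp) sp else clade_species(taxonomy,
                                                       species_table, pick)
      if (any(members %in% covered)) next
      # also reject picks strictly above an accepted clade (superset overlap
      # is covered by the member check since members would intersect)
      selected <- c(selected, pick)
      covered <- c(covered, members)
      if (length(selected) == n_clades) break
    }
    shortfall <- n_clades - length(selected)
    if (shortfall > 0)
      warning(sprintf("only %d of %d non-overlapping clades attainable",
                      length(selected), n_clades), call. = FALSE)
    structure(selected, shortfall = shortfall)
  })
}

# All species under a taxonomy node.
clade_species <- function(taxonomy, species_table, node) {
  nodes <- node
  repeat {
    kids <- taxonomy$clade[!is.na(taxonomy$parent) &
                           taxonomy$parent %in% nodes]
    new <- setdiff(kids, nodes)
    if (!length(new)) break
    nodes <- c(nodes, new)
  }
  species_table$species[species_table$clade %in% nodes]
}
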