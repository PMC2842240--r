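#' Align the records of one cluster
#'
#' Deterministic progressive alignment: records are added in order of
#' decreasing length (ties by accession) and each new sequence is aligned,
#' ends-free under unit costs, against the running column consensus. Merging
#' only ever inserts gap columns — characters are never altered — so
#' ungapping any row recovers its input sequence exactly.
#'
#' @param cluster A (deduplicated) cluster from [cluster_records()].
#' @return A `cluster_alignment`: list with `id`, `rows` (named gapped
#'   sequence strings; names are accessions), `species` (parallel species
#'   vector) and `width`.
#' @export
align_cluster <- function(cluster) {
  m <- cluster$members
  stopifnot(nrow(m) >= 1L)
  ord <- order(-m$length, m$accession)
  m <- m[ord, , drop = FALSE]
  mat <- matrix(seq_to_chars(m$sequence[1L]), nrow = 1L)
  for (i in seq_len(nrow(m))[-1L]) {
    cons <- consensus_chars(mat)
    al <- ends_free_align(m$sequence[i], chars_to_seq(cons))
    # al$b is the gapped consensus: its non-gap positions map old columns
    # into the merged coordinate system.
    bc <- seq_to_chars(al$b)
    map <- which(bc != "-")
    newmat <- matrix("-", nrow = nrow(mat) + 1L, ncol = length(bc))
    newmat[seq_len(nrow(mat)), map] <- mat
    newmat[nrow(mat) + 1L, ] <- seq_to_chars(al$a)
    mat <- newmat
  }
  rows <- apply(mat, 1L, paste, collapse = "")
  structure(list(id = cluster$id, rows = stats::setNames(rows, m$accession),
                 species = stats::setNames(m$species, m$accession),
                 width = ncol(mat)),
            class = "cluster_alignment")
}

# Majority non-gap character per column (ties alphabetical); used as the
# profile representative during progressive merging.
consensus_chars <- function(mat) {
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(mat == b),
                   numeric(ncol(mat)))
  counts <- matrix(counts, ncol = 4L)
  # ties.method = "first" on A,C,G,T order gives the alphabetical tie-break
  best <- max.col(counts, ties.method = "first")
  cons <- bases[best]
  none <- rowSums(counts) == 0
  # columns with no A/C/G/T majority fall back to the first non-gap char
  if (any(none)) {
    cons[none] <- apply(mat[, none, drop = FALSE], 2L, function(col) {
      nz <- col[col != "-"]
      if (length(nz)) nz[1L] else "A"
    })
  }
  cons
}

# Restrict an alignment to a subset of accessions, dropping all-gap columns.
subset_alignment <- function(alignment, accessions) {
  keep <- names(alignment$rows) %in% accessions
  rows <- alignment$rows[keep]
  species <- alignment$species[keep]
  if (!length(rows))
    return(structure(list(id = alignment$id, rows = rows, species = species,
                          width = 0L), class = "cluster_alignment"))
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  nongap <- colSums(mat != "-") > 0L
  mat <- mat[, nongap, drop = FALSE]
  rows <- stats::setNames(apply(mat, 1L, paste, collapse = ""), names(rows))
  structure(list(id = alignment$id, rows = rows, species = species,
                 width = sum(nongap)), class = "cluster_alignment")
}

#' Select the informative, mutually overlapping cluster set
#'
#' Iterates to a fixed point the two inclusion rules for supermatrix
#' membership: a cluster must contain at least `min_species` species and
#' share at least `min_overlap` species with at least one other retained
#' cluster. Dropping a cluster can orphan its only partner, hence the
#' iteration. If the survivors split into several connected components of
#' the overlap graph, the component with the most species is kept (ties:
#' more clusters, then smallest cluster id).
#'
#' @param alignments List of `cluster_alignment` objects (one clade-year).
#' @param min_species Minimum species per cluster (default 4).
#' @param min_overlap Minimum shared species between partners (default 4).
#' @return The retained sublist (possibly empty).
#' @export
select_informative <- function(alignments, min_species = 4L,
                               min_overlap = 4L) {
  if (!length(alignments)) return(alignments)
  sp <- lapply(alignments, function(a) unique(unname(a$species)))
  alive <- vapply(sp, length, 0L) >= min_species
  repeat {
    idx <- which(alive)
    if (!length(idx)) break
    has_partner <- vapply(idx, function(i) {
      any(vapply(setdiff(idx, i), function(j)
        length(intersect(sp[[i]], sp[[j]])) >= min_overlap, TRUE))
    }, TRUE)
    if (all(has_partner)) break
    alive[idx[!has_partner]] <- FALSE
  }
  idx <- which(alive)
  if (length(idx) < 2L) return(alignments[integer(0)])
  # connected components of the overlap graph among survivors
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  pairs <- utils::combn(seq_along(idx), 2L)
  for (k in seq_len(ncol(pairs))) {
    i <- idx[pairs[1L, k]]; j <- idx[pairs[2L, k]]
    if (length(intersect(sp[[i]], sp[[j]])) >= min_overlap)
      g <- igraph::add_edges(g, pairs[, k])
  }
  memb <- igraph::components(g)$membership
  comp_stats <- lapply(unique(memb), function(cm) {
    members <- idx[memb == cm]
    list(cm = cm, n_species = length(unique(unlist(sp[members]))),
         n_clusters = length(members),
         min_id = min(vapply(alignments[members], `[[`, "", "id")))
  })
  ord <- order(-vapply(comp_stats, `[[`, 0L, "n_species"),
               -vapply(comp_stats, `[[`, 0L, "n_clusters"),
               vapply(comp_stats, `[[`, "", "min_id"))
  best <- comp_stats[[ord[1L]]]$cm
  alignments[idx[memb == best]]
}

#' Concatenate aligned clusters into a partitioned supermatrix
#'
#' Builds one row per species in the union of the retained clusters; cells
#' in partitions lacking a species are the missing character `?` (gaps
#' within an aligned cluster remain `-` and count as data). Partition
#' coordinates are recorded 0-based half-open.
#'
#' @param alignments Retained `cluster_alignment` list (see
#'   [select_informative()]); species-deduplicated rows are assumed.
#' @return A `supermatrix`: list with `matrix` (character matrix, rownames =
#'   species), `partitions` (data frame cluster, start, end), `width`,
#'   `density` (fraction of non-missing cells) and `characters_per_species`.
#' @export
concatenate_alignments <- function(alignments) {
  if (!length(alignments)) stopf("no alignments to concatenate")
  all_sp <- sort(unique(unlist(lapply(alignments, function(a)
    unname(a$species)))))
  widths <- vapply(alignments, `[[`, 0L, "width")
  total <- sum(widths)
  mat <- matrix("?", nrow = length(all_sp), ncol = total,
                dimnames = list(all_sp, NULL))
  at <- 0L
  parts <- data.frame(cluster = character(0), start = integer(0),
                      end = integer(0))
  for (a in alignments) {
    cols <- (at + 1L):(at + a$width)
    for (i in seq_along(a$rows)) {
      mat[a$species[[i]], cols] <- seq_to_chars(a$rows[[i]])
    }
    parts <- rbind(parts, data.frame(cluster = a$id, start = at,
                                     end = at + a$width))
    at <- at + a$width
  }
  new_supermatrix(mat, parts)
}

new_supermatrix <- function(mat, parts) {
  nonmiss <- mat != "?"
  structure(list(matrix = mat, partitions = parts, width = ncol(mat),
                 density = mean(nonmiss),
                 characters_per_species = mean(rowSums(nonmiss))),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf(
    "supermatrix: %d species x %d sites, %d partitions, density %.3f\n",
    nrow(x$matrix), x$width, nrow(x$partitions), x$density))
  invisible(x)
}

#' Write a supermatrix to NEXUS (with CHARSET blocks) or relaxed PHYLIP
#'
#' @param sm A `supermatrix`.
#' @param path Output file.
#' @param format `"nexus"` (default; includes an assumptions block with
#'   1-based inclusive CHARSET coordinates) or `"phylip"`.
#' @return `path`, invisibly.
#' @export
write_supermatrix <- function(sm, path, format = c("nexus", "phylip")) {
  format <- match.arg(format)
  seqs <- apply(sm$matrix, 1L, paste, collapse = "")
  taxa <- rownames(sm$matrix)
  safe <- gsub(" ", "_", taxa)
  con <- file(path, "w"); on.exit(close(con))
  if (format == "nexus") {
    writeLines(c("#NEXUS", "", "BEGIN DATA;",
                 sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(taxa),
                         sm$width),
                 "  FORMAT DATATYPE=DNA MISSING=? GAP=-;",
                 "  MATRIX"), con)
    writeLines(sprintf("    %s  %s", formatC(safe, width = max(nchar(safe)),
                                             flag = "-"), seqs), con)
    writeLines(c("  ;", "END;", "", "BEGIN ASSUMPTIONS;"), con)
    writeLines(sprintf("  CHARSET %s = %d-%d;", sm$partitions$cluster,
                       sm$partitions$start + 1L, sm$partitions$end), con)
    writeLines("END;", con)
  } else {
    writeLines(sprintf("%d %d", length(taxa), sm$width), con)
    writeLines(paste(safe, seqs), con)
  }
  invisible(path)
}

#' Read a NEXUS supermatrix written by [write_supermatrix()]
#'
#' @param path NEXUS file path.
#' @return A `supermatrix` (bit-exact round trip of matrix and partitions).
#' @export
read_supermatrix <- function(path) {
  lines <- readLines(path)
  mstart <- grep("^  MATRIX$", lines)[1L]
  mend <- grep("^  ;$", lines)[1L]
  rows <- lines[(mstart + 1L):(mend - 1L)]
  parts <- do.call(rbind, lapply(
    grep("^  CHARSET ", lines, value = TRUE), function(l) {
      m <- regmatches(l, regexec("CHARSET (\\S+) = (\\d+)-(\\d+);", l))[[1L]]
      data.frame(cluster = m[2L], start = as.integer(m[3L]) - 1L,
                 end = as.integer(m[4L]))
    }))
  fields <- regmatches(rows, regexec("^\\s*(\\S+)\\s+(\\S+)$", rows))
  taxa <- gsub("_", " ", vapply(fields, `[[`, "", 2L))
  seqs <- vapply(fields, `[[`, "", 3L)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- taxa
  new_supermatrix(mat, parts)
}
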