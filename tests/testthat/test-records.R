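# Record reading, inclusion filters, name standardization, clade selection.

write_fixture_archive <- function(dir, records, taxonomy) {
  ss <- Biostrings::DNAStringSet(records$sequence)
  names(ss) <- records$accession
  Biostrings::writeXStringSet(ss, file.path(dir, "records_all.fasta"))
  md <- records[, c("accession", "species", "clade", "date", "class_flag")]
  write.table(md, file.path(dir, "metadata.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(taxonomy, file.path(dir, "taxonomy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

toy_taxonomy <- data.frame(
  clade = c("Root", "CladeA", "CladeB"),
  parent = c(NA, "Root", "Root"),
  described_species = c(20, 12, 8))

test_that("read_records joins FASTA with metadata and normalises case", {
  dir <- withr::local_tempdir()
  recs <- make_records(c("A1", "A2", "A3"),
                       c("Gen spa", "Gen spb", "Gen spc"),
                       c("acgtacgt", "ACGTACGTAA", "TTTTCCCC"))
  write_fixture_archive(dir, recs, toy_taxonomy)
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  got <- read_records(file.path(dir, "records_all.fasta"),
                      file.path(dir, "metadata.tsv"), tax)
  expect_identical(nrow(got), 3L)
  expect_identical(got$sequence[got$accession == "A1"], "ACGTACGT")
  expect_identical(got$length[got$accession == "A1"], 8L)
})

test_that("a FASTA id missing from the metadata raises a named error", {
  dir <- withr::local_tempdir()
  recs <- make_records(c("A1", "A2"), "Gen spa", c("ACGT", "GGGG"))
  write_fixture_archive(dir, recs, toy_taxonomy)
  md <- read.delim(file.path(dir, "metadata.tsv"))
  write.table(md[md$accession != "A2", ], file.path(dir, "metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  expect_error(read_records(file.path(dir, "records_all.fasta"),
                            file.path(dir, "metadata.tsv"), tax), "A2")
})

test_that("length bounds are inclusive and rejections carry one reason", {
  pol <- filter_policy(min_len = 100, max_len = 5000, model_threshold = 10)
  recs <- make_records(
    c("A1", "A2", "A3", "A4", "A5"),
    c("Gen spa", "Gen spb", "Gen spc", "Gen spd", "Gen spa x Gen spb"),
    c(strrep("A", 50), strrep("C", 100), strrep("G", 5000),
      strrep("T", 5001), strrep("A", 200)))
  out <- filter_records(recs, pol)
  expect_setequal(out$kept$accession, c("A2", "A3"))
  rej <- setNames(out$rejected$reason, out$rejected$accession)
  expect_identical(rej[["A1"]], "length")
  expect_identical(rej[["A4"]], "length")
  expect_identical(rej[["A5"]], "hybrid")
})

test_that("model organisms are excluded on pre-filter pool counts", {
  pol <- filter_policy(model_threshold = 3)
  recs <- make_records(sprintf("A%02d", 1:6),
                       c(rep("Gen model", 4), "Gen rare", "Gen rare2"),
                       c(strrep("A", 150), strrep("C", 150), strrep("G", 150),
                         strrep("T", 50), strrep("AC", 75), strrep("GT", 75)))
  out <- filter_records(recs, pol)
  # 4 model-organism records exist in the pool; the short one is rejected as
  # "length" first (fixed precedence), the rest as model_organism
  rej <- setNames(out$rejected$reason, out$rejected$accession)
  expect_identical(unname(rej["A04"]), "length")
  expect_identical(unname(rej[c("A01", "A02", "A03")]),
                   rep("model_organism", 3))
  expect_setequal(out$kept$accession, c("A05", "A06"))
})

test_that("class flags are rejected ahead of hybrid status", {
  pol <- filter_policy()
  recs <- make_records("A1", "Gen spa x Gen spb", strrep("A", 300),
                       class_flag = "microsatellite")
  out <- filter_records(recs, pol)
  expect_identical(out$rejected$reason, "class")
})

test_that("filtering is idempotent and partitions the input", {
  w <- dense_world(8)
  pol <- filter_policy(model_threshold = 50)
  out <- filter_records(w$records, pol)
  expect_identical(nrow(out$kept) + nrow(out$rejected), nrow(w$records))
  expect_length(intersect(out$kept$accession, out$rejected$accession), 0L)
  again <- filter_records(out$kept, pol)
  expect_identical(again$kept, out$kept)
  expect_identical(nrow(again$rejected), 0L)
})

test_that("names standardize through aliases; ambiguity drops records", {
  recs <- make_records(c("A1", "A2", "A3"),
                       c("Chelidra serpentina", "Chelydra serpentina",
                         "Ambi guous"),
                       rep(strrep("ACGT", 50), 3))
  aliases <- data.frame(
    variant = c("Chelidra serpentina", "Ambi guous", "Ambi guous"),
    canonical = c("Chelydra serpentina", "Gen spa", "Gen spb"))
  out <- standardize_names(recs, aliases)
  expect_identical(out$records$species[out$records$accession == "A1"],
                   "Chelydra serpentina")
  expect_identical(out$records$species[out$records$accession == "A2"],
                   "Chelydra serpentina")
  expect_identical(out$dropped$accession, "A3")
  expect_identical(out$dropped$reason, "ambiguous")
})

test_that("alias chains resolve and cycles raise", {
  recs <- make_records("A1", "Name one", strrep("ACGT", 50))
  chain <- data.frame(variant = c("Name one", "Name two"),
                      canonical = c("Name two", "Name three"))
  out <- standardize_names(recs, chain)
  expect_identical(out$records$species, "Name three")
  cyc <- data.frame(variant = c("Name one", "Name two"),
                    canonical = c("Name two", "Name one"))
  expect_error(standardize_names(recs, cyc), "cycle")
})

test_that("clade selection walks to the largest clade under the cutoff", {
  # turtles analogue: species-level draw lands in a small clade whose
  # ancestor exceeds the cutoff
  tax <- data.frame(
    clade = c("Root", "Sauropsida", "Testudines", "Aves"),
    parent = c(NA, "Root", "Sauropsida", "Sauropsida"),
    described_species = c(12000, 11800, 400, 11000))
  class(tax) <- c("taxonomy_table", "data.frame")
  sp <- data.frame(
    species = c(sprintf("Turtle sp%03d", 1:310), sprintf("Bird sp%05d", 1:600)),
    clade = c(rep("Testudines", 310), rep("Aves", 600)))
  sampled <- sp$species
  sel <- select_clades(tax, sp, sampled, n_clades = 1, max_sampled = 500,
                       seed = 1)
  # whichever species is drawn, Sauropsida (910 sampled) is over the cutoff:
  # a turtle yields Testudines (310 < 500), a bird yields the species itself
  expect_true(sel %in% c("Testudines", sp$species[311:910]))
  # over 50 draws a turtle is certain to come up: Testudines is selected as
  # a whole, and no individual turtle species ever is
  sel50 <- select_clades(tax, sp, sampled, n_clades = 50, max_sampled = 500,
                         seed = 4)
  expect_true("Testudines" %in% sel50)
  expect_false(any(sp$species[1:310] %in% sel50))
  expect_true(all(setdiff(sel50, "Testudines") %in% sp$species[311:910]))
})

test_that("when every clade exceeds the cutoff, species are selected", {
  tax <- data.frame(clade = c("Root", "Big"),
                    parent = c(NA, "Root"),
                    described_species = c(600, 600))
  class(tax) <- c("taxonomy_table", "data.frame")
  sp <- data.frame(species = sprintf("Gen sp%03d", 1:550),
                   clade = "Big")
  sel <- select_clades(tax, sp, sp$species, n_clades = 3, max_sampled = 500,
                       seed = 2)
  expect_length(sel, 3L)
  expect_true(all(sel %in% sp$species))
})

test_that("selection equals a brute-force walk for every draw", {
  # toy 3-level taxonomy; enumerate the expected pick for each species
  tax <- data.frame(
    clade = c("Root", "Left", "Right", "L1", "L2", "R1"),
    parent = c(NA, "Root", "Root", "Left", "Left", "Right"),
    described_species = c(30, 18, 12, 10, 8, 12))
  class(tax) <- c("taxonomy_table", "data.frame")
  sp <- data.frame(
    species = sprintf("Gen sp%02d", 1:14),
    clade = c(rep("L1", 5), rep("L2", 4), rep("R1", 5)))
  sampled <- sp$species
  max_s <- 10
  # brute force: sampled counts L1=5, L2=4, Left=9, R1=5, Right=5, Root=14
  expected_pick <- function(species) {
    cl <- sp$clade[sp$species == species]
    if (cl %in% c("L1", "L2")) "Left" else "Right"
  }
  for (seed in 1:5) {
    sel <- select_clades(tax, sp, sampled, n_clades = 2,
                         max_sampled = max_s, seed = seed)
    expect_setequal(as.character(sel), c("Left", "Right"))
    expect_true(all(vapply(as.character(sel), function(s)
      s %in% c("Left", "Right"), TRUE)))
  }
  # selected clades are disjoint: Left and Right never share species
  sel <- suppressWarnings(
    select_clades(tax, sp, sampled, n_clades = 5, max_sampled = max_s,
                  seed = 3))
  expect_lte(length(sel), 2L)
})

test_that("unattainable clade counts warn and return fewer", {
  tax <- toy_taxonomy
  class(tax) <- c("taxonomy_table", "data.frame")
  sp <- data.frame(species = c("Gen spa", "Gen spb"),
                   clade = c("CladeA", "CladeB"))
  # max_sampled = 1 forces species-level picks: two attainable, three short
  expect_warning(
    sel <- select_clades(tax, sp, sp$species, n_clades = 5,
                         max_sampled = 1, seed = 1),
    "non-overlapping")
  expect_identical(attr(sel, "shortfall"), 3L)
  expect_setequal(as.character(sel), sp$species)
})
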