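# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  Keeps user-visible determinism
# contracts ("same seed -> same output") without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Stable 31-bit hash of a character key mixed with a base seed; used to fan a
# single run seed out to per-(clade, year) slot seeds so partial reruns are
# reproducible.
slot_seed <- function(seed, ...) {
  key <- paste(..., sep = "\r")
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(key)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Split gapped/ungapped sequence strings into per-character matrices and back.
seq_to_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

chars_to_seq <- function(x) paste(x, collapse = "")

is_nucleotide <- function(ch) ch %in% c("A", "C", "G", "T")
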