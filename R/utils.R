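# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed and a label path.
# All randomness in the package flows from one master seed through named
# substreams so that e.g. the negative shuffle at distance d is independent
# of the train/validation sampling at the same distance. Kept below 2^31
# because R seeds are 32-bit integers.
substream_seed <- function(master, ...) {
  labels <- paste(c(master, ...), collapse = "/")
  bytes <- utf8ToInt(labels)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647L
  as.integer((h + as.numeric(master)) %% 2147483647L)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so package functions never disturb user randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Key identifying a window row in a feature matrix.
window_key <- function(chrom, start) paste0(chrom, ":", start)

# Trailing integer of a chromosome name ("chr12" -> 12); NA when absent.
chrom_number <- function(chrom) {
  m <- regmatches(chrom, regexpr("[0-9]+$", chrom))
  out <- rep(NA_integer_, length(chrom))
  out[lengths(regmatches(chrom, gregexpr("[0-9]+$", chrom))) > 0] <-
    suppressWarnings(as.integer(m))
  out
}

is_chrx <- function(chrom) grepl("(chr)?X$", chrom, ignore.case = FALSE)

assert_scalar_count <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != floor(x) ||
      x < if (allow_zero) 0 else 1) {
    abort(sprintf("`%s` must be a single %s integer, got %s",
                  name, if (allow_zero) "non-negative" else "positive",
                  deparse(substitute(x))))
  }
  invisible(x)
}
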