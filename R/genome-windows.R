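#' Describe a genome as an ordered set of chromosomes with a window grid
#'
#' The layout fixes the window resolution `r`: every analysis in the package
#' operates on non-overlapping windows of exactly `r` bases laid left to
#' right from base 0 of each chromosome.
#'
#' @param chrom_names Character vector of unique chromosome names, in order.
#' @param chrom_lengths Numeric vector of chromosome lengths in bases.
#' @param window_size Window resolution `r` in bases (> 0).
#' @return An object of class `genome_layout`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(10000, 10500), window_size = 1000)
#' @export
genome_layout <- function(chrom_names, chrom_lengths, window_size = 1000L) {
  chrom_names <- as.character(chrom_names)
  if (anyDuplicated(chrom_names)) abort("chromosome names must be unique")
  if (length(chrom_names) != length(chrom_lengths)) {
    abort("chrom_names and chrom_lengths must have equal length")
  }
  if (any(chrom_lengths <= 0)) abort("all chromosome lengths must be > 0")
  if (length(window_size) != 1 || window_size <= 0) {
    abort("window_size must be a single positive number")
  }
  structure(
    list(chrom_names = chrom_names,
         chrom_lengths = setNames(as.numeric(chrom_lengths), chrom_names),
         window_size = as.numeric(window_size)),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome layout: %d chromosomes, %.0f bases, r = %.0f\n",
              length(x$chrom_names), sum(x$chrom_lengths), x$window_size))
  invisible(x)
}

#' Bin a genome into non-overlapping fixed-size windows
#'
#' Each chromosome is tiled with `floor(length / r)` windows starting at
#' 0, r, 2r, ...; a trailing partial window (fewer than `r` bases) is
#' dropped, so every window spans exactly `r` bases. A chromosome shorter
#' than `r` contributes no windows (with a warning).
#'
#' @param layout A [genome_layout()].
#' @return A tibble with one row per window: `chrom`, `start` (0-based),
#'   `end`, and `index` (0-based ordinal within its chromosome). Carries the
#'   resolution in attribute `r`.
#' @examples
#' bin_genome(genome_layout("chr1", 10500, 1000))
#' @export
bin_genome <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  r <- layout$window_size
  n_win <- floor(layout$chrom_lengths / r)
  if (any(n_win == 0)) {
    warn(sprintf("chromosome(s) shorter than r yield no windows: %s",
                 paste(names(n_win)[n_win == 0], collapse = ", ")))
  }
  out <- tibble::tibble(
    chrom = rep(layout$chrom_names, n_win),
    index = unlist(lapply(n_win, function(k) seq_len(k) - 1), use.names = FALSE)
  )
  out$start <- out$index * r
  out$end <- out$start + r
  out <- out[c("chrom", "start", "end", "index")]
  attr(out, "r") <- r
  attr(out, "layout") <- layout
  out
}

# Window starts (on the r-grid) overlapped by >= 1 bp of each interval,
# optionally clipped to windows that exist on the chromosome. Windows form a
# regular grid so overlap reduces to integer division: interval [s, e)
# touches windows floor(s/r) .. floor((e-1)/r).
overlapping_window_starts <- function(intervals, r) {
  first <- floor(intervals$start / r)
  last <- floor((intervals$end - 1) / r)
  n <- last - first + 1
  tibble::tibble(
    chrom = rep(intervals$chrom, n),
    start = unlist(Map(function(f, l) seq(f, l), first, last),
                   use.names = FALSE) * r
  )
}

#' Build a binary feature matrix for a window set
#'
#' One column per peak set (value 1 iff the window overlaps any interval of
#' that assay by at least 1 bp) followed, epigenome-major and state-minor, by
#' one column per (epigenome, chromatin state): 1 iff the window overlaps at
#' least 1 bp annotated with that state in that epigenome. A window may carry
#' several states of one epigenome when the annotation changes within it.
#' Intervals on chromosomes absent from `windows` are ignored (a message
#' reports how many).
#'
#' @param windows Window tibble from [bin_genome()].
#' @param peak_sets Named list of interval tibbles (`chrom`, `start`, `end`);
#'   names become feature labels.
#' @param state_sets Named list of state segmentations (`chrom`, `start`,
#'   `end`, `label` = state name), one per epigenome.
#' @param state_alphabet Character vector of allowed state names; a state
#'   label outside it is an error.
#' @return An integer matrix, windows x features, with row names
#'   `"chrom:start"`, column names as feature labels, and a `source_kind`
#'   attribute (`"peak"` or `"state-onehot"` per column).
#' @export
featurize <- function(windows, peak_sets = list(), state_sets = list(),
                      state_alphabet = character()) {
  r <- attr(windows, "r")
  stopifnot(!is.null(r))
  keys <- window_key(windows$chrom, windows$start)
  labels <- feature_labels(names(peak_sets), names(state_sets), state_alphabet)
  mat <- matrix(0L, nrow = length(keys), ncol = length(labels),
                dimnames = list(keys, labels))
  known <- unique(windows$chrom)
  n_skipped <- 0

  set_col <- function(col, intervals) {
    keep <- intervals$chrom %in% known
    n_skipped <<- n_skipped + sum(!keep)
    if (!any(keep)) return()
    hits <- overlapping_window_starts(intervals[keep, ], r)
    idx <- match(window_key(hits$chrom, hits$start), keys)
    idx <- idx[!is.na(idx)]  # interval tails past the last full window
    mat[idx, col] <<- 1L
  }

  for (nm in names(peak_sets)) set_col(nm, peak_sets[[nm]])
  for (ep in names(state_sets)) {
    seg <- state_sets[[ep]]
    bad <- setdiff(unique(seg$label), state_alphabet)
    if (length(bad)) {
      abort(sprintf("epigenome %s contains state label(s) not in the alphabet: %s",
                    ep, paste(bad, collapse = ", ")))
    }
    for (st in intersect(state_alphabet, unique(seg$label))) {
      set_col(paste(ep, st, sep = "."), seg[seg$label == st, ])
    }
  }
  if (n_skipped > 0) {
    inform(sprintf("featurize: ignored %d interval(s) on chromosomes absent from the window set",
                   n_skipped))
  }
  attr(mat, "source_kind") <- c(
    rep("peak", length(peak_sets)),
    rep("state-onehot", length(state_sets) * length(state_alphabet))
  )
  attr(mat, "r") <- r
  mat
}

#' Feature column labels for a peak + one-hot-state design
#'
#' Deterministic column order: peak sets in input order, then epigenomes in
#' input order with the state alphabet nested within each (epigenome-major,
#' state-minor). The total count is `P + S * E` for `P` peak sets, `S`
#' states and `E` epigenomes.
#'
#' @param peak_names Character vector of assay names.
#' @param epigenome_names Character vector of epigenome identifiers.
#' @param state_alphabet Character vector of state names.
#' @return Character vector of feature labels.
#' @examples
#' length(feature_labels(paste0("p", 1:3), c("E1", "E2"), c("A", "B")))  # 7
#' @export
feature_labels <- function(peak_names, epigenome_names, state_alphabet) {
  c(as.character(peak_names),
    as.vector(t(outer(as.character(epigenome_names), as.character(state_alphabet),
                      paste, sep = "."))))
}

#' Remove window pairs overlapping assembly gaps
#'
#' A pair is excluded when either of its windows overlaps any gap interval by
#' at least 1 bp; surviving rows keep their order. Used for all biological
#' analyses (features do not map well into gaps) but not for reporting
#' predictive performance.
#'
#' @param pairs A pair or score table with `chrom`, `start1`, `start2`.
#' @param gaps Interval tibble (`chrom`, `start`, `end`) of assembly gaps.
#' @param r Window resolution; defaults to the table's `r` attribute.
#' @return The same type of table with gap-overlapping pairs removed.
#' @export
filter_gap_pairs <- function(pairs, gaps, r = attr(pairs, "r")) {
  if (is.null(r)) abort("window resolution r is needed (attribute or argument)")
  if (nrow(gaps) == 0 || nrow(pairs) == 0) return(pairs)
  gw <- overlapping_window_starts(gaps, r)
  hit <- unique(window_key(gw$chrom, gw$start))
  bad <- window_key(pairs$chrom, pairs$start1) %in% hit |
    window_key(pairs$chrom, pairs$start2) %in% hit
  out <- pairs[!bad, ]
  for (a in c("kind", "r", "distance", "seed")) {
    if (!is.null(attr(pairs, a))) attr(out, a) <- attr(pairs, a)
  }
  class(out) <- class(pairs)
  out
}
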