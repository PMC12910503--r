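#' Enumerate all true-distance (positive) window pairs
#'
#' A positive pair at distance `d` is two windows on the same chromosome
#' whose first bases are exactly `d` apart. With `W` windows on a chromosome
#' and `d = k * r` there are `max(0, W - k)` such pairs.
#'
#' @param windows Window tibble from [bin_genome()].
#' @param d Pairwise distance in bases; must be a positive multiple of `r`.
#' @return A pair tibble: `chrom`, `start1` (upstream), `start2`
#'   (downstream), `distance`, `label = "pos"`; attribute `r` retained.
#' @examples
#' w <- bin_genome(genome_layout("chr1", 10000, 1000))
#' nrow(enumerate_positive_pairs(w, 3000))  # 7
#' @export
enumerate_positive_pairs <- function(windows, d) {
  r <- attr(windows, "r")
  k <- d / r
  if (d <= 0 || k != floor(k)) {
    abort(sprintf("d = %s is not a positive multiple of r = %s", d, r))
  }
  per_chrom <- dplyr::summarise(dplyr::group_by(windows, .data$chrom),
                                W = dplyr::n(), .groups = "drop")
  n_pairs <- pmax(0, per_chrom$W - k)
  out <- tibble::tibble(
    chrom = rep(per_chrom$chrom, n_pairs),
    start1 = unlist(lapply(n_pairs, function(n) (seq_len(n) - 1)),
                    use.names = FALSE) * r
  )
  out$start2 <- out$start1 + d
  out$distance <- d
  out$label <- "pos"
  attr(out, "r") <- r
  out
}

#' Shuffle positive pairs into distance-mismatched negatives
#'
#' Within each chromosome the downstream partners of the positive pairs are
#' re-assigned by a uniform random permutation; upstream windows are left in
#' place. The resulting pairs are usually no longer `d` bases apart but are
#' built from exactly the same windows, per chromosome and per role, so a
#' classifier separating positives from negatives must exploit joint
#' (pairwise) structure rather than marginal window characteristics. Fixed
#' points (a negative that coincides with its positive) are allowed; their
#' count is recorded in attribute `n_true_distance`.
#'
#' @param positives Pair tibble of positive pairs (label `"pos"`).
#' @param seed Integer seed; the shuffle is deterministic given it.
#' @return Pair tibble with `label = "neg"`; `distance` holds the nominal
#'   distance of the positives it was built from.
#' @export
shuffle_negatives <- function(positives, seed) {
  stopifnot(all(positives$label == "pos"))
  out <- with_seed(substream_seed(seed, "shuffle"), {
    dplyr::mutate(dplyr::group_by(positives, .data$chrom),
                  start2 = .data$start2[sample.int(dplyr::n())]) |>
      dplyr::ungroup()
  })
  n_fixed <- sum(out$start2 == positives$start2)
  out$label <- "neg"
  attr(out, "r") <- attr(positives, "r")
  attr(out, "n_true_distance") <- n_fixed
  if (n_fixed > 0) {
    inform(sprintf("shuffle_negatives: %d negative(s) coincide with a true-distance pair",
                   n_fixed))
  }
  out
}

#' Define a train/validation/test chromosome split
#'
#' To score pairs on chromosomes of one parity (plus chrX), classifiers are
#' trained on autosomes of the *other* parity: a few chromosomes of the
#' training parity are held out for validation, the rest form the training
#' set, and test pairs are drawn from the target-parity autosomes. chrX is
#' never used for training, validation or testing (it is scored only).
#'
#' @param layout A [genome_layout()].
#' @param target_parity `"odd"` or `"even"`: the parity of the chromosomes
#'   the trained classifiers will score.
#' @param seed Integer seed for the validation-chromosome draw.
#' @param n_validation_chroms Number of validation chromosomes (default 3).
#' @param n_validation,n_test,n_train_sample Pair-sampling sizes attached to
#'   the split (defaults 5000, 5000, 50000).
#' @return A `split_spec` list with `train_chroms`, `validation_chroms`,
#'   `test_chroms` and the sampling sizes.
#' @export
make_split <- function(layout, target_parity = c("odd", "even"), seed = 1,
                       n_validation_chroms = 3, n_validation = 5000,
                       n_test = 5000, n_train_sample = 50000) {
  target_parity <- match.arg(target_parity)
  chroms <- layout$chrom_names
  num <- chrom_number(chroms)
  xmask <- is_chrx(chroms)
  bad <- is.na(num) & !xmask
  if (any(bad)) {
    abort(sprintf("cannot determine parity for chromosome(s): %s",
                  paste(chroms[bad], collapse = ", ")))
  }
  autos <- chroms[!xmask]
  parity <- ifelse(chrom_number(autos) %% 2 == 1, "odd", "even")
  target_chroms <- autos[parity == target_parity]
  source_chroms <- autos[parity != target_parity]
  if (length(source_chroms) < n_validation_chroms + 1) {
    abort(sprintf(
      "need at least %d %s autosomes (%d validation + 1 training), found %d",
      n_validation_chroms + 1, setdiff(c("odd", "even"), target_parity),
      n_validation_chroms, length(source_chroms)))
  }
  val <- with_seed(substream_seed(seed, "split", target_parity),
                   sample(source_chroms, n_validation_chroms))
  structure(
    list(target_parity = target_parity,
         train_chroms = setdiff(source_chroms, val),
         validation_chroms = sort(val),
         test_chroms = target_chroms,
         n_validation = n_validation, n_test = n_test,
         n_train_sample = n_train_sample, seed = seed),
    class = "split_spec"
  )
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("split (target %s): train {%s} | validation {%s} | test {%s}\n",
              x$target_parity,
              paste(x$train_chroms, collapse = ", "),
              paste(x$validation_chroms, collapse = ", "),
              paste(x$test_chroms, collapse = ", ")))
  invisible(x)
}

#' Sample pairs uniformly without replacement
#'
#' @param pairs A pair tibble.
#' @param n Number of pairs to keep; if `n >= nrow(pairs)` all are returned.
#' @param seed Integer seed.
#' @return Pair tibble of `min(n, nrow(pairs))` rows.
#' @export
sample_pairs <- function(pairs, n, seed) {
  assert_scalar_count(n, "n", allow_zero = TRUE)
  if (n >= nrow(pairs)) return(pairs)
  idx <- with_seed(substream_seed(seed, "sample", n),
                   sample.int(nrow(pairs), n))
  out <- pairs[idx, ]
  attr(out, "r") <- attr(pairs, "r")
  out
}
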