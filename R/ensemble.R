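# Final score: for a pair at distance d, average the predictions of the
# 5-member ensembles at distances d - r, d and d + r, each member applied to
# both input orders (30 values at interior distances; 20 at the distance
# range's edges, where one adjacent ensemble does not exist). The averaged
# multiset is invariant under swapping the two windows, so the score is
# exactly symmetric even though a single forward pass is not.

ensemble_distances <- function(ensembles) {
  sort(vapply(ensembles, `[[`, numeric(1), "distance"))
}

find_ensemble <- function(ensembles, d) {
  dd <- vapply(ensembles, `[[`, numeric(1), "distance")
  i <- which(dd == d)
  if (length(i) != 1) abort(sprintf("no ensemble available for distance %.0f", d))
  ensembles[[i]]
}

# Matrix of member predictions for explicit feature-row matrices.
ensemble_predictions <- function(ensemble, Xu, Xd) {
  vals <- lapply(ensemble$members, function(m) {
    cbind(siamese_forward(m$params, Xu, Xd),
          siamese_forward(m$params, Xd, Xu))
  })
  do.call(cbind, vals)  # n_pairs x (2 * k)
}

#' Score one window pair with the adjacent-distance ensemble rule
#'
#' @param ensembles List of `distance_ensemble` objects covering the needed
#'   distances.
#' @param fvec_up,fvec_down Binary feature vectors of the two windows.
#' @param d Pairwise distance of the pair in bases.
#' @param r Window resolution in bases.
#' @param d_min,d_max Smallest/largest distance of the score's range;
#'   default to the range spanned by `ensembles`.
#' @return A single score in \[0, 1\], with attribute `n_values` giving the
#'   number of averaged predictions (30 interior, 20 at the edges).
#' @export
score_pair <- function(ensembles, fvec_up, fvec_down, d, r,
                       d_min = min(ensemble_distances(ensembles)),
                       d_max = max(ensemble_distances(ensembles))) {
  if (length(fvec_up) != length(fvec_down)) abort("feature vectors differ in length")
  needed <- intersect(c(d - r, d, d + r), seq(d_min, d_max, by = r))
  if (!d %in% needed) abort(sprintf("d = %.0f outside [d_min, d_max]", d))
  Xu <- matrix(as.numeric(fvec_up), nrow = 1)
  Xd <- matrix(as.numeric(fvec_down), nrow = 1)
  vals <- unlist(lapply(needed, function(dd) {
    ensemble_predictions(find_ensemble(ensembles, dd), Xu, Xd)
  }))
  structure(mean(vals), n_values = length(vals))
}

#' Score all true-distance pairs of held-out chromosomes
#'
#' Applies the adjacent-distance ensemble rule to every positive-structure
#' pair at each requested distance on the target chromosomes. Scoring is
#' refused if any involved ensemble saw a target chromosome during training
#' (the held-out guarantee).
#'
#' @param ensembles List of `distance_ensemble` objects, one per distance
#'   from `d_min` to `d_max` on the `r` grid.
#' @param windows Window tibble from [bin_genome()].
#' @param features Feature matrix covering the windows.
#' @param target_chroms Chromosomes to score.
#' @param distances Distances to score (default: every ensemble distance).
#' @return A score table (`epair_score_table`): `chrom`, `start1`, `start2`,
#'   `distance`, `score`, with `kind = "learned"`.
#' @export
score_genome <- function(ensembles, windows, features, target_chroms,
                         distances = ensemble_distances(ensembles)) {
  r <- attr(windows, "r")
  trained_on <- unique(unlist(lapply(ensembles, `[[`, "train_chroms")))
  leak <- intersect(target_chroms, trained_on)
  if (length(leak)) {
    abort(sprintf("target chromosome(s) seen in training: %s",
                  paste(leak, collapse = ", ")))
  }
  d_min <- min(ensemble_distances(ensembles))
  d_max <- max(ensemble_distances(ensembles))
  sub <- windows[windows$chrom %in% target_chroms, ]
  attr(sub, "r") <- r
  out <- purrr::map_dfr(distances, function(d) {
    pairs <- enumerate_positive_pairs(sub, d)
    if (nrow(pairs) == 0) return(NULL)
    dat <- pairs_to_matrices(pairs, features)
    needed <- intersect(c(d - r, d, d + r), seq(d_min, d_max, by = r))
    preds <- do.call(cbind, lapply(needed, function(dd) {
      ensemble_predictions(find_ensemble(ensembles, dd), dat$Xu, dat$Xd)
    }))
    tibble::tibble(chrom = pairs$chrom, start1 = pairs$start1,
                   start2 = pairs$start2, distance = d,
                   score = rowMeans(preds))
  })
  new_score_table(out, kind = "learned", r = r)
}

#' Score the rows of a pair table with the adjacent-distance rule
#'
#' Each row is scored with the ensembles for its *nominal* distance (the
#' `distance` column) and its neighbours: shuffled negatives carry the
#' nominal distance of the positives they were built from, so positives and
#' negatives of one classification task are scored by the same machinery.
#'
#' @inheritParams score_genome
#' @param pairs Pair or score table.
#' @return Numeric vector of scores, one per row of `pairs`.
#' @export
score_pair_table <- function(ensembles, pairs, features) {
  d_min <- min(ensemble_distances(ensembles))
  d_max <- max(ensemble_distances(ensembles))
  r <- attr(pairs, "r") %||% min(diff(sort(unique(ensemble_distances(ensembles)))))
  out <- numeric(nrow(pairs))
  for (d in unique(pairs$distance)) {
    sel <- which(pairs$distance == d)
    dat <- pairs_to_matrices(pairs[sel, ], features)
    needed <- intersect(c(d - r, d, d + r), seq(d_min, d_max, by = r))
    preds <- do.call(cbind, lapply(needed, function(dd) {
      ensemble_predictions(find_ensemble(ensembles, dd), dat$Xu, dat$Xd)
    }))
    out[sel] <- rowMeans(preds)
  }
  out
}

#' Replace scores by their empirical percentiles
#'
#' Each value becomes its mean-rank percentile `(rank - 0.5) / n`, either
#' within the whole table (`global`) or within each pairwise-distance
#' stratum (`per_distance`). Ties receive the mean rank, so a constant
#' column maps to 0.5 everywhere. Distance-stratified percentiles remove the
#' distance confound before any downstream enrichment analysis; the global
#' mode reproduces the overall score distribution on a common scale.
#'
#' @param table A score table.
#' @param mode `"per_distance"` (default) or `"global"`.
#' @return A score table of kind `"percentile"` with values in (0, 1).
#' @export
percentile_transform <- function(table, mode = c("per_distance", "global")) {
  mode <- match.arg(mode)
  if (nrow(table) == 0) abort("empty score table")
  pct <- function(x) (rank(x, ties.method = "average") - 0.5) / length(x)
  out <- as_tibble(table)
  if (mode == "global") {
    out$score <- pct(out$score)
  } else {
    out <- dplyr::mutate(dplyr::group_by(out, .data$distance),
                         score = pct(.data$score)) |> dplyr::ungroup()
  }
  new_score_table(out, kind = "percentile", r = attr(table, "r"))
}
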