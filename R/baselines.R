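#' Jaccard index of two binary feature vectors
#'
#' Intersection over union of the active features; 0 when both vectors are
#' all-zero. The package's similarity baseline.
#'
#' @param fvec_a,fvec_b Binary vectors of equal length.
#' @return Value in \[0, 1\].
#' @examples
#' jaccard_index(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1/3
#' @export
jaccard_index <- function(fvec_a, fvec_b) {
  if (length(fvec_a) != length(fvec_b)) abort("vectors differ in length")
  inter <- sum(fvec_a & fvec_b)
  union <- sum(fvec_a | fvec_b)
  if (union == 0) 0 else inter / union
}

#' Jaccard scores for a pair table
#'
#' Computes the Jaccard index of the two windows' feature vectors for every
#' pair, returning a score table comparable to the learned one.
#'
#' @param pairs Pair or score table.
#' @param features Feature matrix.
#' @return Score table of kind `"jaccard"`.
#' @export
score_jaccard <- function(pairs, features) {
  dat <- pairs_to_matrices(pairs, features)
  inter <- rowSums(dat$Xu * dat$Xd)
  union <- rowSums((dat$Xu + dat$Xd) > 0)
  out <- tibble::tibble(chrom = pairs$chrom, start1 = pairs$start1,
                        start2 = pairs$start2, distance = pairs$distance,
                        score = ifelse(union == 0, 0, inter / union))
  new_score_table(out, kind = "jaccard", r = attr(pairs, "r"))
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a randomly drawn positive score outranks a randomly
#' drawn negative score, with ties counted one half.
#'
#' @param pos_scores,neg_scores Non-empty numeric score vectors.
#' @return Value in \[0, 1\].
#' @examples
#' auroc(c(0.9, 0.4), c(0.5, 0.1))  # 0.75
#' @export
auroc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores)
  nn <- length(neg_scores)
  if (np == 0 || nn == 0) abort("both score classes must be non-empty")
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

new_distance_curve <- function(tab, metric) {
  out <- as_tibble(tab)
  attr(out, "metric") <- metric
  class(out) <- unique(c("distance_curve", class(out)))
  out
}

#' Evaluate a scorer's AUROC across pairwise distances
#'
#' For each distance and replicate (typically the odd-target and even-target
#' classifier sets, each evaluated on its own held-out test pairs), computes
#' the AUROC of the scorer on positive versus shuffled-negative pairs, and
#' the mean over replicates.
#'
#' @param replicates A list of replicates, each a list with elements
#'   `scorer` (a function `(pairs) -> numeric` scoring a pair table) and
#'   `test_sets` (a named list, keyed by distance, of lists `pos`/`neg` pair
#'   tibbles). All replicates must cover the same distances.
#' @return A `distance_curve` tibble: `distance`, `replicate`, `auroc`, plus
#'   the per-distance `mean_auroc`.
#' @export
evaluate_by_distance <- function(replicates) {
  dists <- lapply(replicates, function(rep) sort(as.numeric(names(rep$test_sets))))
  if (length(unique(dists)) != 1) {
    abort("all replicates must cover the same distances")
  }
  rows <- purrr::map2_dfr(replicates, seq_along(replicates), function(rep, i) {
    purrr::map_dfr(names(rep$test_sets), function(dn) {
      ts <- rep$test_sets[[dn]]
      sp <- rep$scorer(ts$pos)
      sn <- rep$scorer(ts$neg)
      tibble::tibble(distance = as.numeric(dn), replicate = i,
                     auroc = auroc(sp, sn))
    })
  })
  rows <- dplyr::arrange(rows, .data$distance, .data$replicate)
  means <- dplyr::summarise(dplyr::group_by(rows, .data$distance),
                            mean_auroc = mean(.data$auroc), .groups = "drop")
  new_distance_curve(dplyr::left_join(rows, means, by = "distance"), "auroc")
}

#' Per-distance decision-tree baseline
#'
#' Mirrors the neural training protocol with a single classification tree
#' per distance: the tree is fit on the concatenated
#' (upstream, downstream) feature vector with both orderings included (flip
#' augmentation), its depth tuned on validation AUROC over
#' \{4, 8, 16, 30\} (30 is the implementation's maximum, serving as the
#' unlimited arm), and evaluated identically to the learned score.
#'
#' @param train_pairs,val_pairs,test_pairs Labelled pair tibbles for one
#'   distance.
#' @param features Feature matrix.
#' @param depth_grid Depths tried (default `c(4, 8, 16, 30)`).
#' @return A list: `auroc` (test), `depth` (selected), `fit` (the tree),
#'   `val_aurocs`.
#' @export
decision_tree_baseline <- function(train_pairs, val_pairs, test_pairs,
                                   features, depth_grid = c(4, 8, 16, 30)) {
  cat_matrix <- function(pairs) {
    dat <- pairs_to_matrices(pairs, features)
    X <- rbind(cbind(dat$Xu, dat$Xd), cbind(dat$Xd, dat$Xu))
    colnames(X) <- c(paste0("u", seq_len(ncol(dat$Xu))),
                     paste0("d", seq_len(ncol(dat$Xd))))
    list(X = as.data.frame(X), y = factor(c(dat$y, dat$y), levels = c(0, 1)))
  }
  tr <- cat_matrix(train_pairs)
  va <- cat_matrix(val_pairs)
  fits <- lapply(depth_grid, function(depth) {
    rpart::rpart(y ~ ., data = cbind(tr$X, y = tr$y), method = "class",
                 control = rpart::rpart.control(maxdepth = depth, cp = 1e-4,
                                                xval = 0))
  })
  val_auc <- vapply(fits, function(f) {
    p <- predict(f, va$X)[, "1"]
    auroc(p[va$y == 1], p[va$y == 0])
  }, numeric(1))
  best <- which.max(val_auc)
  te <- cat_matrix(test_pairs)
  # flip-averaged test prediction: the two orderings sit in rows i and n + i
  p <- predict(fits[[best]], te$X)[, "1"]
  n <- length(p) / 2
  pa <- (p[seq_len(n)] + p[n + seq_len(n)]) / 2
  y <- te$y[seq_len(n)]
  list(auroc = auroc(pa[y == 1], pa[y == 0]),
       depth = depth_grid[best], fit = fits[[best]],
       val_aurocs = setNames(val_auc, depth_grid))
}

#' Correlation between score and pairwise distance
#'
#' Pearson and Spearman correlations between the pairwise distance and the
#' score over a seeded random sample of the table, quantifying how much of
#' the score is explained by 1D distance alone.
#'
#' @param table Score table spanning at least two distances.
#' @param n_sample Sample size (default 1e6; capped at the table size).
#' @param seed Integer seed.
#' @return A list with `pcc`, `scc` (either `NA` with attribute
#'   `"degenerate"` when a variance is zero) and `n`.
#' @export
distance_correlation <- function(table, n_sample = 1e6, seed = 1) {
  if (dplyr::n_distinct(table$distance) < 2) {
    abort("table must span at least two distances")
  }
  n <- min(n_sample, nrow(table))
  idx <- with_seed(substream_seed(seed, "distcor"),
                   sample.int(nrow(table), n))
  d <- table$distance[idx]
  s <- table$score[idx]
  if (stats::sd(s) == 0 || stats::sd(d) == 0) {
    out <- list(pcc = NA_real_, scc = NA_real_, n = n)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  list(pcc = cor(d, s, method = "pearson"),
       scc = cor(d, s, method = "spearman"), n = n)
}

#' Per-distance correlation between two scorings of the same pairs
#'
#' Typically the learned score against the Jaccard index: a moderate mean
#' correlation indicates the learned score captures information beyond
#' feature similarity.
#'
#' @param score_table,other_table Score tables with identical pair coverage.
#' @return A `distance_curve` tibble (`distance`, `pcc`) with attribute
#'   `mean_pcc`.
#' @export
score_similarity_correlation <- function(score_table, other_table) {
  a <- dplyr::arrange(as_tibble(score_table), .data$chrom, .data$distance,
                      .data$start1)
  b <- dplyr::arrange(as_tibble(other_table), .data$chrom, .data$distance,
                      .data$start1)
  if (nrow(a) != nrow(b) ||
      !all(a$chrom == b$chrom & a$start1 == b$start1 & a$start2 == b$start2)) {
    abort("tables must cover the same pairs")
  }
  joined <- tibble::tibble(distance = a$distance, s1 = a$score, s2 = b$score)
  per_d <- dplyr::summarise(
    dplyr::group_by(joined, .data$distance),
    pcc = if (stats::sd(.data$s1) == 0 || stats::sd(.data$s2) == 0)
      NA_real_ else cor(.data$s1, .data$s2),
    .groups = "drop")
  out <- new_distance_curve(per_d, "pcc")
  attr(out, "mean_pcc") <- mean(per_d$pcc, na.rm = TRUE)
  out
}
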