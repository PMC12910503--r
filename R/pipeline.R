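# High-level orchestration: per-distance training data, hyperparameter
# search, final ensembles and held-out evaluation, wired together the way
# the scoring protocol prescribes. Each step remains callable on its own.

#' Assemble training and validation pairs for one distance
#'
#' Positives are enumerated on the split's training (resp. validation)
#' chromosomes, negatives are within-chromosome shuffles of them, and both
#' sets are sampled down to the split's sizes. Validation pairs are pooled
#' across the validation chromosomes before sampling.
#'
#' @param windows Window tibble from [bin_genome()].
#' @param split A [make_split()] spec.
#' @param d Pairwise distance.
#' @param seed Master seed.
#' @return List with labelled `train` and `validation` pair tibbles.
#' @export
prepare_distance_data <- function(windows, split, d, seed = 1) {
  r <- attr(windows, "r")
  subset_windows <- function(chroms) {
    w <- windows[windows$chrom %in% chroms, ]
    attr(w, "r") <- r
    w
  }
  build <- function(chroms, n, role) {
    pos <- enumerate_positive_pairs(subset_windows(chroms), d)
    pos <- sample_pairs(pos, n, seed = substream_seed(seed, role, "pos", d))
    neg <- suppressMessages(
      shuffle_negatives(pos, seed = substream_seed(seed, role, "neg", d)))
    out <- dplyr::bind_rows(pos, neg)
    attr(out, "r") <- r
    out
  }
  list(train = build(split$train_chroms, split$n_train_sample, "train"),
       validation = build(split$validation_chroms, split$n_validation, "val"))
}

#' Train per-distance classifier ensembles for a chromosome split
#'
#' For every distance: runs the hyperparameter random search on that
#' distance's training/validation pairs, then trains the final ensemble
#' with the selected combination.
#'
#' @param windows,features Window tibble and feature matrix.
#' @param split A [make_split()] spec.
#' @param distances Distances to train (bases, multiples of `r`).
#' @param n_trials Random-search trials per distance (default 10).
#' @param k Ensemble size per distance (default 5).
#' @param epochs,patience Training schedule per classifier.
#' @param seed Master seed.
#' @return Named list (by distance) of `distance_ensemble` objects.
#' @export
train_pair_classifiers <- function(windows, features, split, distances,
                                   n_trials = 10, k = 5, epochs = 120,
                                   patience = 5, seed = 1) {
  ensembles <- lapply(distances, function(d) {
    dat <- prepare_distance_data(windows, split, d, seed = seed)
    search <- random_search(dat$train, dat$validation, features,
                            n_trials = n_trials,
                            seed = substream_seed(seed, "search", d),
                            epochs = epochs, patience = patience)
    train_final_ensemble(search$best_hp, dat$train, features, k = k,
                         n_per_model = split$n_train_sample,
                         seed = substream_seed(seed, "ensemble", d),
                         epochs = epochs, patience = patience,
                         validation = dat$validation)
  })
  names(ensembles) <- as.character(distances)
  ensembles
}

#' Held-out test pairs per distance
#'
#' Positives sampled from the split's test chromosomes, negatives shuffled
#' from the sampled positives. Test pairs are deliberately not gap-filtered:
#' gap filtering applies to biological analyses, not to reporting
#' predictive performance.
#'
#' @inheritParams train_pair_classifiers
#' @return Named list (by distance) of lists with `pos` and `neg` tibbles.
#' @export
make_test_sets <- function(windows, split, distances, seed = 1) {
  r <- attr(windows, "r")
  out <- lapply(distances, function(d) {
    w <- windows[windows$chrom %in% split$test_chroms, ]
    attr(w, "r") <- r
    pos <- enumerate_positive_pairs(w, d)
    pos <- sample_pairs(pos, split$n_test,
                        seed = substream_seed(seed, "test", "pos", d))
    neg <- suppressMessages(
      shuffle_negatives(pos, seed = substream_seed(seed, "test", "neg", d)))
    list(pos = pos, neg = neg)
  })
  names(out) <- as.character(distances)
  out
}

#' Run the complete pipeline on a synthetic world
#'
#' Featurizes the world, builds the chromosome split(s), trains the
#' per-distance ensembles, and evaluates held-out AUROC by distance for the
#' learned score and the Jaccard baseline. The default scale (3 search
#' trials, 2-member ensembles) matches the package's test worlds.
#'
#' @param world A [simulate_world()] world.
#' @param target_parities Chromosome parities to hold out and score
#'   (replicates of the evaluation; default `"odd"`).
#' @param distances Distances to train; default `r, 2r, ..., D`.
#' @param n_trials,k,epochs,patience Training scale.
#' @param n_validation_chroms Validation chromosomes per split (default 1,
#'   suited to small synthetic genomes).
#' @param seed Master seed (default: the world's).
#' @return A list: `windows`, `features`, `splits`, `ensembles` (per
#'   parity), `test_sets`, `curve` (learned AUROC by distance),
#'   `jaccard_curve`.
#' @export
run_fixture_pipeline <- function(world, target_parities = "odd",
                                 distances = NULL, n_trials = 3, k = 2,
                                 epochs = 120, patience = 5,
                                 n_validation_chroms = 1,
                                 seed = world$params$seed) {
  p <- world$params
  if (is.null(distances)) distances <- seq(p$r, p$D, by = p$r)
  windows <- bin_genome(world$layout)
  features <- featurize(windows, world$peaks, world$states,
                        world$state_alphabet)
  splits <- list()
  ensembles <- list()
  test_sets <- list()
  replicates <- list()
  jac_replicates <- list()
  for (parity in target_parities) {
    split <- make_split(world$layout, parity,
                        seed = substream_seed(seed, "split", parity),
                        n_validation_chroms = n_validation_chroms)
    ens <- train_pair_classifiers(windows, features, split, distances,
                                  n_trials = n_trials, k = k, epochs = epochs,
                                  patience = patience,
                                  seed = substream_seed(seed, parity))
    ts <- make_test_sets(windows, split, distances,
                         seed = substream_seed(seed, parity, "test"))
    splits[[parity]] <- split
    ensembles[[parity]] <- ens
    test_sets[[parity]] <- ts
    make_scorer <- function(e) function(pairs) score_pair_table(e, pairs, features)
    replicates[[parity]] <- list(scorer = make_scorer(ens), test_sets = ts)
    jac_replicates[[parity]] <- list(
      scorer = function(pairs) score_jaccard(pairs, features)$score,
      test_sets = ts)
  }
  list(windows = windows, features = features, splits = splits,
       ensembles = ensembles, test_sets = test_sets,
       curve = evaluate_by_distance(replicates),
       jaccard_curve = evaluate_by_distance(jac_replicates))
}
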