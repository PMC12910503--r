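# Shared toy objects for the unit tests. Everything is built in code; the
# larger trained-pipeline objects live in test-acceptance.R only.

toy_layout <- function(n_chroms = 2, n_windows = 20, r = 1000) {
  genome_layout(paste0("chr", seq_len(n_chroms)),
                rep(n_windows * r, n_chroms), r)
}

toy_windows <- function(...) bin_genome(toy_layout(...))

# a window-aligned interval covering windows `from:to` (0-based indices)
win_interval <- function(chrom, from, to, r = 1000, label = NULL) {
  out <- tibble::tibble(chrom = chrom, start = from * r, end = (to + 1) * r)
  if (!is.null(label)) out$label <- label
  out
}

# score table over all positive pairs of a window set, scores supplied
toy_score_table <- function(windows, distances, score_fun, r = 1000) {
  tabs <- lapply(distances, function(d) {
    p <- enumerate_positive_pairs(windows, d)
    tibble::tibble(chrom = p$chrom, start1 = p$start1, start2 = p$start2,
                   distance = d)
  })
  tab <- dplyr::bind_rows(tabs)
  tab$score <- score_fun(tab)
  out <- tab
  attr(out, "kind") <- "learned"
  attr(out, "r") <- r
  class(out) <- c("epair_score_table", class(out))
  out
}

# an ensemble whose members always predict the given constants
constant_model <- function(p, n_features = 5) {
  hp <- siamese_hyperparams(16, 1e-4, 0, 32, 32)
  m <- build_siamese(hp, n_features, seed = 1)
  m$params <- lapply(m$params, function(x) x * 0)
  m$params$b3 <- log(p / (1 - p))
  m
}

constant_ensemble <- function(d, probs, n_features = 5, chroms = "chrZ") {
  structure(list(distance = d,
                 members = lapply(probs, constant_model, n_features = n_features),
                 best_hp = siamese_hyperparams(16, 1e-4, 0, 32, 32),
                 train_chroms = chroms),
            class = "distance_ensemble")
}

random_ensemble <- function(d, k = 2, n_features = 8, seed = 1,
                            chroms = "chrZ") {
  hp <- siamese_hyperparams(16, 1e-4, 0, 32, 32)
  structure(list(distance = d,
                 members = lapply(seq_len(k), function(i) {
                   build_siamese(hp, n_features, seed = seed + i)
                 }),
                 best_hp = hp, train_chroms = chroms),
            class = "distance_ensemble")
}

# brute-force AUROC oracle: all pos x neg comparisons, ties count 1/2
auroc_bruteforce <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}
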