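toy_training_world <- function(n_windows = 40, seed = 3) {
  w <- toy_windows(n_chroms = 2, n_windows = n_windows)
  withr::with_seed(seed, {
    fm <- matrix(as.integer(runif(nrow(w) * 10) < 0.3), nrow(w), 10,
                 dimnames = list(paste0(w$chrom, ":", w$start),
                                 paste0("f", 1:10)))
  })
  pos <- enumerate_positive_pairs(w, 1000)
  neg <- suppressMessages(shuffle_negatives(pos, seed = seed))
  list(windows = w, features = fm, pairs = dplyr::bind_rows(pos, neg))
}

test_that("the hyperparameter space is the 3^5 grid and is enforced", {
  grid <- hyperparam_grid()
  expect_equal(nrow(grid), 243)
  expect_equal(nrow(dplyr::distinct(grid)), 243)
  expect_error(siamese_hyperparams(10, 1e-4, 0, 32, 32), "batch_size")
  expect_error(siamese_hyperparams(16, 1e-3, 0, 32, 32), "learning_rate")
  expect_silent(siamese_hyperparams(64, 1e-8, 0.5, 128, 128))
})

test_that("model building is seed-deterministic and outputs stay in (0, 1)", {
  hp <- siamese_hyperparams(16, 1e-4, 0.25, 32, 64)
  m1 <- build_siamese(hp, 12, seed = 5)
  m2 <- build_siamese(hp, 12, seed = 5)
  expect_identical(m1$params, m2$params)
  m3 <- build_siamese(hp, 12, seed = 6)
  expect_false(identical(m1$params, m3$params))

  zero <- matrix(0, 1, 12)
  p <- epair:::siamese_forward(m1$params, zero, zero)
  expect_true(p > 0 && p < 1)
})

test_that("a raw forward pass is order-sensitive; symmetry comes from flips", {
  hp <- siamese_hyperparams(16, 1e-4, 0, 32, 32)
  m <- build_siamese(hp, 6, seed = 2)
  x1 <- matrix(c(1, 0, 1, 0, 0, 1), 1)
  x2 <- matrix(c(0, 1, 0, 1, 1, 0), 1)
  p12 <- epair:::siamese_forward(m$params, x1, x2)
  p21 <- epair:::siamese_forward(m$params, x2, x1)
  expect_false(isTRUE(all.equal(p12, p21)))
  # flip averaging restores exact symmetry
  expect_equal((p12 + p21) / 2, (p21 + p12) / 2)
})

test_that("backpropagation matches finite-difference gradients", {
  hp <- siamese_hyperparams(16, 1e-4, 0, 32, 32)
  m <- build_siamese(hp, 7, seed = 11)
  withr::with_seed(21, {
    Xu <- matrix(as.numeric(runif(21) < 0.4), 3, 7)
    Xd <- matrix(as.numeric(runif(21) < 0.4), 3, 7)
    y <- c(1, 0, 1)
    # jitter the zero-initialised biases so no pre-activation sits exactly
    # on the ReLU kink, where two-sided differences are ill-defined
    m$params$b1 <- rnorm(length(m$params$b1), sd = 0.05)
    m$params$b2 <- rnorm(length(m$params$b2), sd = 0.05)
  })
  loss <- function(params) {
    p <- epair:::siamese_forward(params, Xu, Xd)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  g <- epair:::siamese_gradient(m$params, Xu, Xd, y, dropout = 0)
  eps <- 1e-6
  for (nm in names(m$params)) {
    pick <- if (length(m$params[[nm]]) > 4) c(1, 3) else 1
    for (i in pick) {
      up <- m$params
      up[[nm]][i] <- up[[nm]][i] + eps
      down <- m$params
      down[[nm]][i] <- down[[nm]][i] - eps
      numeric_grad <- (loss(up) - loss(down)) / (2 * eps)
      expect_equal(as.numeric(g[[nm]][i]), numeric_grad, tolerance = 1e-5)
    }
  }
})

test_that("training doubles the stream with flips and requires both labels", {
  tw <- toy_training_world()
  hp <- siamese_hyperparams(32, 1e-4, 0, 32, 32)
  m <- build_siamese(hp, ncol(tw$features), seed = 1)
  pairs100 <- dplyr::bind_rows(
    dplyr::slice_head(tw$pairs[tw$pairs$label == "pos", ], n = 50),
    dplyr::slice_head(tw$pairs[tw$pairs$label == "neg", ], n = 50))
  fit <- train_siamese(m, pairs100, tw$features, epochs = 1, seed = 2)
  expect_equal(fit$n_train_instances, 200)
  expect_true(fit$trained)
  expect_equal(fit$distance, 1000)

  only_pos <- tw$pairs[tw$pairs$label == "pos", ]
  expect_error(train_siamese(m, only_pos, tw$features, epochs = 1),
               "both pos and neg")
})

test_that("training is deterministic given the seed", {
  tw <- toy_training_world()
  hp <- siamese_hyperparams(16, 1e-4, 0.25, 32, 32)
  m <- build_siamese(hp, ncol(tw$features), seed = 1)
  f1 <- train_siamese(m, tw$pairs, tw$features, epochs = 2, seed = 7)
  f2 <- train_siamese(m, tw$pairs, tw$features, epochs = 2, seed = 7)
  expect_identical(f1$params, f2$params)
  f3 <- train_siamese(m, tw$pairs, tw$features, epochs = 2, seed = 8)
  expect_false(identical(f1$params, f3$params))
})

test_that("training separates a linearly planted pair signal", {
  # positives share feature 1 on both sides; negatives never do
  w <- toy_windows(n_chroms = 1, n_windows = 60)
  fm <- matrix(0L, 60, 4, dimnames = list(paste0("chr1:", w$start),
                                          paste0("f", 1:4)))
  fm[, 1] <- rep(c(1L, 0L), 30)
  withr::with_seed(2, fm[, 2:4] <- as.integer(runif(180) < 0.3))
  pos <- enumerate_positive_pairs(w, 2000)   # both ends share fm[,1] parity
  neg <- pos
  neg$start2 <- pos$start2 + 1000            # opposite parity partner
  neg <- neg[neg$start2 < 60000, ]
  neg$label <- "neg"
  pairs <- dplyr::bind_rows(pos, head(neg, nrow(pos)))
  hp <- siamese_hyperparams(16, 1e-4, 0, 32, 32)
  m <- build_siamese(hp, 4, seed = 3)
  fit <- train_siamese(m, pairs, fm, epochs = 120, seed = 4)
  p <- predict_pairs(fit, pairs, fm, flip_average = TRUE)
  expect_gt(auroc(p[pairs$label == "pos"], p[pairs$label == "neg"]), 0.95)
})

test_that("random search returns the first-best trial over shared data", {
  tw <- toy_training_world()
  train <- tw$pairs
  val <- tw$pairs  # tiny world: reuse; the search contract is what is tested
  rs <- random_search(train, val, tw$features, n_trials = 3, seed = 5,
                      epochs = 2)
  expect_s3_class(rs, "random_search")
  expect_equal(nrow(rs$trials), 3)
  expect_equal(rs$best_auroc, max(rs$trials$val_auroc))
  first_best <- which.max(rs$trials$val_auroc)
  expect_equal(rs$best_hp$batch_size, rs$trials$batch_size[first_best])
  expect_equal(rs$best_hp$learning_rate, rs$trials$learning_rate[first_best])
  # combinations are drawn without replacement
  expect_equal(nrow(dplyr::distinct(rs$trials[1:5])), 3)

  rs1 <- random_search(train, val, tw$features, n_trials = 1, seed = 5,
                       epochs = 2)
  expect_equal(nrow(rs1$trials), 1)
  expect_equal(rs1$best_auroc, rs1$trials$val_auroc[1])
})

test_that("final ensembles have k seed-distinct members and reproduce exactly", {
  tw <- toy_training_world()
  hp <- siamese_hyperparams(32, 1e-4, 0, 32, 32)
  e1 <- train_final_ensemble(hp, tw$pairs, tw$features, k = 2,
                             n_per_model = 50, seed = 9, epochs = 2)
  expect_s3_class(e1, "distance_ensemble")
  expect_length(e1$members, 2)
  expect_false(identical(e1$members[[1]]$params, e1$members[[2]]$params))
  e2 <- train_final_ensemble(hp, tw$pairs, tw$features, k = 2,
                             n_per_model = 50, seed = 9, epochs = 2)
  expect_identical(lapply(e1$members, `[[`, "params"),
                   lapply(e2$members, `[[`, "params"))
  e3 <- train_final_ensemble(hp, tw$pairs, tw$features, k = 1,
                             n_per_model = 50, seed = 9, epochs = 2)
  expect_length(e3$members, 1)
  expect_error(train_final_ensemble(hp, tw$pairs[0, ], tw$features, k = 1),
               "empty")
})
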