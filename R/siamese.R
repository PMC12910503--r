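# Siamese pairwise classifier: two weight-sharing twin sub-networks (one
# hidden layer each, shared parameters) map the upstream and downstream
# feature vectors to hidden representations; a combining sub-network (one
# hidden layer on the ordered concatenation) emits the probability that the
# pair is a true-distance pair. Trained by minibatch Adam on binary
# cross-entropy with flip augmentation. Implemented directly with matrix
# algebra; the backward pass accumulates the twin gradient from both inputs
# into the single shared parameter store.

#' Hyperparameter grids for the pairwise classifier
#'
#' The random search draws from fixed grids: batch size \{16, 32, 64\},
#' learning rate \{1e-8, 1e-6, 1e-4\}, dropout rate \{0, 0.25, 0.5\}, twin
#' hidden width \{32, 64, 128\} and combiner hidden width \{32, 64, 128\} —
#' 243 combinations in total.
#'
#' @return A tibble with one row per combination.
#' @export
hyperparam_grid <- function() {
  tidyr::expand_grid(
    batch_size = c(16L, 32L, 64L),
    learning_rate = c(1e-8, 1e-6, 1e-4),
    dropout_rate = c(0, 0.25, 0.5),
    n_hidden_twin = c(32L, 64L, 128L),
    n_hidden_final = c(32L, 64L, 128L)
  )
}

#' Construct and validate a hyperparameter combination
#'
#' @param batch_size,learning_rate,dropout_rate,n_hidden_twin,n_hidden_final
#'   Values from the grids of [hyperparam_grid()].
#' @return A named list of class `siamese_hp`.
#' @export
siamese_hyperparams <- function(batch_size, learning_rate, dropout_rate,
                                n_hidden_twin, n_hidden_final) {
  hp <- list(batch_size = as.integer(batch_size),
             learning_rate = learning_rate,
             dropout_rate = dropout_rate,
             n_hidden_twin = as.integer(n_hidden_twin),
             n_hidden_final = as.integer(n_hidden_final))
  grid <- hyperparam_grid()
  for (nm in names(hp)) {
    if (!hp[[nm]] %in% grid[[nm]]) {
      abort(sprintf("%s = %s is not in the allowed grid {%s}",
                    nm, format(hp[[nm]]),
                    paste(unique(grid[[nm]]), collapse = ", ")))
    }
  }
  structure(hp, class = "siamese_hp")
}

#' Build an untrained Siamese pairwise classifier
#'
#' Architecture: twin `F -> n_hidden_twin` (ReLU, weights shared between the
#' two inputs); combiner: concatenation of the two twin outputs
#' `2*n_hidden_twin -> n_hidden_final` (ReLU) `-> 1` (sigmoid). Dropout at
#' the configured rate is applied to all hidden activations during training
#' only. Weights are He-initialised from the seed, so two builds with the
#' same seed are identical.
#'
#' @param hp A `siamese_hp` from [siamese_hyperparams()].
#' @param n_features Length `F` of each window's feature vector.
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `siamese_model`.
#' @export
build_siamese <- function(hp, n_features, seed = 1) {
  if (!inherits(hp, "siamese_hp")) {
    hp <- do.call(siamese_hyperparams, as.list(hp)[c(
      "batch_size", "learning_rate", "dropout_rate",
      "n_hidden_twin", "n_hidden_final")])
  }
  assert_scalar_count(n_features, "n_features")
  h1 <- hp$n_hidden_twin
  h2 <- hp$n_hidden_final
  params <- with_seed(substream_seed(seed, "init"), list(
    W1 = matrix(rnorm(n_features * h1, sd = sqrt(2 / n_features)),
                n_features, h1),
    b1 = numeric(h1),
    W2 = matrix(rnorm(2 * h1 * h2, sd = sqrt(2 / (2 * h1))), 2 * h1, h2),
    b2 = numeric(h2),
    W3 = matrix(rnorm(h2, sd = sqrt(2 / h2)), h2, 1),
    b3 = 0
  ))
  structure(
    list(hp = hp, n_features = as.integer(n_features), params = params,
         seed = as.integer(seed), distance = NA_real_, epochs_run = 0L,
         trained = FALSE, train_chroms = character(),
         val_history = numeric()),
    class = "siamese_model"
  )
}

#' @export
print.siamese_model <- function(x, ...) {
  cat(sprintf(
    "siamese model: F = %d, twin %d, combiner %d | lr %.0e, batch %d, dropout %.2f | %s\n",
    x$n_features, x$hp$n_hidden_twin, x$hp$n_hidden_final,
    x$hp$learning_rate, x$hp$batch_size, x$hp$dropout_rate,
    if (x$trained) sprintf("trained %d epoch(s), d = %.0f", x$epochs_run,
                           x$distance) else "untrained"))
  invisible(x)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}
sigmoid <- function(x) 1 / (1 + exp(-x))

add_bias <- function(M, b) M + rep(b, each = nrow(M))

# Forward pass on row-matrix inputs; returns activations when `keep = TRUE`.
siamese_forward <- function(params, Xu, Xd, dropout = 0, keep = FALSE) {
  A1 <- relu(add_bias(Xu %*% params$W1, params$b1))
  B1 <- relu(add_bias(Xd %*% params$W1, params$b1))
  Ma <- Mb <- Mh <- NULL
  if (dropout > 0) {
    Ma <- matrix(runif(length(A1)) >= dropout, nrow(A1)) / (1 - dropout)
    Mb <- matrix(runif(length(B1)) >= dropout, nrow(B1)) / (1 - dropout)
    A1 <- A1 * Ma
    B1 <- B1 * Mb
  }
  C <- cbind(A1, B1)
  Z2 <- add_bias(C %*% params$W2, params$b2)
  H <- relu(Z2)
  if (dropout > 0) {
    Mh <- matrix(runif(length(H)) >= dropout, nrow(H)) / (1 - dropout)
    H <- H * Mh
  }
  p <- sigmoid(drop(H %*% params$W3) + params$b3)
  if (!keep) return(p)
  list(p = p, A1 = A1, B1 = B1, C = C, Z2 = Z2, H = H,
       Ma = Ma, Mb = Mb, Mh = Mh)
}

# One minibatch gradient of mean BCE. The twin weight gradient sums the
# contributions from the upstream and downstream inputs (weight sharing).
siamese_gradient <- function(params, Xu, Xd, y, dropout) {
  fw <- siamese_forward(params, Xu, Xd, dropout = dropout, keep = TRUE)
  n <- length(y)
  do <- matrix((fw$p - y) / n, ncol = 1)
  gW3 <- crossprod(fw$H, do)
  gb3 <- sum(do)
  dH <- tcrossprod(do, params$W3)
  if (!is.null(fw$Mh)) dH <- dH * fw$Mh
  dZ2 <- dH * (fw$Z2 > 0)
  gW2 <- crossprod(fw$C, dZ2)
  gb2 <- colSums(dZ2)
  dC <- tcrossprod(dZ2, params$W2)
  h1 <- ncol(fw$A1)
  dA1 <- dC[, seq_len(h1), drop = FALSE]
  dB1 <- dC[, h1 + seq_len(h1), drop = FALSE]
  if (!is.null(fw$Ma)) dA1 <- dA1 * fw$Ma
  if (!is.null(fw$Mb)) dB1 <- dB1 * fw$Mb
  dZa <- dA1 * (fw$A1 > 0)
  dZb <- dB1 * (fw$B1 > 0)
  gW1 <- crossprod(Xu, dZa) + crossprod(Xd, dZb)
  gb1 <- colSums(dZa) + colSums(dZb)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

# Look up the feature rows of a pair table; rows keyed "chrom:start".
pairs_to_matrices <- function(pairs, features) {
  iu <- match(window_key(pairs$chrom, pairs$start1), rownames(features))
  id <- match(window_key(pairs$chrom, pairs$start2), rownames(features))
  if (anyNA(iu) || anyNA(id)) {
    abort("some pair windows have no row in the feature matrix")
  }
  list(Xu = `dimnames<-`(features[iu, , drop = FALSE] * 1.0, NULL),
       Xd = `dimnames<-`(features[id, , drop = FALSE] * 1.0, NULL),
       y = if ("label" %in% names(pairs)) as.numeric(pairs$label == "pos"))
}

#' Train a Siamese classifier on labelled pairs
#'
#' Every pair enters the training stream twice per epoch — once in the
#' original (upstream, downstream) order and once flipped — doubling the
#' number of training instances; the stream is reshuffled each epoch.
#' Optimised with Adam on binary cross-entropy. When validation pairs are
#' supplied, the validation AUROC (flip-averaged) is tracked each epoch and
#' training stops early once it has not improved by at least 0.001 for
#' `patience` epochs; the best-epoch parameters are restored. Classifiers
#' drawn with learning rates too small to move the loss are abandoned
#' within a few epochs, while learning ones run to their plateau.
#'
#' @param model An untrained (or further-trainable) [build_siamese()] model.
#' @param pairs Pair tibble with both `"pos"` and `"neg"` labels.
#' @param features Feature matrix from [featurize()].
#' @param epochs Maximum training epochs (default 120; the grid's top
#'   learning rate bounds the per-step displacement, so convergence takes
#'   many small steps and early stopping prunes the rest).
#' @param seed Integer seed driving minibatch shuffling and dropout.
#' @param validation Optional pair tibble for early stopping.
#' @param patience Early-stopping patience in epochs (default 3).
#' @return The trained `siamese_model`, with `epochs_run`, `distance`,
#'   `train_chroms` and `val_history` filled in.
#' @export
train_siamese <- function(model, pairs, features, epochs = 120, seed = 1,
                          validation = NULL, patience = 5) {
  stopifnot(inherits(model, "siamese_model"))
  labs <- unique(pairs$label)
  if (!all(c("pos", "neg") %in% labs)) {
    abort("training pairs must contain both pos and neg labels")
  }
  dat <- pairs_to_matrices(pairs, features)
  n <- nrow(pairs)
  hp <- model$hp
  params <- model$params
  adam <- list(m = lapply(params, function(p) p * 0),
               v = lapply(params, function(p) p * 0), t = 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8

  val_dat <- if (!is.null(validation)) pairs_to_matrices(validation, features)
  best <- list(auc = -Inf, params = params, epoch = 0L)
  history <- numeric()

  # flip augmentation: instances 1..n are the original order, n+1..2n the
  # flipped order of the same pairs — the stream is twice the pair count
  Xu2 <- rbind(dat$Xu, dat$Xd)
  Xd2 <- rbind(dat$Xd, dat$Xu)
  y2 <- c(dat$y, dat$y)

  run_epochs <- with_seed(substream_seed(seed, "train"), {
    done <- 0L
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(2 * n)
      starts <- seq(1, 2 * n, by = hp$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + hp$batch_size - 1, 2 * n)]
        g <- siamese_gradient(params, Xu2[idx, , drop = FALSE],
                              Xd2[idx, , drop = FALSE], y2[idx],
                              hp$dropout_rate)
        adam$t <- adam$t + 1
        for (nm in names(params)) {
          adam$m[[nm]] <- beta1 * adam$m[[nm]] + (1 - beta1) * g[[nm]]
          adam$v[[nm]] <- beta2 * adam$v[[nm]] + (1 - beta2) * g[[nm]]^2
          mhat <- adam$m[[nm]] / (1 - beta1^adam$t)
          vhat <- adam$v[[nm]] / (1 - beta2^adam$t)
          params[[nm]] <- params[[nm]] - hp$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      done <- epoch
      if (!is.null(val_dat)) {
        pv <- (siamese_forward(params, val_dat$Xu, val_dat$Xd) +
                 siamese_forward(params, val_dat$Xd, val_dat$Xu)) / 2
        auc <- auroc(pv[val_dat$y == 1], pv[val_dat$y == 0])
        history <- c(history, auc)
        if (auc > best$auc + 1e-3) {
          best <- list(auc = auc, params = params, epoch = epoch)
        } else if (epoch - best$epoch >= patience) {
          break
        }
      }
    }
    done
  })

  if (!is.null(val_dat) && best$epoch > 0) params <- best$params
  model$params <- params
  model$n_train_instances <- 2L * n
  model$epochs_run <- as.integer(run_epochs)
  model$trained <- TRUE
  model$distance <- unique(pairs$distance[pairs$label == "pos"])[1]
  model$train_chroms <- sort(unique(pairs$chrom))
  model$val_history <- history
  model
}

#' Predict pair probabilities with a trained model
#'
#' @param model A `siamese_model`.
#' @param pairs Pair or score table identifying the windows.
#' @param features Feature matrix.
#' @param flip_average Average the predictions over both input orders
#'   (default `FALSE`; ensemble scoring handles flips itself).
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_pairs <- function(model, pairs, features, flip_average = FALSE) {
  dat <- pairs_to_matrices(pairs, features)
  p <- siamese_forward(model$params, dat$Xu, dat$Xd)
  if (flip_average) {
    p <- (p + siamese_forward(model$params, dat$Xd, dat$Xu)) / 2
  }
  p
}

#' @export
predict.siamese_model <- function(object, pairs, features,
                                  flip_average = FALSE, ...) {
  predict_pairs(object, pairs, features, flip_average = flip_average)
}

#' Random hyperparameter search
#'
#' Draws `n_trials` hyperparameter combinations uniformly without
#' replacement from the grids, trains one classifier per combination on the
#' same training pairs, and returns the combination whose validation AUROC
#' (flip-averaged) is maximal; ties are broken by trial order.
#'
#' @param train_pairs,val_pairs Labelled pair tibbles shared by all trials.
#' @param features Feature matrix.
#' @param n_trials Number of combinations to try (default 10).
#' @param seed Master seed (combination draw, per-trial training).
#' @param epochs,patience Passed to [train_siamese()].
#' @return A list of class `random_search`: `best_hp`, `best_auroc`, and a
#'   `trials` tibble (one row per trial, with its validation AUROC).
#' @export
random_search <- function(train_pairs, val_pairs, features, n_trials = 10,
                          seed = 1, epochs = 120, patience = 5) {
  assert_scalar_count(n_trials, "n_trials")
  grid <- hyperparam_grid()
  rows <- with_seed(substream_seed(seed, "hp-draw"),
                    sample.int(nrow(grid), n_trials))
  trials <- grid[rows, ]
  aucs <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    hp <- siamese_hyperparams(trials$batch_size[i], trials$learning_rate[i],
                              trials$dropout_rate[i], trials$n_hidden_twin[i],
                              trials$n_hidden_final[i])
    m <- build_siamese(hp, ncol(features), seed = substream_seed(seed, "trial", i))
    m <- train_siamese(m, train_pairs, features, epochs = epochs,
                       seed = substream_seed(seed, "trial", i),
                       validation = val_pairs, patience = patience)
    pv <- predict_pairs(m, val_pairs, features, flip_average = TRUE)
    aucs[i] <- auroc(pv[val_pairs$label == "pos"], pv[val_pairs$label == "neg"])
  }
  trials$val_auroc <- aucs
  best <- which.max(aucs)  # which.max returns the first maximum: tie rule
  structure(
    list(best_hp = siamese_hyperparams(
      trials$batch_size[best], trials$learning_rate[best],
      trials$dropout_rate[best], trials$n_hidden_twin[best],
      trials$n_hidden_final[best]),
      best_auroc = aucs[best], trials = trials, seed = seed),
    class = "random_search"
  )
}

#' Train the final classifier ensemble for one distance
#'
#' With the selected hyperparameters, trains `k` classifiers (default 5),
#' each on an independent without-replacement sample of
#' `min(n_per_model, |pool|)` pairs from the training pool, with distinct
#' derived seeds.
#'
#' @param best_hp Hyperparameters (e.g. `random_search(...)$best_hp`).
#' @param train_pool Labelled pair pool to sample from.
#' @param features Feature matrix.
#' @param k Ensemble size (default 5).
#' @param n_per_model Training pairs per member (default 50000).
#' @param seed Master seed.
#' @param epochs,patience,validation Passed to [train_siamese()].
#' @return A `distance_ensemble`: members, their shared hyperparameters and
#'   distance, and training provenance.
#' @export
train_final_ensemble <- function(best_hp, train_pool, features, k = 5,
                                 n_per_model = 50000, seed = 1, epochs = 120,
                                 patience = 5, validation = NULL) {
  assert_scalar_count(k, "k")
  if (nrow(train_pool) == 0) abort("empty training pool")
  members <- lapply(seq_len(k), function(i) {
    sub <- sample_pairs(train_pool, min(n_per_model, nrow(train_pool)),
                        seed = substream_seed(seed, "member-sample", i))
    m <- build_siamese(best_hp, ncol(features),
                       seed = substream_seed(seed, "member", i))
    train_siamese(m, sub, features, epochs = epochs,
                  seed = substream_seed(seed, "member", i),
                  validation = validation, patience = patience)
  })
  structure(
    list(distance = members[[1]]$distance, members = members,
         best_hp = best_hp, seed = seed,
         train_chroms = sort(unique(unlist(lapply(members, `[[`, "train_chroms"))))),
    class = "distance_ensemble"
  )
}

#' @export
print.distance_ensemble <- function(x, ...) {
  cat(sprintf("distance ensemble: d = %.0f, %d member(s), trained on {%s}\n",
              x$distance, length(x$members),
              paste(x$train_chroms, collapse = ", ")))
  invisible(x)
}
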