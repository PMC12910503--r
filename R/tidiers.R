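# broom-style accessors for the package's result objects.

#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a distance curve
#'
#' @param x A `distance_curve`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @method tidy distance_curve
#' @export
tidy.distance_curve <- function(x, ...) as_tibble(x)

#' @rdname tidy.distance_curve
#' @method glance distance_curve
#' @export
glance.distance_curve <- function(x, ...) {
  metric <- attr(x, "metric")
  col <- if (metric %in% names(x)) x[[metric]] else x[[ncol(x)]]
  tibble::tibble(metric = metric, n_distances = dplyr::n_distinct(x$distance),
                 mean = mean(col, na.rm = TRUE),
                 min = min(col, na.rm = TRUE), max = max(col, na.rm = TRUE))
}

#' Tidy the gene-body quartile contrast
#'
#' @param x A `gene_quartile_test`.
#' @param ... Unused.
#' @method tidy gene_quartile_test
#' @export
tidy.gene_quartile_test <- function(x, ...) x$differences

#' @rdname tidy.gene_quartile_test
#' @method glance gene_quartile_test
#' @export
glance.gene_quartile_test <- function(x, ...) {
  tibble::tibble(n_genes = x$n_genes, n_dropped = x$n_dropped,
                 median_difference = stats::median(x$differences$difference),
                 p_value = x$p_value)
}

#' Tidy the TAD within-versus-cross test
#'
#' @param x A `tad_test`.
#' @param ... Unused.
#' @method tidy tad_test
#' @export
tidy.tad_test <- function(x, ...) x$per_distance

#' @rdname tidy.tad_test
#' @method glance tad_test
#' @export
glance.tad_test <- function(x, ...) {
  tibble::tibble(n_significant = x$n_significant, n_distances = x$n_distances,
                 alpha = x$alpha, n_two_tads = x$n_two_tads)
}

#' Tidy the matched-control variant test
#'
#' @param x A `variant_pair_test`.
#' @param ... Unused.
#' @method tidy variant_pair_test
#' @export
tidy.variant_pair_test <- function(x, ...) x$per_trait

#' @rdname tidy.variant_pair_test
#' @method glance variant_pair_test
#' @export
glance.variant_pair_test <- function(x, ...) {
  tibble::tibble(n_higher = x$n_higher, n_traits = x$n_traits,
                 expected = x$expected, p_value = x$p_value)
}

#' Tidy a state-pair category summary
#'
#' @param x A `state_category_summary`.
#' @param ... Unused.
#' @method tidy state_category_summary
#' @export
tidy.state_category_summary <- function(x, ...) {
  dplyr::select(x$summary, -"values")
}

#' Tidy a hyperparameter random search
#'
#' @param x A `random_search`.
#' @param ... Unused.
#' @return One row per trial with its validation AUROC.
#' @method tidy random_search
#' @export
tidy.random_search <- function(x, ...) x$trials

#' @rdname tidy.random_search
#' @method glance random_search
#' @export
glance.random_search <- function(x, ...) {
  tibble::tibble(best_auroc = x$best_auroc,
                 batch_size = x$best_hp$batch_size,
                 learning_rate = x$best_hp$learning_rate,
                 dropout_rate = x$best_hp$dropout_rate,
                 n_hidden_twin = x$best_hp$n_hidden_twin,
                 n_hidden_final = x$best_hp$n_hidden_final)
}

#' Summarise a trained Siamese model
#'
#' @param x A `siamese_model`.
#' @param ... Unused.
#' @method glance siamese_model
#' @export
glance.siamese_model <- function(x, ...) {
  tibble::tibble(n_features = x$n_features, distance = x$distance,
                 epochs_run = x$epochs_run, trained = x$trained,
                 best_val_auroc = if (length(x$val_history))
                   max(x$val_history) else NA_real_)
}
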