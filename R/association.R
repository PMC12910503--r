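# Biological-validation statistics. Every analysis takes a score table of
# the shared schema (chrom, start1, start2, distance, score), so the
# learned, Jaccard and contact scorings are compared with identical code.

snap_to_window <- function(pos, r) floor(pos / r) * r

# Score lookup for arbitrary window pairs (orientation normalised).
lookup_pair_scores <- function(table, chrom, w1, w2) {
  q <- tibble::tibble(chrom = chrom, start1 = pmin(w1, w2),
                      start2 = pmax(w1, w2))
  dplyr::left_join(q, as_tibble(table)[c("chrom", "start1", "start2", "score")],
                   by = c("chrom", "start1", "start2"))$score
}

#' Gene-body quartile contrast
#'
#' For a gene of length `l` with quartile `q = l/4`, compares the score
#' percentile of a pair of bases inside the gene body (quartile points 1 and
#' 3, i.e. `2q` apart) with a distance-matched pair sharing the inner base
#' but crossing the gene's end (`q` beyond the transcription end site). Both
#' bases are snapped to their window starts; genes whose two pairs are no
#' longer distance-matched after snapping, are shorter than `4r`, or lack a
#' scored pair (e.g. beyond the maximum distance) are dropped and counted. A
#' positive difference means the score prefers pairs within genes over pairs
#' crossing gene boundaries; the one-sided Wilcoxon signed-rank test asks
#' whether differences exceed zero.
#'
#' @param pct_table Percentile score table (see [percentile_transform()]).
#' @param genes Tibble with `chrom`, `tss`, `tes`, `name`, `strand`
#'   (`"+"`/`"-"`; for `-` genes the geometry is mirrored).
#' @param r Window resolution; defaults to the table's attribute.
#' @return A `gene_quartile_test` list: per-gene `differences` tibble,
#'   `p_value`, `n_genes`, `n_dropped`.
#' @export
gene_percentile_differences <- function(pct_table, genes,
                                        r = attr(pct_table, "r")) {
  if (is.null(r)) abort("window resolution r is needed")
  g <- as_tibble(genes)
  if (!"strand" %in% names(g)) g$strand <- "+"
  l <- abs(g$tes - g$tss)
  q <- l / 4
  short <- l < 4 * r
  sgn <- ifelse(g$strand == "-", -1, 1)
  within_a <- snap_to_window(g$tss + sgn * q, r)
  within_b <- snap_to_window(g$tss + sgn * 3 * q, r)
  cross_b <- snap_to_window(g$tes + sgn * q, r)
  d_within <- abs(within_b - within_a)
  d_cross <- abs(cross_b - within_b)
  ok <- !short & d_within == d_cross & d_within > 0
  w_pct <- rep(NA_real_, nrow(g))
  c_pct <- rep(NA_real_, nrow(g))
  w_pct[ok] <- lookup_pair_scores(pct_table, g$chrom[ok], within_a[ok], within_b[ok])
  c_pct[ok] <- lookup_pair_scores(pct_table, g$chrom[ok], within_b[ok], cross_b[ok])
  keep <- ok & !is.na(w_pct) & !is.na(c_pct)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("gene quartile contrast: dropped %d gene(s) (short, distance-mismatched after snapping, or unscored pair)",
                   n_dropped))
  }
  diffs <- tibble::tibble(
    name = g$name[keep], chrom = g$chrom[keep],
    within_pct = w_pct[keep], crossing_pct = c_pct[keep],
    difference = w_pct[keep] - c_pct[keep])
  pv <- if (nrow(diffs) == 0 || all(diffs$difference == 0)) {
    1
  } else {
    suppressWarnings(wilcox.test(diffs$difference, alternative = "greater"))$p.value
  }
  structure(list(differences = diffs, p_value = pv, n_genes = nrow(diffs),
                 n_dropped = n_dropped),
            class = "gene_quartile_test")
}

#' @export
print.gene_quartile_test <- function(x, ...) {
  cat(sprintf("gene quartile contrast: %d gene(s), median difference %.3f, one-sided signed-rank p = %.3g\n",
              x$n_genes, stats::median(x$differences$difference), x$p_value))
  invisible(x)
}

#' Bundle a chromatin-state segmentation with its state groups
#'
#' @param intervals Tibble `chrom`, `start`, `end`, `label` (state name).
#' @param groups Named character vector mapping every state name to a
#'   broader state group (e.g. promoter, enhancer, transcription,
#'   quiescent).
#' @return A `state_annotation` list.
#' @export
state_annotation <- function(intervals, groups) {
  missing <- setdiff(unique(intervals$label), names(groups))
  if (length(missing)) {
    abort(sprintf("states missing from the group map: %s",
                  paste(missing, collapse = ", ")))
  }
  structure(list(intervals = as_tibble(intervals), groups = groups),
            class = "state_annotation")
}

# Base counts of each state within each grid window: tibble key x state.
window_state_weights <- function(intervals, r) {
  first <- floor(intervals$start / r)
  last <- floor((intervals$end - 1) / r)
  n <- last - first + 1
  w <- tibble::tibble(
    chrom = rep(intervals$chrom, n),
    state = rep(intervals$label, n),
    wstart = unlist(Map(seq, first, last), use.names = FALSE) * r,
    istart = rep(intervals$start, n),
    iend = rep(intervals$end, n)
  )
  w$width <- pmin(w$iend, w$wstart + r) - pmax(w$istart, w$wstart)
  dplyr::summarise(dplyr::group_by(w, .data$chrom, .data$wstart, .data$state),
                   width = sum(.data$width), .groups = "drop")
}

#' Weighted mean score percentile for every pair of chromatin states
#'
#' Each window pair at distance `d` contributes to cell (u, v) with weight
#' equal to (bases of state u in the upstream window) times (bases of state
#' v in the downstream window); the cell value is the weighted mean score.
#' Cells whose total weight is less than `min_cov_frac` of the summed weight
#' of all state pairs are masked (`NA`), removing combinations too rare to
#' estimate. The default threshold is 5e-6, i.e. 0.0005%.
#'
#' @param pct_table Percentile score table restricted internally to
#'   distance `d`.
#' @param states A [state_annotation()].
#' @param d The single pairwise distance analysed.
#' @param min_cov_frac Masking threshold as a fraction (default `5e-6`).
#' @param r Window resolution; defaults to the table's attribute.
#' @return A `state_pair_matrix`: states x states numeric matrix with
#'   attributes `weights`, `d`, `groups`.
#' @export
state_pair_matrix <- function(pct_table, states, d, min_cov_frac = 5e-6,
                              r = attr(pct_table, "r")) {
  if (is.null(r)) abort("window resolution r is needed")
  stopifnot(inherits(states, "state_annotation"))
  tab <- as_tibble(pct_table)
  tab <- tab[tab$distance == d, ]
  alphabet <- names(states$groups)
  ww <- window_state_weights(states$intervals, r)
  keys <- unique(window_key(ww$chrom, ww$wstart))
  W <- matrix(0, nrow = length(keys), ncol = length(alphabet),
              dimnames = list(keys, alphabet))
  W[cbind(match(window_key(ww$chrom, ww$wstart), keys),
          match(ww$state, alphabet))] <- ww$width
  iu <- match(window_key(tab$chrom, tab$start1), keys)
  id <- match(window_key(tab$chrom, tab$start2), keys)
  keep <- !is.na(iu) & !is.na(id)
  Wu <- W[iu[keep], , drop = FALSE]
  Wd <- W[id[keep], , drop = FALSE]
  s <- tab$score[keep]
  weights <- t(Wu) %*% Wd
  values <- t(Wu) %*% (Wd * s)
  M <- values / weights
  total <- sum(weights)
  masked <- weights < min_cov_frac * total | weights == 0
  M[masked] <- NA_real_
  structure(M, weights = weights, d = d, groups = states$groups,
            min_cov_frac = min_cov_frac, class = c("state_pair_matrix", "matrix"))
}

#' Summarise a state-pair matrix by pair category
#'
#' Cells are placed in three disjoint categories: pairs of the same state;
#' pairs of different states from the same state group; and pairs of states
#' from different groups where both groups are "active" (promoter,
#' transcription or enhancer associated). When several matrices are given
#' (e.g. learned, Jaccard and contact scorings of the same pairs), each
#' non-reference scoring is compared to the reference per category with a
#' two-sided Mann-Whitney U test.
#'
#' @param matrices A `state_pair_matrix` or a named list of them (the first
#'   is the reference).
#' @param active_groups Group names counted as active (default
#'   `c("promoter", "transcription", "enhancer")`).
#' @return A `state_category_summary` list: `summary` tibble (category,
#'   kind, n, mean) with cell values as a list-column, and `comparisons`
#'   tibble (category, kind, p_value) when several matrices were given.
#' @export
state_category_summary <- function(matrices,
                                   active_groups = c("promoter",
                                                     "transcription",
                                                     "enhancer")) {
  if (inherits(matrices, "state_pair_matrix")) {
    matrices <- list(score = matrices)
  }
  cell_values <- function(M) {
    groups <- attr(M, "groups")
    states <- rownames(M)
    gu <- groups[rep(states, times = length(states))]
    gv <- groups[rep(states, each = length(states))]
    su <- rep(states, times = length(states))
    sv <- rep(states, each = length(states))
    v <- as.vector(M)
    category <- dplyr::case_when(
      su == sv ~ "same state",
      gu == gv ~ "same group, different state",
      gu %in% active_groups & gv %in% active_groups ~ "active cross-group",
      TRUE ~ NA_character_
    )
    tibble::tibble(value = v, category = category)[!is.na(v) & !is.na(category), ]
  }
  summary <- purrr::imap_dfr(matrices, function(M, kind) {
    dplyr::summarise(dplyr::group_by(cell_values(M), .data$category),
                     kind = kind, n = dplyr::n(), mean = mean(.data$value),
                     values = list(.data$value), .groups = "drop")
  })
  all_cats <- c("same state", "same group, different state", "active cross-group")
  empty <- setdiff(all_cats, unique(summary$category))
  if (length(empty)) {
    warn(sprintf("empty state-pair categor%s: %s",
                 if (length(empty) > 1) "ies" else "y",
                 paste(empty, collapse = "; ")))
  }
  comparisons <- NULL
  if (length(matrices) > 1) {
    ref_kind <- names(matrices)[1]
    comparisons <- purrr::map_dfr(setdiff(names(matrices), ref_kind), function(k) {
      purrr::map_dfr(intersect(all_cats, unique(summary$category)), function(cat) {
        a <- summary$values[summary$kind == ref_kind & summary$category == cat]
        b <- summary$values[summary$kind == k & summary$category == cat]
        if (length(a) == 0 || length(b) == 0) return(NULL)
        tibble::tibble(category = cat, kind = k, p_value = suppressWarnings(
          wilcox.test(a[[1]], b[[1]])$p.value))
      })
    })
  }
  structure(list(summary = summary, comparisons = comparisons,
                 active_groups = active_groups),
            class = "state_category_summary")
}

#' Compare score distributions within TADs to those crossing a boundary
#'
#' At each pairwise distance, pairs with both windows fully inside the same
#' topologically associating domain form the within group; pairs with
#' exactly one window inside a TAD and the other outside any TAD form the
#' cross group. Pairs whose two windows sit in two different TADs belong to
#' neither group (their count is recorded). A one-sided Mann-Whitney U test
#' asks whether within-TAD scores are higher.
#'
#' @param table Score table.
#' @param tads Tibble `chrom`, `start`, `end` of TAD intervals.
#' @param alpha Significance threshold for the reported count of
#'   significant distances (default `1e-4`).
#' @param r Window resolution; defaults to the table's attribute.
#' @return A `tad_test` list: per-distance tibble (`distance`, `n_within`,
#'   `n_cross`, `p_value`), `n_significant`, `alpha`, `n_two_tads`.
#' @export
tad_within_vs_cross <- function(table, tads, alpha = 1e-4,
                                r = attr(table, "r")) {
  if (is.null(r)) abort("window resolution r is needed")
  tads <- as_tibble(tads)
  tads$tad_id <- seq_len(nrow(tads))
  # full windows inside each TAD
  first <- ceiling(tads$start / r)
  last <- floor(tads$end / r) - 1
  n <- pmax(0, last - first + 1)
  inside <- tibble::tibble(
    chrom = rep(tads$chrom, n),
    wstart = unlist(Map(function(f, l) if (l >= f) seq(f, l) else integer(0),
                        first, last), use.names = FALSE) * r,
    tad_id = rep(tads$tad_id, n))
  tab <- as_tibble(table)
  t1 <- inside$tad_id[match(window_key(tab$chrom, tab$start1),
                            window_key(inside$chrom, inside$wstart))]
  t2 <- inside$tad_id[match(window_key(tab$chrom, tab$start2),
                            window_key(inside$chrom, inside$wstart))]
  within <- !is.na(t1) & !is.na(t2) & t1 == t2
  cross <- xor(is.na(t1), is.na(t2))
  two_tads <- !is.na(t1) & !is.na(t2) & t1 != t2
  res <- purrr::map_dfr(sort(unique(tab$distance)), function(d) {
    sel <- tab$distance == d
    w <- tab$score[sel & within]
    x <- tab$score[sel & cross]
    if (length(w) == 0 || length(x) == 0) {
      inform(sprintf("TAD test: distance %.0f skipped (empty group)", d))
      return(NULL)
    }
    tibble::tibble(distance = d, n_within = length(w), n_cross = length(x),
                   p_value = suppressWarnings(
                     wilcox.test(w, x, alternative = "greater")$p.value))
  })
  if (nrow(res) == 0) {
    res <- tibble::tibble(distance = numeric(), n_within = integer(),
                          n_cross = integer(), p_value = numeric())
  }
  structure(list(per_distance = res,
                 n_significant = sum(res$p_value < alpha),
                 n_distances = nrow(res), alpha = alpha,
                 n_two_tads = sum(two_tads)),
            class = "tad_test")
}

#' @export
print.tad_test <- function(x, ...) {
  cat(sprintf("TAD within vs cross: %d of %d distance(s) significant at p < %g\n",
              x$n_significant, x$n_distances, x$alpha))
  invisible(x)
}

#' Per-distance correlation with a contact-frequency table
#'
#' Inner-joins the two tables on (chrom, start1, start2) and reports the
#' Pearson correlation per pairwise distance plus their unweighted mean.
#' Distances whose join is degenerate (fewer than two pairs, or zero
#' variance) are excluded.
#'
#' @param score_table,contact_table Score tables (the second typically of
#'   kind `"contact"`).
#' @return A `distance_curve` tibble (`distance`, `n`, `pcc`) with
#'   attribute `mean_pcc`.
#' @export
contact_correlation <- function(score_table, contact_table) {
  joined <- dplyr::inner_join(
    as_tibble(score_table),
    dplyr::rename(as_tibble(contact_table)[c("chrom", "start1", "start2", "score")],
                  contact = "score"),
    by = c("chrom", "start1", "start2"))
  if (nrow(joined) == 0) abort("no overlapping pairs between the tables")
  per_d <- dplyr::summarise(
    dplyr::group_by(joined, .data$distance),
    n = dplyr::n(),
    pcc = if (dplyr::n() < 2 || stats::sd(.data$score) == 0 ||
              stats::sd(.data$contact) == 0) NA_real_
    else cor(.data$score, .data$contact),
    .groups = "drop")
  per_d <- per_d[!is.na(per_d$pcc), ]
  if (nrow(per_d) == 0) abort("correlation undefined at every distance")
  out <- new_distance_curve(per_d, "pcc")
  attr(out, "mean_pcc") <- mean(per_d$pcc)
  out
}

#' Matched-control test for pairs of fine-mapped variants
#'
#' For each trait, original pairs are all same-chromosome pairs of windows
#' each containing at least one fine-mapped variant of the trait, with
#' pairwise distance between `r` and `D`. Each original pair (a, b) at
#' distance d yields two mirrored control pairs (a - d, a) and (b, b + d):
#' each control shares one window with the original and preserves its
#' distance, and its free window holds no fine-mapped variant of the trait.
#' Controls whose free window carries such a variant, falls off the scored
#' table (e.g. off-chromosome), or overlaps an assembly gap are dropped. A
#' trait counts as "higher" when the mean score of its original pairs
#' exceeds the mean of its retained controls (ties do not count). Under the
#' null each trait is higher with probability one half, giving the binomial
#' expectation and a two-sided binomial test.
#'
#' @param table Score table.
#' @param variants Tibble `trait`, `chrom`, `pos` (0-based base positions);
#'   filter to one fine-mapping method beforehand if several are present.
#' @param D Maximum pairwise distance (default: maximum in `table`).
#' @param gaps Optional gap intervals used to drop gap-overlapping controls.
#' @param r Window resolution; defaults to the table's attribute.
#' @return A `variant_pair_test` list: `per_trait` tibble, `n_higher`,
#'   `n_traits`, `expected`, `p_value`.
#' @export
variant_pair_test <- function(table, variants, D = max(table$distance),
                              gaps = NULL, r = attr(table, "r")) {
  if (is.null(r)) abort("window resolution r is needed")
  v <- as_tibble(variants)
  v$wstart <- snap_to_window(v$pos, r)
  per_trait <- purrr::map_dfr(split(v, v$trait), function(tv) {
    trait <- tv$trait[1]
    vkeys <- unique(window_key(tv$chrom, tv$wstart))
    orig <- purrr::map_dfr(split(tv, tv$chrom), function(cv) {
      ws <- sort(unique(cv$wstart))
      if (length(ws) < 2) return(NULL)
      combs <- t(utils::combn(ws, 2))
      tibble::tibble(chrom = cv$chrom[1], start1 = combs[, 1],
                     start2 = combs[, 2])
    })
    if (nrow(orig) == 0) return(NULL)
    orig$distance <- orig$start2 - orig$start1
    orig <- orig[orig$distance >= r & orig$distance <= D, ]
    if (nrow(orig) == 0) return(NULL)
    orig$score <- lookup_pair_scores(table, orig$chrom, orig$start1, orig$start2)
    orig <- orig[!is.na(orig$score), ]
    if (nrow(orig) == 0) return(NULL)
    ctrl <- dplyr::bind_rows(
      tibble::tibble(chrom = orig$chrom, start1 = orig$start1 - orig$distance,
                     start2 = orig$start1, free = orig$start1 - orig$distance),
      tibble::tibble(chrom = orig$chrom, start1 = orig$start2,
                     start2 = orig$start2 + orig$distance,
                     free = orig$start2 + orig$distance))
    ctrl <- ctrl[ctrl$start1 >= 0, ]
    ctrl <- ctrl[!window_key(ctrl$chrom, ctrl$free) %in% vkeys, ]
    if (!is.null(gaps) && nrow(ctrl) > 0) {
      attr(ctrl, "r") <- r
      ctrl <- filter_gap_pairs(ctrl, gaps, r = r)
    }
    if (nrow(ctrl) > 0) {
      ctrl$score <- lookup_pair_scores(table, ctrl$chrom, ctrl$start1, ctrl$start2)
      ctrl <- ctrl[!is.na(ctrl$score), ]
    }
    if (nrow(ctrl) == 0) {
      inform(sprintf("variant test: trait %s has no retained control pairs; excluded",
                     trait))
      return(NULL)
    }
    tibble::tibble(trait = trait, n_pairs = nrow(orig), n_controls = nrow(ctrl),
                   mean_original = mean(orig$score),
                   mean_control = mean(ctrl$score),
                   higher = mean(orig$score) > mean(ctrl$score))
  })
  if (nrow(per_trait) == 0) abort("no trait had any evaluable variant pair")
  n_traits <- nrow(per_trait)
  n_higher <- sum(per_trait$higher)
  structure(list(per_trait = per_trait, n_higher = n_higher,
                 n_traits = n_traits, expected = n_traits * 0.5,
                 p_value = binom.test(n_higher, n_traits, 0.5)$p.value),
            class = "variant_pair_test")
}

#' @export
print.variant_pair_test <- function(x, ...) {
  cat(sprintf("variant pair test: %d of %d trait(s) higher (%.1f expected by chance), binomial p = %.3g\n",
              x$n_higher, x$n_traits, x$expected, x$p_value))
  invisible(x)
}
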