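# A deterministic "domain world" where the truth is known: scores are high
# exactly when both windows fall in the same planted domain. Genes, TADs and
# variants coincide with the domains, so every analysis has a known answer.
domain_world <- function(seed = 21, n_chroms = 2, n_windows = 120,
                         distances = seq(1000, 5000, by = 1000)) {
  r <- 1000
  w <- toy_windows(n_chroms = n_chroms, n_windows = n_windows)
  withr::with_seed(seed, {
    doms <- purrr::map_dfr(unique(w$chrom), function(ch) {
      lens <- c()
      while (sum(lens) < n_windows) lens <- c(lens, sample(6:14, 1))
      lens[length(lens)] <- lens[length(lens)] - (sum(lens) - n_windows)
      tibble::tibble(chrom = ch,
                     start = (cumsum(lens) - lens) * r,
                     end = cumsum(lens) * r)
    })
    dom_of <- function(chrom, wstart) {
      hit <- doms$chrom == chrom & doms$start <= wstart & doms$end > wstart
      ifelse(any(hit), which(hit)[1], NA_integer_)
    }
    tab <- toy_score_table(w, distances, function(t) {
      same <- mapply(function(ch, a, b) {
        da <- dom_of(ch, a); db <- dom_of(ch, b)
        !is.na(da) && !is.na(db) && da == db
      }, t$chrom, t$start1, t$start2)
      ifelse(same, 0.7, 0.2) + runif(nrow(t), 0, 0.1)
    })
  })
  list(windows = w, domains = doms, table = tab,
       pct = percentile_transform(tab, "per_distance"), r = r)
}

test_that("gene quartile geometry snaps to windows and finds planted genes", {
  dw <- domain_world(n_windows = 300, distances = seq(1000, 6000, by = 1000))
  # genes = domains of length >= 8 windows, mixed strands
  doms <- dw$domains[dw$domains$end - dw$domains$start >= 8000, ]
  genes <- tibble::tibble(
    chrom = doms$chrom,
    strand = rep(c("+", "-"), length.out = nrow(doms)),
    name = paste0("g", seq_len(nrow(doms))))
  genes$tss <- ifelse(genes$strand == "+", doms$start, doms$end)
  genes$tes <- ifelse(genes$strand == "+", doms$end, doms$start)
  res <- suppressMessages(gene_percentile_differences(dw$pct, genes))
  expect_s3_class(res, "gene_quartile_test")
  expect_gt(res$n_genes, 3)
  expect_gt(median(res$differences$difference), 0)
  expect_lt(res$p_value, 0.05)
  g <- glance(res)
  expect_equal(g$p_value, res$p_value)
})

test_that("a constant score yields zero differences and no significance", {
  w <- toy_windows(n_chroms = 1, n_windows = 60)
  tab <- toy_score_table(w, seq(1000, 5000, 1000), function(t) rep(1, nrow(t)))
  pct <- percentile_transform(tab)
  genes <- tibble::tibble(chrom = "chr1", tss = 0, tes = 8000,
                          name = "g1", strand = "+")
  res <- gene_percentile_differences(pct, genes)
  expect_equal(res$differences$difference, 0)
  expect_equal(res$p_value, 1)
})

test_that("short or distance-mismatched genes are dropped with a log", {
  w <- toy_windows(n_chroms = 1, n_windows = 60)
  tab <- toy_score_table(w, seq(1000, 5000, 1000), function(t) runif(nrow(t)))
  pct <- percentile_transform(tab)
  genes <- tibble::tibble(
    chrom = "chr1",
    tss = c(0, 0),
    tes = c(3000, 55000),   # too short; crossing pair beyond max distance
    name = c("short", "far"), strand = "+")
  expect_message(res <- gene_percentile_differences(pct, genes), "dropped")
  expect_equal(res$n_genes, 0)
  expect_equal(res$n_dropped, 2)
})

test_that("a gene of length 8r yields distance-matched 4r pairs", {
  # l = 8r: quartile points at 2r, 6r; crossing point at TES + 2r;
  # both pairs span 4r after snapping, so the gene must be retained
  w <- toy_windows(n_chroms = 1, n_windows = 40)
  tab <- toy_score_table(w, seq(1000, 8000, 1000), function(t) runif(nrow(t)))
  pct <- percentile_transform(tab)
  genes <- tibble::tibble(chrom = "chr1", tss = 8000, tes = 16000,
                          name = "g", strand = "+")
  res <- gene_percentile_differences(pct, genes)
  expect_equal(res$n_genes, 1)
  expect_equal(res$n_dropped, 0)
})

test_that("state-pair matrices recover hand-computed weighted means", {
  r <- 1000
  w <- toy_windows(n_chroms = 1, n_windows = 8)
  tab <- toy_score_table(w, 2000, function(t) seq(0.1, by = 0.1,
                                                  length.out = nrow(t)))
  # windows 0 and 2 paired at d=2: scores known; annotate partial windows
  ann <- state_annotation(
    tibble::tibble(chrom = "chr1",
                   start = c(0, 600, 2000, 2500),
                   end = c(600, 2000, 2500, 8000),
                   label = c("A", "B", "A", "B")),
    groups = c(A = "enhancer", B = "quiescent"))
  m <- state_pair_matrix(tab, ann, d = 2000, min_cov_frac = 0, r = r)
  expect_equal(dim(m), c(2, 2))
  # hand oracle, cell (A, A): only pair (0, 2000) has A on both sides
  # (600 bases upstream x 500 downstream); its score is 0.1
  expect_equal(m["A", "A"], 0.1)
  # cell (B, B), accumulated over the six pairs at d = 2000:
  # (0,2000): 400x500 @ 0.1; (1000,3000): 1000x1000 @ 0.2;
  # (2000,4000): 500x1000 @ 0.3; (3000..5000, +2000): 1000x1000 @ 0.4-0.6
  wts <- c(400 * 500, 1000 * 1000, 500 * 1000, 1e6, 1e6, 1e6)
  vals <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  expect_equal(m["B", "B"], sum(wts * vals) / sum(wts))
})

test_that("single-state annotations collapse to the unweighted mean", {
  w <- toy_windows(n_chroms = 1, n_windows = 10)
  withr::with_seed(3, {
    tab <- toy_score_table(w, 3000, function(t) runif(nrow(t)))
  })
  ann <- state_annotation(
    tibble::tibble(chrom = "chr1", start = 0, end = 10000, label = "S"),
    groups = c(S = "quiescent"))
  m <- state_pair_matrix(tab, ann, d = 3000, r = 1000)
  expect_equal(dim(m), c(1, 1))
  expect_equal(as.numeric(m), mean(tab$score[tab$distance == 3000]))
})

test_that("low-coverage state pairs are masked at the configured fraction", {
  w <- toy_windows(n_chroms = 1, n_windows = 50)
  tab <- toy_score_table(w, 1000, function(t) runif(nrow(t)))
  ann <- state_annotation(
    tibble::tibble(chrom = "chr1", start = c(0, 1000),
                   end = c(1000, 50000), label = c("rare", "common")),
    groups = c(rare = "enhancer", common = "quiescent"))
  m_all <- state_pair_matrix(tab, ann, d = 1000, min_cov_frac = 0)
  expect_false(is.na(m_all["rare", "common"]))
  m_masked <- state_pair_matrix(tab, ann, d = 1000, min_cov_frac = 0.05)
  expect_true(is.na(m_masked["rare", "common"]))
  expect_false(is.na(m_masked["common", "common"]))
})

test_that("state categories are disjoint and track planted diagonal signal", {
  groups <- c(P1 = "promoter", P2 = "promoter", E1 = "enhancer",
              T1 = "transcription", Q1 = "quiescent")
  M <- matrix(0.5, 5, 5, dimnames = list(names(groups), names(groups)))
  diag(M) <- 0.9
  attr(M, "groups") <- groups
  class(M) <- c("state_pair_matrix", "matrix")
  res <- state_category_summary(M)
  s <- res$summary
  expect_setequal(unique(s$category),
                  c("same state", "same group, different state",
                    "active cross-group"))
  expect_equal(s$n[s$category == "same state"], 5)
  expect_equal(s$n[s$category == "same group, different state"], 2)  # P1P2, P2P1
  expect_equal(s$n[s$category == "active cross-group"], 10)
  expect_equal(sum(s$n), 17)  # categories never share a cell
  expect_gt(s$mean[s$category == "same state"], mean(M))

  flat <- M
  flat[] <- 0.4
  attr(flat, "groups") <- groups
  class(flat) <- c("state_pair_matrix", "matrix")
  res2 <- state_category_summary(list(learned = M, jaccard = M))
  expect_equal(res2$summary$mean[res2$summary$kind == "learned"],
               res2$summary$mean[res2$summary$kind == "jaccard"])
  # identical distributions: the rank-sum test finds nothing (ties can make
  # the normal approximation degenerate, reported as NA)
  expect_true(all(is.na(res2$comparisons$p_value) |
                    res2$comparisons$p_value > 0.9))
})

test_that("TAD contrast separates planted domains and handles edge pairs", {
  dw <- domain_world()
  # TAD calls skip every third domain, so some windows lie outside any TAD
  # while adjacent TADs still touch (making straddling pairs possible)
  tads <- dw$domains[-seq(3, nrow(dw$domains), by = 3), ]
  res <- suppressMessages(tad_within_vs_cross(dw$table, tads, alpha = 1e-4))
  expect_s3_class(res, "tad_test")
  expect_equal(res$n_distances, 5)
  expect_gte(res$n_significant, res$n_distances - 1)
  # straddling pairs (two different TADs) belong to neither group
  expect_gt(res$n_two_tads, 0)
  per_d <- tidy(res)
  expect_true(all(per_d$n_within > 0))
  expect_true(all(per_d$n_cross > 0))

  flat <- dw$table
  flat$score <- 0.5
  res2 <- suppressMessages(tad_within_vs_cross(flat, tads, alpha = 1e-4))
  expect_equal(res2$n_significant, 0)
})

test_that("analyses on percentile tables ignore monotone score transforms", {
  dw <- domain_world()
  warped <- dw$table
  warped$score <- exp(3 * warped$score)  # strictly increasing transform
  p1 <- percentile_transform(dw$table, "per_distance")
  p2 <- percentile_transform(warped, "per_distance")
  expect_equal(p1$score, p2$score)
})

test_that("contact correlation joins by pair and averages defined distances", {
  dw <- domain_world()
  self <- contact_correlation(dw$table, dw$table)
  expect_equal(attr(self, "mean_pcc"), 1)

  withr::with_seed(31, {
    indep <- dw$table
    indep$score <- runif(nrow(indep))
  })
  res <- contact_correlation(dw$table, indep)
  expect_lt(abs(attr(res, "mean_pcc")), 0.1)

  # a single shared pair at a distance has undefined variance: excluded
  one <- dw$table[dw$table$distance == 1000, ][1, ]
  rest <- dw$table[dw$table$distance == 2000, ]
  both <- dplyr::bind_rows(one, rest)
  res2 <- contact_correlation(both, both)
  expect_false(1000 %in% res2$distance)

  off <- dw$table
  off$start1 <- off$start1 + 7
  expect_error(contact_correlation(dw$table, off), "no overlapping")
})

test_that("variant controls mirror the original pair and traits are counted", {
  r <- 1000
  w <- toy_windows(n_chroms = 1, n_windows = 100)
  withr::with_seed(41, {
    tab <- toy_score_table(w, seq(1000, 10000, 1000),
                           function(t) runif(nrow(t), 0, 0.2))
  })
  # plant one high-scoring pair and depressed controls for trait A
  hi <- tab$chrom == "chr1" & tab$start1 == 50000 & tab$start2 == 53000
  tab$score[hi] <- 0.99
  variants <- tibble::tibble(trait = "A", method = "synthetic",
                             chrom = "chr1", pos = c(50500, 53900))
  res <- variant_pair_test(tab, variants, D = 10000)
  expect_equal(res$n_traits, 1)
  expect_equal(res$per_trait$n_pairs, 1)
  # controls are (47000, 50000) and (53000, 56000)
  expect_equal(res$per_trait$n_controls, 2)
  expect_true(res$per_trait$higher)
  expect_equal(res$expected, 0.5)

  # a constant score ties every comparison: no trait counts as higher
  flat <- tab
  flat$score <- 0.3
  res2 <- variant_pair_test(flat, variants, D = 10000)
  expect_equal(res2$n_higher, 0)
})

test_that("variant test finds planted enrichment across many traits", {
  dw <- domain_world(n_chroms = 2, n_windows = 200)
  withr::with_seed(55, {
    doms <- dw$domains[(dw$domains$end - dw$domains$start) / 1000 >= 4, ]
    variants <- purrr::map_dfr(1:40, function(t) {
      row <- doms[sample.int(nrow(doms), 1), ]
      nw <- (row$end - row$start) / 1000
      offs <- sample(seq(0, nw - 1), 2)
      tibble::tibble(trait = sprintf("t%02d", t), method = "synthetic",
                     chrom = row$chrom,
                     pos = row$start + offs * 1000 +
                       sample(0:999, 2, replace = TRUE))
    })
  })
  res <- suppressMessages(variant_pair_test(dw$table, variants, D = 5000))
  expect_gte(res$n_traits, 25)
  expect_gt(res$n_higher, res$expected)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$expected, res$n_traits * 0.5)
})
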