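test_that("binning tiles chromosomes with fixed windows and drops the remainder", {
  w <- bin_genome(genome_layout("chr1", 10000, 1000))
  expect_equal(nrow(w), 10)
  expect_equal(w$start, seq(0, 9000, by = 1000))

  w2 <- bin_genome(genome_layout("chr1", 10500, 1000))
  expect_equal(nrow(w2), 10)
  expect_equal(max(w2$end), 10000)  # bases 10000-10499 unassigned

  expect_warning(w3 <- bin_genome(genome_layout("chr1", 999, 1000)),
                 "no windows")
  expect_equal(nrow(w3), 0)
})

test_that("total window count matches the per-chromosome floor formula", {
  withr::with_seed(42, {
    for (i in 1:10) {
      lens <- sample(500:25000, sample(2:6, 1))
      r <- sample(c(250, 1000, 2000), 1)
      layout <- genome_layout(paste0("c", seq_along(lens)), lens, r)
      w <- suppressWarnings(bin_genome(layout))
      expect_equal(nrow(w), sum(floor(lens / r)))
      expect_true(all(w$start %% r == 0))
      expect_true(all(w$end <= layout$chrom_lengths[w$chrom]))
    }
  })
})

test_that("featurization sets peak columns on >=1 bp overlap", {
  w <- toy_windows(n_chroms = 1, n_windows = 5)
  peaks <- list(
    a = tibble::tibble(chrom = "chr1", start = 999, end = 1200),
    b = tibble::tibble(chrom = "chr1", start = 4990, end = 4995)
  )
  fm <- featurize(w, peaks)
  expect_equal(dim(fm), c(5, 2))
  # 1-bp overlap with window [0,1000) counts, as does the rest of the peak
  expect_equal(unname(fm[, "a"]), c(1L, 1L, 0L, 0L, 0L))
  expect_equal(unname(fm[, "b"]), c(0L, 0L, 0L, 0L, 1L))
  expect_true(all(fm %in% c(0L, 1L)))
})

test_that("a window can carry several one-hot states of one epigenome", {
  w <- toy_windows(n_chroms = 1, n_windows = 2)
  seg <- tibble::tibble(chrom = "chr1", start = c(0, 500, 1000),
                        end = c(500, 1000, 2000),
                        label = c("A", "B", "A"))
  fm <- featurize(w, state_sets = list(E1 = seg), state_alphabet = c("A", "B"))
  expect_equal(colnames(fm), c("E1.A", "E1.B"))
  expect_equal(unname(fm[1, ]), c(1L, 1L))  # both states touch window 1
  expect_equal(unname(fm[2, ]), c(1L, 0L))
})

test_that("feature columns follow the P + S x E identity and fixed order", {
  w <- toy_windows(n_chroms = 1, n_windows = 3)
  peaks <- setNames(rep(list(win_interval("chr1", 0, 0)), 3), c("p1", "p2", "p3"))
  seg <- tibble::tibble(chrom = "chr1", start = 0, end = 1000, label = "A")
  fm <- featurize(w, peaks, list(E1 = seg, E2 = seg), c("A", "B"))
  expect_equal(ncol(fm), 3 + 2 * 2)
  expect_equal(colnames(fm), c("p1", "p2", "p3", "E1.A", "E1.B", "E2.A", "E2.B"))
  expect_equal(attr(fm, "source_kind"),
               c(rep("peak", 3), rep("state-onehot", 4)))
})

test_that("unknown state labels error and off-layout intervals are ignored", {
  w <- toy_windows(n_chroms = 1, n_windows = 3)
  seg_bad <- tibble::tibble(chrom = "chr1", start = 0, end = 100, label = "Z")
  expect_error(featurize(w, state_sets = list(E1 = seg_bad),
                         state_alphabet = c("A")), "Z")
  off <- tibble::tibble(chrom = "chrUn", start = 0, end = 100)
  expect_message(fm <- featurize(w, list(p = off)), "ignored 1")
  expect_equal(sum(fm), 0)
})

test_that("adding a peak interval is monotone on the feature matrix", {
  w <- toy_windows(n_chroms = 2, n_windows = 12)
  withr::with_seed(7, {
    for (i in 1:5) {
      base <- tibble::tibble(
        chrom = sample(c("chr1", "chr2"), 4, replace = TRUE),
        start = sample(0:11000, 4))
      base$end <- base$start + sample(100:3000, 4)
      extra <- dplyr::bind_rows(base, tibble::tibble(
        chrom = "chr1", start = sample(0:11000, 1), end = 12000))
      f1 <- featurize(w, list(p = base))
      f2 <- featurize(w, list(p = extra))
      expect_true(all(f2 >= f1))
    }
  })
})

test_that("grid overlap agrees with IRanges on random interval sets", {
  skip_if_not_installed("IRanges")
  w <- toy_windows(n_chroms = 1, n_windows = 50)
  withr::with_seed(13, {
    for (i in 1:10) {
      iv <- tibble::tibble(chrom = "chr1", start = sample(0:49500, 8))
      iv$end <- iv$start + sample(1:5000, 8)
      fm <- featurize(w, list(p = iv))
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(w$start + 1, w$end),
        IRanges::IRanges(iv$start + 1, iv$end))
      expected <- integer(nrow(w))
      expected[unique(S4Vectors::queryHits(hits))] <- 1L
      expect_equal(unname(fm[, 1]), expected)
    }
  })
})

test_that("gap filtering removes pairs touching a gap in either window", {
  pairs <- tibble::tibble(
    chrom = "chr1",
    start1 = c(0, 1000, 2000, 3000, 4000),
    start2 = c(5000, 6000, 5000, 8000, 9000),
    distance = c(5000, 5000, 3000, 5000, 5000))
  attr(pairs, "r") <- 1000

  gap <- tibble::tibble(chrom = "chr1", start = 5500, end = 5600)
  kept <- filter_gap_pairs(pairs, gap)
  # gap hits window 5000-5999, which appears in pairs 1 and 3
  expect_equal(nrow(kept), 3)
  expect_false(any(kept$start1 == 0))

  expect_identical(filter_gap_pairs(pairs,
                                    tibble::tibble(chrom = character(),
                                                   start = numeric(),
                                                   end = numeric())),
                   pairs)
  # idempotent
  expect_equal(filter_gap_pairs(kept, gap), kept)
})

test_that("feature matrices round-trip through the dense text format", {
  w <- toy_windows(n_chroms = 1, n_windows = 6)
  peaks <- list(a = win_interval("chr1", 0, 2), b = win_interval("chr1", 4, 5))
  seg <- tibble::tibble(chrom = "chr1", start = 0, end = 6000, label = "A")
  fm <- featurize(w, peaks, list(E1 = seg), c("A", "B"))
  path <- withr::local_tempfile()
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path, r = 1000)
  expect_equal(unname(back), unname(fm), ignore_attr = TRUE)
  expect_equal(colnames(back), colnames(fm))
  expect_equal(rownames(back), rownames(fm))
  expect_equal(attr(back, "source_kind"), attr(fm, "source_kind"))
})
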