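# Synthetic test worlds. The generator plants the one statistical property
# the scoring method relies on — windows near each other are more likely to
# share (or complement) feature activity than random windows of the same
# chromosome — and emits every annotation the analysis stack consumes
# (peaks, states, genes, TADs, gaps, fine-mapped variants) aligned to that
# planted structure. It makes no attempt at realistic chromatin biology.

#' Parameters of a synthetic genome
#'
#' Chromosomes are tiled by latent domains whose lengths are geometric with
#' mean `decay_scale` bases, so the probability that two windows at distance
#' `d` share a domain — and hence the planted association — decays roughly
#' as `exp(-d / decay_scale)`. Active domains (probability `p_active`)
#' activate a planted block of peak features in their windows at a rate set
#' by `association_strength`; the remaining features fire independently at
#' the background rate. Association modes: `"shared"` plants the same block
#' on all windows of a domain (associated *and* similar); `"complementary"`
#' alternates two disjoint blocks by window parity within the domain, so
#' adjacent true pairs have disjoint planted supports (associated but not
#' similar — feature similarity carries no signal at odd multiples of `r`);
#' `"none"` plants nothing (features independent of pairing). Chromatin
#' states are uniform per-window noise in every mode; genes and TADs
#' coincide with domains; per-trait variants are placed inside active
#' domains; gaps sit at a fraction of the domain boundaries.
#'
#' @param n_chroms,chrom_length Number of chromosomes and their length in
#'   bases (defaults 6 x 500 windows, enough for a split with two training
#'   chromosomes per parity).
#' @param r Window resolution in bases (default 1000).
#' @param D Maximum pairwise distance (default `10 * r`).
#' @param n_peak_features,n_state_epigenomes,n_states Feature design
#'   (defaults 60 peak assays, 3 epigenomes x 5 states).
#' @param association_mode `"shared"`, `"complementary"` or `"none"`.
#' @param association_strength Planted association strength in \[0, 1\].
#' @param decay_scale Mean domain length in bases (default `10 * r`).
#' @param p_active Probability a domain is active (default 0.9).
#' @param background_rate Background peak firing probability (default 0.05).
#' @param peak_block_size Planted block width in features (default 6 shared,
#'   5 complementary); smaller blocks mean more distinct blocks and fewer
#'   coincidental block matches among shuffled negatives.
#' @param n_traits,n_domains_per_trait,n_variants_per_domain Synthetic
#'   fine-mapped variant design (defaults 10, 3, 2).
#' @param gap_prob Probability of an assembly gap at a domain boundary
#'   (default 0.15).
#' @param seed Master seed; everything in the world derives from it.
#' @return A `fixture_params` list.
#' @export
fixture_params <- function(n_chroms = 6, chrom_length = 500 * r, r = 1000,
                           D = 10 * r, n_peak_features = 60,
                           n_state_epigenomes = 3, n_states = 5,
                           association_mode = c("shared", "complementary", "none"),
                           association_strength = 0.8,
                           decay_scale = 10 * r, p_active = 0.9,
                           background_rate = 0.05, peak_block_size = NULL,
                           n_traits = 10, n_domains_per_trait = 3,
                           n_variants_per_domain = 2, gap_prob = 0.15,
                           seed = 1) {
  association_mode <- match.arg(association_mode)
  if (association_strength < 0 || association_strength > 1) {
    abort("association_strength must be in [0, 1]")
  }
  if (decay_scale <= 0) abort("decay_scale must be > 0")
  if (is.null(peak_block_size)) {
    peak_block_size <- if (association_mode == "complementary") 5 else 6
  }
  structure(as.list(environment()), class = "fixture_params")
}

#' Simulate a synthetic genome with planted pairwise association
#'
#' @param params A [fixture_params()].
#' @return A `fixture_world` list: `params`, `layout`, `domains`, `peaks`
#'   (named list of interval tibbles, one per assay), `states` (named list
#'   of BED4-style segmentations, one per epigenome), `state_alphabet`,
#'   `genes`, `tads`, `gaps`, `variants`.
#' @export
simulate_world <- function(params = fixture_params()) {
  stopifnot(inherits(params, "fixture_params"))
  p <- params
  layout <- genome_layout(paste0("chr", seq_len(p$n_chroms)),
                          rep(p$chrom_length, p$n_chroms), p$r)
  with_seed(substream_seed(p$seed, "world"), {
    n_win <- floor(p$chrom_length / p$r)
    mean_len <- max(2, p$decay_scale / p$r)
    n_blocks <- if (p$association_mode == "complementary") {
      floor(p$n_peak_features / (2 * p$peak_block_size))
    } else {
      floor(p$n_peak_features / p$peak_block_size)
    }

    domains <- list()
    peak_mats <- list()
    for (chrom in layout$chrom_names) {
      # tile the chromosome with geometric-length domains (min 2 windows)
      lens <- integer(0)
      while (sum(lens) < n_win) {
        lens <- c(lens, 2 + stats::rgeom(1, prob = 1 / (mean_len - 1)))
      }
      lens[length(lens)] <- lens[length(lens)] - (sum(lens) - n_win)
      lens <- lens[lens > 0]
      dom <- tibble::tibble(
        chrom = chrom,
        dom_id = seq_along(lens),
        n_windows = lens,
        start = (cumsum(lens) - lens) * p$r,
        end = cumsum(lens) * p$r,
        active = runif(length(lens)) < p$p_active,
        block = sample.int(max(n_blocks, 1), length(lens), replace = TRUE)
      )
      domains[[chrom]] <- dom

      # per-window peak firing probabilities
      prob <- matrix(p$background_rate, n_win, p$n_peak_features)
      if (p$association_mode != "none" && p$association_strength > 0) {
        p_on <- p$background_rate +
          (0.95 - p$background_rate) * p$association_strength
        dom_of_win <- rep(seq_along(lens), lens)
        offset <- unlist(lapply(lens, seq_len), use.names = FALSE) - 1
        for (i in which(dom$active)) {
          win <- which(dom_of_win == i)
          if (p$association_mode == "shared") {
            cols <- (dom$block[i] - 1) * p$peak_block_size + seq_len(p$peak_block_size)
            prob[win, cols] <- p_on
          } else {
            half <- floor(p$n_peak_features / 2)
            colsA <- (dom$block[i] - 1) * p$peak_block_size + seq_len(p$peak_block_size)
            colsB <- half + colsA
            even <- win[offset[win] %% 2 == 0]
            odd <- win[offset[win] %% 2 == 1]
            prob[even, colsA] <- p_on
            prob[odd, colsB] <- p_on
          }
        }
      }
      peak_mats[[chrom]] <- matrix(runif(length(prob)) < prob, n_win)
    }
    domains <- dplyr::bind_rows(domains)

    # peak matrices -> one interval set per assay (merged adjacent windows)
    runs_to_intervals <- function(on, chrom) {
      if (!any(on)) return(NULL)
      rl <- rle(on)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1
      keep <- rl$values
      tibble::tibble(chrom = chrom, start = (starts[keep] - 1) * p$r,
                     end = ends[keep] * p$r)
    }
    peak_names <- sprintf("peak_%03d", seq_len(p$n_peak_features))
    peaks <- lapply(seq_len(p$n_peak_features), function(j) {
      res <- dplyr::bind_rows(lapply(layout$chrom_names, function(chrom) {
        runs_to_intervals(peak_mats[[chrom]][, j], chrom)
      }))
      if (nrow(res) == 0) {
        res <- tibble::tibble(chrom = character(), start = numeric(),
                              end = numeric())
      }
      res
    })
    names(peaks) <- peak_names

    # chromatin states: uniform per-window noise segmentations
    state_alphabet <- paste0("S", seq_len(p$n_states))
    states <- lapply(seq_len(p$n_state_epigenomes), function(e) {
      dplyr::bind_rows(lapply(layout$chrom_names, function(chrom) {
        st <- sample(state_alphabet, n_win, replace = TRUE)
        rl <- rle(st)
        ends <- cumsum(rl$lengths)
        tibble::tibble(chrom = chrom, start = (ends - rl$lengths) * p$r,
                       end = ends * p$r, label = rl$values)
      }))
    })
    names(states) <- sprintf("epigenome_%02d", seq_len(p$n_state_epigenomes))

    # genes and TADs coincide with domains
    eligible <- domains[domains$active & domains$n_windows >= 5, ]
    genes <- tibble::tibble(
      chrom = eligible$chrom,
      strand = sample(c("+", "-"), nrow(eligible), replace = TRUE),
      name = sprintf("gene_%03d", seq_len(nrow(eligible))))
    genes$tss <- ifelse(genes$strand == "+", eligible$start, eligible$end)
    genes$tes <- ifelse(genes$strand == "+", eligible$end, eligible$start)
    genes <- genes[c("chrom", "tss", "tes", "name", "strand")]
    # TADs cover the active domains only: real TAD calls leave inter-domain
    # territory uncovered, and the within/cross contrast needs both sides
    tads <- domains[domains$active, c("chrom", "start", "end")]

    # assembly gaps at a fraction of interior domain boundaries
    boundaries <- domains[domains$start > 0, ]
    pick <- runif(nrow(boundaries)) < p$gap_prob
    gaps <- tibble::tibble(
      chrom = boundaries$chrom[pick],
      start = pmax(0, boundaries$start[pick] - 200),
      end = boundaries$start[pick] + 200)

    # fine-mapped variants: clusters inside active domains, one set per trait
    act <- domains[domains$active, ]
    variants <- purrr::map_dfr(seq_len(p$n_traits), function(t) {
      if (nrow(act) == 0) return(NULL)
      rows <- act[sample.int(nrow(act), min(p$n_domains_per_trait, nrow(act))), ]
      purrr::map_dfr(seq_len(nrow(rows)), function(i) {
        tibble::tibble(
          trait = sprintf("trait_%02d", t), method = "synthetic",
          chrom = rows$chrom[i],
          pos = sort(sample(seq(rows$start[i], rows$end[i] - 1),
                            p$n_variants_per_domain)))
      })
    })

    structure(list(params = p, layout = layout, domains = domains,
                   peaks = peaks, states = states,
                   state_alphabet = state_alphabet, genes = genes,
                   tads = tads, gaps = gaps, variants = variants),
              class = "fixture_world")
  })
}

#' @export
print.fixture_world <- function(x, ...) {
  cat(sprintf(
    "synthetic world: %d chrom(s) x %.0f bases, mode %s (strength %.2f), %d peak assays, %d epigenomes x %d states, %d domains\n",
    length(x$layout$chrom_names), x$layout$chrom_lengths[1],
    x$params$association_mode, x$params$association_strength,
    length(x$peaks), length(x$states), length(x$state_alphabet),
    nrow(x$domains)))
  invisible(x)
}

#' Write a synthetic world to disk in the package's interchange formats
#'
#' Emits `chrom.sizes`, one BED3 per peak assay, one BED4 per epigenome
#' segmentation, `genes.tsv`, `tads.bed`, `gaps.bed`, `variants.tsv` and a
#' JSON manifest recording the parameters, seed and every emitted file, so
#' the world can be regenerated byte-identically.
#'
#' @param world A `fixture_world` from [simulate_world()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest as a list, invisibly; written to `manifest.json`.
#' @export
write_fixture <- function(world, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "states"), showWarnings = FALSE)
  files <- character()
  emit <- function(rel, writer) {
    writer(file.path(out_dir, rel))
    files <<- c(files, rel)
  }
  emit("chrom.sizes", function(f) {
    readr::write_tsv(tibble::tibble(chrom = world$layout$chrom_names,
                                    length = world$layout$chrom_lengths),
                     f, col_names = FALSE, progress = FALSE)
  })
  for (nm in names(world$peaks)) {
    emit(file.path("peaks", paste0(nm, ".bed")),
         function(f) write_bed(world$peaks[[nm]], f))
  }
  for (nm in names(world$states)) {
    emit(file.path("states", paste0(nm, ".bed")),
         function(f) write_bed(world$states[[nm]], f))
  }
  emit("genes.tsv", function(f) readr::write_tsv(world$genes, f, progress = FALSE))
  emit("tads.bed", function(f) write_bed(world$tads, f))
  emit("gaps.bed", function(f) write_bed(world$gaps, f))
  emit("variants.tsv", function(f) readr::write_tsv(world$variants, f, progress = FALSE))
  manifest <- list(
    params = world$params[setdiff(names(world$params), "")],
    state_alphabet = world$state_alphabet,
    files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
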