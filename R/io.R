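#' Read a chromosome-sizes table
#'
#' Reads the standard two-column tab-delimited `chrom.sizes` format
#' (chromosome name, length in bases) into a [genome_layout()].
#'
#' @param path Path to a tab-delimited file with columns name, length.
#' @param window_size Window resolution `r` in bases attached to the layout.
#' @return A `genome_layout` object.
#' @export
read_chrom_sizes <- function(path, window_size = 1000L) {
  tab <- readr::read_tsv(path, col_names = c("chrom", "length"),
                         col_types = readr::cols(chrom = "c", length = "d"),
                         progress = FALSE)
  genome_layout(tab$chrom, tab$length, window_size)
}

#' Read a BED3+ interval file
#'
#' Coordinates are 0-based half-open, as in the BED convention. Columns beyond
#' the requested ones are ignored.
#'
#' @param path Path to a tab-delimited BED file with no header.
#' @param label_col If not `NA`, the 1-based column index carrying a label
#'   (e.g. a chromatin-state name in BED4); stored in a `label` column.
#' @return A tibble with columns `chrom`, `start`, `end` and optionally
#'   `label`, 0-based half-open.
#' @export
read_bed <- function(path, label_col = NA) {
  tab <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  out <- tibble::tibble(
    chrom = tab[[1]],
    start = as.numeric(tab[[2]]),
    end = as.numeric(tab[[3]])
  )
  if (!is.na(label_col)) out$label <- tab[[label_col]]
  if (any(out$start >= out$end)) {
    abort(sprintf("invalid intervals in %s: start must be < end", path))
  }
  out
}

#' Write intervals as BED
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optional `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- intervals[intersect(c("chrom", "start", "end", "label"),
                              names(intervals))]
  readr::write_tsv(cols, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read or write a pair table
#'
#' The on-disk pair format is tab-delimited with columns
#' `chrom, start1, start2, distance` plus either a `label` column (pair sets
#' used for training) or a `score` column (score tables). A header row is
#' written and expected.
#'
#' @param path File path.
#' @param kind Score kind recorded on the returned table (`"learned"`,
#'   `"jaccard"`, `"contact"`, `"percentile"`); ignored for labelled pairs.
#' @return A tibble; score tables carry a `kind` attribute.
#' @export
read_pair_table <- function(path, kind = "learned") {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", .default = "d"), progress = FALSE)
  if ("score" %in% names(tab)) {
    new_score_table(tab, kind = kind)
  } else {
    tab
  }
}

#' @rdname read_pair_table
#' @param table Pair or score table to write.
#' @export
write_pair_table <- function(table, path) {
  tab <- as_tibble(table)
  if ("score" %in% names(tab)) tab$score <- round(tab$score, 4)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read a fine-mapped variant table
#'
#' Tab-delimited with header columns `trait`, `method`, `chrom`, `pos`
#' (0-based base position).
#'
#' @param path File path.
#' @return Tibble with those columns.
#' @export
read_variants <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    trait = "c", method = "c", chrom = "c", pos = "d"), progress = FALSE)
}

#' Persist a feature matrix as dense tab-delimited text
#'
#' The matrix is written with a `window` key column and one column per
#' feature; a sidecar `<path>.labels` file lists the column labels with
#' their source kind (`peak` / `state-onehot`), preserving column order
#' and provenance.
#'
#' @param features Matrix from [featurize()].
#' @param path Output path for the matrix; the sidecar adds `.labels`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  tab <- tibble::as_tibble(as.data.frame(features))
  tab <- dplyr::bind_cols(tibble::tibble(window = rownames(features)), tab)
  readr::write_tsv(tab, path, progress = FALSE)
  readr::write_tsv(
    tibble::tibble(label = colnames(features),
                   source_kind = attr(features, "source_kind") %||%
                     rep(NA_character_, ncol(features))),
    paste0(path, ".labels"), progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @param r Window resolution restored onto the matrix attribute.
#' @export
read_feature_matrix <- function(path, r = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(window = "c",
                                                       .default = "i"),
                         progress = FALSE)
  m <- as.matrix(tab[-1])
  rownames(m) <- tab$window
  labels <- readr::read_tsv(paste0(path, ".labels"),
                            col_types = "cc", progress = FALSE)
  attr(m, "source_kind") <- labels$source_kind
  attr(m, "r") <- r
  m
}

#' Save and load a distance ensemble as text checkpoints
#'
#' Each member is written as one JSON checkpoint embedding its
#' hyperparameters, training metadata (distance, seed, epochs run, training
#' chromosomes) and full-precision weights; `manifest.json` lists the
#' member files with the shared hyperparameters and distance.
#'
#' @param ensemble A `distance_ensemble`.
#' @param dir Checkpoint directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
save_ensemble <- function(ensemble, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(seq_along(ensemble$members), function(i) {
    m <- ensemble$members[[i]]
    f <- sprintf("member_%02d.json", i)
    jsonlite::write_json(
      list(hyperparams = unclass(m$hp), n_features = m$n_features,
           distance = m$distance, seed = m$seed, epochs_run = m$epochs_run,
           train_chroms = m$train_chroms,
           params = lapply(m$params, function(p) {
             if (is.matrix(p)) list(dim = dim(p), values = as.vector(p))
             else list(dim = NULL, values = as.vector(p))
           })),
      file.path(dir, f), auto_unbox = TRUE, digits = NA)
    f
  }, character(1))
  manifest <- list(distance = ensemble$distance,
                   best_hp = unclass(ensemble$best_hp),
                   train_chroms = ensemble$train_chroms,
                   seed = ensemble$seed, members = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  members <- lapply(manifest$members, function(f) {
    ck <- jsonlite::read_json(file.path(dir, f), simplifyVector = TRUE)
    hp <- do.call(siamese_hyperparams, ck$hyperparams)
    m <- build_siamese(hp, ck$n_features, seed = ck$seed)
    m$params <- lapply(ck$params, function(p) {
      d <- unlist(p$dim)
      if (length(d) == 2) matrix(as.numeric(p$values), d[1], d[2])
      else as.numeric(p$values)
    })
    m$distance <- ck$distance
    m$epochs_run <- as.integer(ck$epochs_run)
    m$trained <- TRUE
    m$train_chroms <- as.character(ck$train_chroms)
    m
  })
  structure(list(distance = manifest$distance, members = members,
                 best_hp = do.call(siamese_hyperparams, manifest$best_hp),
                 seed = manifest$seed,
                 train_chroms = as.character(manifest$train_chroms)),
            class = "distance_ensemble")
}

as_tibble <- tibble::as_tibble

new_score_table <- function(tab, kind, r = attr(tab, "r")) {
  out <- as_tibble(tab)
  attr(out, "kind") <- kind
  attr(out, "r") <- r
  class(out) <- unique(c("epair_score_table", class(out)))
  out
}

#' @export
print.epair_score_table <- function(x, ...) {
  cat(sprintf("# pair score table: %d pairs, %d distance(s), kind = %s\n",
              nrow(x), dplyr::n_distinct(x$distance), attr(x, "kind") %||% "?"))
  NextMethod()
}
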