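#' Robust Hausdorff distance from the full data to a sketch
#'
#' For every cell, the minimum distance to any sketch cell is computed; the
#' largest `floor(alpha * n)` of these nearest-sketch distances are discarded
#' and the maximum of the remainder is returned. With `alpha = 0` this is the
#' exact directed Hausdorff distance from the full data to the sketch (the
#' reverse direction is identically zero because the sketch is a subset of
#' the data). The trimming makes the measure robust to a small fraction of
#' outlying cells; 1% trimming is the conventional default.
#'
#' @param data cells-by-dimensions input, see [as_coord_matrix()].
#' @param sketch either a `spherical_sketch` object or an integer vector of
#'   sketch cell indices (1-based).
#' @param alpha trim fraction in `[0, 0.5)`.
#' @param metric distance metric; defaults to the sketch's own metric when a
#'   `spherical_sketch` is supplied, else `"pearson"`.
#' @return a single nonnegative number.
#' @examples
#' x <- matrix(c(0, 1, 2, 10), ncol = 1)
#' robust_hausdorff(x, 1L, alpha = 0.25, metric = "euclidean")  # 2
#' @export
robust_hausdorff <- function(data, sketch, alpha = 0.01, metric = NULL) {
  if (inherits(sketch, "spherical_sketch")) {
    idx <- sketch$centers
    metric <- metric %||% sketch$metric
  } else {
    idx <- as.integer(sketch)
    metric <- metric %||% "pearson"
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha >= 0.5)
    abort("`alpha` must lie in [0, 0.5)")
  X <- as_coord_matrix(data)
  n <- nrow(X)
  if (length(idx) == 0L) abort("the sketch must contain at least one cell")
  if (any(idx < 1L | idx > n)) abort("sketch indices out of range")
  Dc <- cross_distances(X, X[idx, , drop = FALSE], metric)
  mind <- apply(Dc, 1L, min)
  mind[idx] <- 0
  drop_n <- floor(alpha * n)
  kept <- sort(mind, decreasing = TRUE)[(drop_n + 1L):n]
  max(kept)
}

#' Class composition of a sketch versus the full data
#'
#' Reports, per cell class, the absolute counts and fractions in the full
#' data and in the sketch. Classes absent from the sketch are reported with
#' zero counts, not dropped -- rare-population retention is precisely what
#' this table is for.
#'
#' @param labels character vector, one class label per cell.
#' @param sketch a `spherical_sketch` or an integer vector of sketch indices.
#' @return a tibble with columns `class`, `full_count`, `sketch_count`,
#'   `full_fraction`, `sketch_fraction`.
#' @export
composition_report <- function(labels, sketch) {
  idx <- if (inherits(sketch, "spherical_sketch")) sketch$centers else as.integer(sketch)
  labels <- as.character(labels)
  if (any(idx < 1L | idx > length(labels))) abort("sketch indices out of range")
  cls <- sort(unique(labels))
  full_count <- as.integer(table(factor(labels, levels = cls)))
  sketch_count <- as.integer(table(factor(labels[idx], levels = cls)))
  tibble(
    class = cls,
    full_count = full_count,
    sketch_count = sketch_count,
    full_fraction = full_count / sum(full_count),
    sketch_fraction = if (sum(sketch_count) > 0) sketch_count / sum(sketch_count) else 0
  )
}

#' Write a sketch evaluation report
#'
#' Writes the machine-readable evaluation of a sketch: `<prefix>.eval.json`
#' with the robust Hausdorff distance, covering radius, sketch size, metric,
#' trim fraction and seed, and (when labels are given)
#' `<prefix>.composition.tsv` with the class composition table.
#'
#' @param data the full embedding the sketch was computed from.
#' @param sketch a `spherical_sketch`.
#' @param prefix output path prefix.
#' @param labels optional per-cell class labels.
#' @param alpha trim fraction for the robust Hausdorff distance.
#' @return invisibly, the list written as JSON.
#' @export
write_sketch_report <- function(data, sketch, prefix, labels = NULL, alpha = 0.01) {
  stopifnot(inherits(sketch, "spherical_sketch"))
  hd <- robust_hausdorff(data, sketch, alpha = alpha)
  info <- list(
    hausdorff = hd,
    alpha = alpha,
    radius = sketch$radius,
    k = length(sketch$centers),
    metric = sketch$metric,
    seed = sketch$seed
  )
  jsonlite::write_json(info, paste0(prefix, ".eval.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(labels)) {
    readr::write_tsv(composition_report(labels, sketch),
                     paste0(prefix, ".composition.tsv"))
  }
  invisible(info)
}
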