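#' Coerce a cells-by-dimensions input to a coordinate matrix
#'
#' User-facing functions accept either a numeric matrix (cells as rows) or a
#' data frame such as the tibbles returned by [simulate_mixture()] or
#' [read_cells()]. For data frames, all numeric columns are taken as
#' coordinates; the metadata columns `cell_id`, `label` and `is_outlier` are
#' ignored. Cell identifiers are taken from a `cell_id` column, else from row
#' names, else synthesized as `cell_0 ... cell_{n-1}`.
#'
#' @param data matrix or data frame, one row per cell.
#' @return numeric matrix with unique row names (the cell ids).
#' @export
as_coord_matrix <- function(data) {
  if (is.matrix(data)) {
    x <- data
    if (!is.numeric(x)) abort("coordinate matrix must be numeric")
    ids <- rownames(x)
  } else if (is.data.frame(data)) {
    meta <- intersect(c("cell_id", "label", "is_outlier"), names(data))
    keep <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], meta)
    if (length(keep) == 0L) abort("no numeric coordinate columns found")
    x <- as.matrix(data[keep])
    ids <- if ("cell_id" %in% names(data)) as.character(data$cell_id) else rownames(data)
    if (!is.null(ids) && all(ids == as.character(seq_len(nrow(x))))) ids <- NULL
  } else {
    abort("`data` must be a numeric matrix or a data frame")
  }
  if (nrow(x) < 1L || ncol(x) < 1L) abort("need at least one cell and one dimension")
  if (!all(is.finite(x))) abort("coordinates contain non-finite values")
  if (is.null(ids)) ids <- paste0("cell_", seq_len(nrow(x)) - 1L)
  if (anyDuplicated(ids)) abort("cell ids must be unique")
  rownames(x) <- ids
  x
}

metric_names <- c("euclidean", "manhattan", "cosine", "pearson")

check_metric_rows <- function(x, metric) {
  ids <- rownames(x)
  if (metric == "cosine") {
    nrm <- sqrt(rowSums(x^2))
    bad <- which(nrm == 0)
    if (length(bad))
      abort(paste0("cosine distance undefined for zero-norm cell(s): ",
                   paste(ids[bad], collapse = ", ")))
  }
  if (metric == "pearson") {
    if (ncol(x) < 2L)
      abort("pearson distance undefined for 1-dimensional coordinates")
    v <- apply(x, 1L, stats::var)
    bad <- which(v == 0)
    if (length(bad))
      abort(paste0("pearson distance undefined for zero-variance cell(s): ",
                   paste(ids[bad], collapse = ", ")))
  }
  invisible(TRUE)
}

#' Pairwise distances between cells
#'
#' Computes the full symmetric n x n distance matrix under one of the four
#' supported dissimilarities: `euclidean`, `manhattan`, `cosine`
#' (1 - cosine similarity) and `pearson` (1 - Pearson correlation of the two
#' coordinate rows). Cosine and Pearson are not metrics (no triangle
#' inequality); none of the covering machinery relies on it. The diagonal is
#' exactly zero and boundary ties are kept exact (no epsilon slack): a cell at
#' distance exactly `r` from a center belongs to the closed ball of radius `r`.
#'
#' @param data cells-by-dimensions input, see [as_coord_matrix()].
#' @param metric one of `"euclidean"`, `"manhattan"`, `"cosine"`, `"pearson"`.
#' @return symmetric numeric matrix with zero diagonal, dimnames = cell ids.
#' @examples
#' x <- rbind(c(0, 0), c(3, 4))
#' pairwise_distances(x, "euclidean")[1, 2]  # 5
#' @export
pairwise_distances <- function(data, metric = c("pearson", "euclidean", "manhattan", "cosine")) {
  metric <- match.arg(metric, metric_names)
  x <- as_coord_matrix(data)
  check_metric_rows(x, metric)
  D <- switch(metric,
    euclidean = cpp_finish_euclidean(tcrossprod(x), rowSums(x^2)),
    manhattan = cpp_finish_dist(as.matrix(stats::dist(x, method = "manhattan")),
                                take_sqrt = FALSE),
    cosine = {
      xn <- x / sqrt(rowSums(x^2))
      cpp_finish_dist(1 - tcrossprod(xn), take_sqrt = FALSE)
    },
    pearson = cpp_finish_dist(1 - stats::cor(t(x)), take_sqrt = FALSE)
  )
  dimnames(D) <- list(rownames(x), rownames(x))
  D
}

#' Distances from every cell to a reference subset
#'
#' Rectangular companion of [pairwise_distances()]: distances from each row of
#' `data` to each row of `ref` under the same metric definitions.
#'
#' @inheritParams pairwise_distances
#' @param ref reference cells (matrix or data frame, same dimensionality).
#' @return numeric matrix, `nrow(data)` x `nrow(ref)`.
#' @export
cross_distances <- function(data, ref, metric = c("pearson", "euclidean", "manhattan", "cosine")) {
  metric <- match.arg(metric, metric_names)
  x <- as_coord_matrix(data)
  y <- as_coord_matrix(ref)
  if (ncol(x) != ncol(y)) abort("`data` and `ref` must have the same dimensionality")
  check_metric_rows(x, metric)
  check_metric_rows(y, metric)
  D <- switch(metric,
    euclidean = {
      d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
      sqrt(pmax(d2, 0))
    },
    manhattan = {
      out <- matrix(0, nrow(x), nrow(y))
      for (j in seq_len(nrow(y)))
        out[, j] <- rowSums(abs(x - rep(y[j, ], each = nrow(x))))
      out
    },
    cosine = {
      xn <- x / sqrt(rowSums(x^2))
      yn <- y / sqrt(rowSums(y^2))
      pmax(1 - tcrossprod(xn, yn), 0)
    },
    pearson = {
      pmax(1 - stats::cor(t(x), t(y)), 0)
    }
  )
  dimnames(D) <- list(rownames(x), rownames(y))
  D
}

#' Members of a closed ball around a cell
#'
#' Given one row of a distance matrix, returns the indices of all cells within
#' `radius` of the row's cell, boundary included. With `radius = 0` the ball
#' still contains the center (distance 0) and any exact duplicates.
#'
#' @param dist_row numeric vector of distances from one cell to all cells.
#' @param radius nonnegative ball radius.
#' @return integer vector of 1-based cell indices.
#' @export
ball_members <- function(dist_row, radius) {
  if (!is.numeric(radius) || length(radius) != 1L || is.na(radius) || radius < 0)
    abort("`radius` must be a single nonnegative number")
  which(dist_row <= radius)
}
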