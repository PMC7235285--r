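#' Simulate a PCA-like embedding as a Gaussian mixture
#'
#' Generates an `n_cells` x `n_dims` embedding from a mixture of isotropic
#' Gaussian components with very unequal abundances, emulating the geometry a
#' dimensionality-reduced scRNA-seq dataset presents to a sketching
#' algorithm: a few dominant populations plus rare ones. By default five
#' components are used, four equally abundant and one rare at 1% abundance,
#' in 10 dimensions, with component means drawn (from the same seeded RNG) as
#' `N(0, separation^2)` vectors and unit within-component noise; with
#' `separation = 5` and `n_dims = 10` the populations are well separated
#' relative to their spread, as distinct cell types are after PCA.
#'
#' Component labels are reported either as component names
#' (`comp_1 ... comp_K`) or, with `labels_as = "time_point"`, as synthetic
#' collection time points `t0/t24/t48/t72` cycling over components --
#' mirroring a differentiation time course sampled every 24 h between 0 and
#' 72 h.
#'
#' @param n_cells number of cells.
#' @param n_dims embedding dimensionality.
#' @param n_components number of mixture components (ignored when `means`
#'   is supplied).
#' @param rare_weight abundance of the last ("rare") component; the remaining
#'   weight is split evenly (ignored when `weights` is supplied).
#' @param separation standard deviation of the component means around the
#'   origin, in units of the within-component noise.
#' @param sd isotropic within-component standard deviation; scalar or one
#'   value per component.
#' @param means optional `n_components` x `n_dims` matrix of component means.
#' @param weights optional positive abundance weights (normalized to sum 1).
#' @param labels_as `"component"` or `"time_point"`.
#' @param seed optional integer seed; identical seeds give bitwise-identical
#'   output.
#' @return a tibble with columns `cell_id`, `label`, `dim_1..dim_d`, plus
#'   attributes `component` (integer assignment per cell), `component_counts`
#'   (realized per-component counts), `means`, `sds`, `weights`.
#' @examples
#' cells <- simulate_mixture(n_cells = 500, seed = 1)
#' attr(cells, "component_counts")
#' @export
simulate_mixture <- function(n_cells, n_dims = 10, n_components = 5,
                             rare_weight = 0.01, separation = 5, sd = 1,
                             means = NULL, weights = NULL,
                             labels_as = c("component", "time_point"),
                             seed = NULL) {
  labels_as <- match.arg(labels_as)
  if (!is.null(seed)) set.seed(seed)
  if (n_cells < 1L || n_dims < 1L) abort("need at least one cell and one dimension")

  if (is.null(means)) {
    if (n_components < 1L) abort("need at least one component")
    means <- matrix(rnorm(n_components * n_dims, sd = separation),
                    nrow = n_components)
  } else {
    means <- as.matrix(means)
    if (ncol(means) != n_dims) abort("`means` must have `n_dims` columns")
    n_components <- nrow(means)
  }
  if (is.null(weights)) {
    weights <- if (n_components == 1L) 1
               else c(rep((1 - rare_weight) / (n_components - 1), n_components - 1),
                      rare_weight)
  }
  if (length(weights) != n_components || any(!is.finite(weights)) || any(weights <= 0))
    abort("`weights` must be positive and finite, one per component")
  weights <- weights / sum(weights)
  sds <- rep_len(sd, n_components)
  if (any(sds < 0)) abort("`sd` must be nonnegative")

  comp <- sample.int(n_components, n_cells, replace = TRUE, prob = weights)
  noise <- matrix(rnorm(n_cells * n_dims), nrow = n_cells)
  X <- means[comp, , drop = FALSE] + noise * sds[comp]
  colnames(X) <- paste0("dim_", seq_len(n_dims))

  lab <- component_labels(comp, n_components, labels_as)
  out <- tibble(
    cell_id = paste0("cell_", seq_len(n_cells) - 1L),
    label = lab
  )
  out <- dplyr::bind_cols(out, as_tibble(X))
  attr(out, "component") <- comp
  attr(out, "component_counts") <- as.integer(table(factor(comp, levels = seq_len(n_components))))
  attr(out, "means") <- means
  attr(out, "sds") <- sds
  attr(out, "weights") <- weights
  out
}

component_labels <- function(comp, n_components, labels_as) {
  if (labels_as == "time_point") {
    tp <- c("t0", "t24", "t48", "t72")
    tp[((seq_len(n_components) - 1L) %% 4L) + 1L][comp]
  } else {
    paste0("comp_", comp)
  }
}

#' Simulate a time-course embedding with planted label outliers
#'
#' Same mixture as [simulate_mixture()] with time-point labels, but
#' `n_outliers` randomly chosen cells are relabeled with the time point of a
#' *different* component: their coordinates come from one transcriptomic
#' state while their recorded collection time point disagrees with it. Such
#' cells sit deep inside a foreign cluster, so a fairness-constrained sketch
#' that must pick a minimum number of cells per time point can meet each
#' quota with well-placed cells instead, implicitly discouraging the
#' selection of outliers as centers.
#'
#' @inheritParams simulate_mixture
#' @param n_outliers number of planted label outliers (less than `n_cells`).
#' @return as [simulate_mixture()], plus a logical `is_outlier` column and an
#'   `outliers` attribute with the planted indices.
#' @export
simulate_outlier_timepoints <- function(n_cells, n_dims = 10, n_components = 4,
                                        rare_weight = 0.01, separation = 5,
                                        sd = 1, means = NULL, weights = NULL,
                                        n_outliers = 0, seed = NULL) {
  if (n_outliers >= n_cells) abort("`n_outliers` must be less than `n_cells`")
  out <- simulate_mixture(n_cells, n_dims, n_components, rare_weight,
                          separation, sd, means, weights,
                          labels_as = "time_point", seed = seed)
  comp <- attr(out, "component")
  n_components <- nrow(attr(out, "means"))
  out$is_outlier <- FALSE
  planted <- integer(0)
  if (n_outliers > 0) {
    if (n_components < 2L)
      abort("planting outliers needs at least two components")
    planted <- sample.int(n_cells, n_outliers)
    for (i in planted) {
      foreign <- sample(setdiff(seq_len(n_components), comp[i]), 1L)
      out$label[i] <- component_labels(foreign, n_components, "time_point")
      # guard: the foreign time point must actually differ (components can
      # share a time point when n_components > 4)
      truelab <- component_labels(comp[i], n_components, "time_point")
      if (out$label[i] == truelab) {
        alt <- setdiff(c("t0", "t24", "t48", "t72")[seq_len(min(n_components, 4L))], truelab)
        out$label[i] <- alt[sample.int(length(alt), 1L)]
      }
      out$is_outlier[i] <- TRUE
    }
  }
  attr(out, "outliers") <- sort(planted)
  out
}
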