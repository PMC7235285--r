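#' Spherical sketch of a cell embedding
#'
#' Selects at most `size` cells (the sketch) so that closed balls of minimal
#' radius centered at the selected cells cover every cell. The minimal radius
#' is found by a thresholding search: candidate radii are tested for
#' feasibility ("does a greedy ball cover at this radius use at most `size`
#' centers?") and the search homes in on the smallest feasible one. In
#' `ladder` mode the candidates are the sorted distinct pairwise distances
#' (including 0) and the search is a binary search over that ladder; in
#' `bisect` mode the search bisects the continuous interval `[0, max
#' distance]` to relative tolerance `radius_tol`, which avoids sorting the
#' full ladder on larger inputs. Greedy feasibility is not provably monotone
#' along the ladder; the binary search treats it as monotone (as any
#' thresholding scheme must), verifies feasibility at the returned radius and
#' then tightens it with a downward linear scan over up to 32 ladder
#' neighbors.
#'
#' For large datasets, `presample` switches on the hybrid strategy: a fast
#' grid presampling (see [grid_presample()]) reduces the data to `presample`
#' representatives, the radius search runs on the representatives only, and
#' every original cell is then assigned to its nearest selected center. The
#' reported covering radius is always measured on the full data. For grid
#' side length `s`, the hybrid radius exceeds the direct radius by at most
#' `s * sqrt(d)` under the euclidean metric, since each cell shares a cube
#' with its representative.
#'
#' @param data cells-by-dimensions input, see [as_coord_matrix()].
#' @param size sketch size budget: a positive integer `k`, or a fraction in
#'   (0, 1) resolved to `ceiling(size * n)`.
#' @param metric distance metric; default `"pearson"` (correlation distance),
#'   the default used throughout; `"euclidean"`, `"manhattan"` and `"cosine"`
#'   are also supported.
#' @param engine greedy set cover engine, `"dfg"` (disk-friendly greedy,
#'   default) or `"exact"`; see [greedy_cover()].
#' @param p DFG bucket base (> 1), default 1.05.
#' @param fairness optional [fairness_spec()]; quotas must sum to at most the
#'   resolved sketch size.
#' @param radius_mode `"auto"` (ladder for n <= 20,000, else bisect),
#'   `"ladder"` or `"bisect"`.
#' @param radius_tol relative tolerance of the bisect search (default 1e-3).
#' @param presample optional integer: run the hybrid pipeline with this many
#'   grid representatives (must be >= the sketch size).
#' @param grid_side optional numeric: hybrid with a fixed grid side length
#'   instead of a target representative count.
#' @param pad_to_size if TRUE and the greedy cover uses fewer than `size`
#'   centers, pad the sketch to exactly `size` cells by farthest-point
#'   additions. Off by default: the objective is coverage, not an exact count.
#' @param seed optional integer seed; all randomness (greedy tie-breaking,
#'   grid representative choice) flows from R's RNG.
#' @return an object of class `spherical_sketch`; see [tidy.spherical_sketch()]
#'   and [glance.spherical_sketch()].
#' @examples
#' x <- matrix(c(0, 1, 2, 3, 4), ncol = 1)
#' s <- sketch_spherical(x, size = 1, metric = "euclidean", seed = 1)
#' s$radius  # 2: one ball of radius 2 around x = 2 covers 0..4
#' @export
sketch_spherical <- function(data, size, metric = c("pearson", "euclidean", "manhattan", "cosine"),
                             engine = c("dfg", "exact"), p = 1.05,
                             fairness = NULL,
                             radius_mode = c("auto", "ladder", "bisect"),
                             radius_tol = 1e-3,
                             presample = NULL, grid_side = NULL,
                             pad_to_size = FALSE, seed = NULL) {
  metric <- match.arg(metric, metric_names)
  engine <- match.arg(engine)
  radius_mode <- match.arg(radius_mode)
  X <- as_coord_matrix(data)
  n <- nrow(X)
  k <- resolve_size(size, n)
  if (!is.null(fairness)) {
    stopifnot(inherits(fairness, "fairness_spec"))
    if (length(fairness$labels) != n)
      abort("fairness labels must have one entry per cell")
    if (sum(fairness$quotas) > k)
      abort("fairness quotas sum to more than the sketch size")
  }
  if (!is.null(seed)) set.seed(seed)
  timings <- c(grid = 0, distances = 0, set_cover = 0)

  hybrid <- !is.null(presample) || !is.null(grid_side)
  if (hybrid) {
    if (!is.null(presample) && presample < k)
      abort("`presample` must be at least the sketch size")
    t0 <- proc.time()[["elapsed"]]
    reps <- grid_presample_matrix(X, target_size = presample, side_length = grid_side)
    timings[["grid"]] <- proc.time()[["elapsed"]] - t0
    sub_fair <- subset_fairness(fairness, reps)
    Xr <- X[reps, , drop = FALSE]
  } else {
    if (n > 20000L)
      abort("direct sketching needs the full n x n distance matrix; use `presample` for inputs this large")
    reps <- seq_len(n)
    sub_fair <- fairness
    Xr <- X
  }

  t0 <- proc.time()[["elapsed"]]
  D <- pairwise_distances(Xr, metric)
  timings[["distances"]] <- proc.time()[["elapsed"]] - t0

  t0 <- proc.time()[["elapsed"]]
  found <- radius_search(D, k, engine = engine, p = p, fairness = sub_fair,
                         mode = radius_mode, tol = radius_tol)
  centers <- reps[found$selected]
  timings[["set_cover"]] <- proc.time()[["elapsed"]] - t0

  # assign every original cell to its nearest selected center; the covering
  # radius is measured on the full data
  Dc <- if (hybrid) cross_distances(X, X[centers, , drop = FALSE], metric)
        else D[, found$selected, drop = FALSE]
  if (pad_to_size && length(centers) < k) {
    while (length(centers) < k) {
      dmin <- do.call(pmin, c(as.data.frame(Dc), list(numeric(n) + Inf)))
      cand <- setdiff(which(dmin == max(dmin)), centers)
      if (length(cand) == 0L) break
      add <- cand[sample.int(length(cand), 1L)]
      centers <- c(centers, add)
      Dc <- cbind(Dc, cross_distances(X, X[add, , drop = FALSE], metric))
    }
  }
  j <- max.col(-Dc, ties.method = "first")
  assignment <- centers[j]
  dist_to_center <- Dc[cbind(seq_len(n), j)]
  # a center always represents itself (relevant only for exact duplicates)
  assignment[centers] <- centers
  dist_to_center[centers] <- 0

  structure(list(
    centers = centers,
    radius = max(dist_to_center),
    radius_threshold = found$threshold,
    prev_infeasible = found$prev_infeasible,
    assignment = assignment,
    dist_to_center = dist_to_center,
    metric = metric,
    engine = engine,
    p = p,
    k_requested = k,
    n = n,
    n_dims = ncol(X),
    cell_ids = rownames(X),
    coords = X,
    fairness = fairness,
    radius_mode = found$mode,
    grid = if (hybrid) list(side_length = attr(reps, "side_length"),
                            n_representatives = length(reps),
                            representatives = as.integer(reps)) else NULL,
    seed = seed,
    timings = timings
  ), class = "spherical_sketch")
}

resolve_size <- function(size, n) {
  if (!is.numeric(size) || length(size) != 1L || is.na(size) || size <= 0)
    abort("`size` must be a positive number")
  k <- if (size < 1) as.integer(ceiling(size * n)) else as.integer(size)
  if (k < 1L || k > n) abort("sketch size must lie in 1..n")
  k
}

subset_fairness <- function(fairness, reps) {
  if (is.null(fairness)) return(NULL)
  labs <- fairness$labels[reps]
  tryCatch(
    fairness_spec(labs, fairness$quotas),
    error = function(e) abort(paste0(
      "fairness quotas are not satisfiable on the grid representatives (",
      conditionMessage(e), "); increase `presample`"))
  )
}

# thresholding search for the smallest feasible radius.
# Returns list(threshold, selected, mode); `selected` is the greedy ball
# cover computed at the returned threshold.
radius_search <- function(D, k, engine, p, fairness, mode = "auto", tol = 1e-3) {
  n <- nrow(D)
  if (mode == "auto") mode <- if (n <= 20000L) "ladder" else "bisect"
  cache <- new.env(parent = emptyenv())
  run_at <- function(r) {
    key <- sprintf("%.17g", r)
    if (!is.null(cache[[key]])) return(cache[[key]])
    sel <- greedy_cover_dist(D, r, engine = engine, p = p,
                             fairness = fairness, max_size = k)
    res <- list(ok = !isTRUE(attr(sel, "infeasible")) && length(sel) <= k,
                sel = sel)
    cache[[key]] <- res
    res
  }
  feasible <- function(r) run_at(r)$ok

  if (mode == "ladder") {
    ladder <- sort(unique(c(0, D[upper.tri(D)])))
    lo <- 1L
    hi <- length(ladder)
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (feasible(ladder[mid])) hi <- mid else lo <- mid + 1L
    }
    idx <- hi
    # guards against non-monotone greedy feasibility
    while (idx < length(ladder) && !feasible(ladder[idx])) idx <- idx + 1L
    steps <- 0L
    while (idx > 1L && steps < 32L && feasible(ladder[idx - 1L])) {
      idx <- idx - 1L
      steps <- steps + 1L
    }
    r <- ladder[idx]
    # frontier trace: was the preceding candidate radius tested infeasible?
    prev_infeasible <- if (idx == 1L) NA else !run_at(ladder[idx - 1L])$ok
  } else {
    maxd <- max(D)
    if (feasible(0)) {
      r <- 0
      prev_infeasible <- NA
    } else {
      lo <- 0
      hi <- maxd
      while (hi - lo > tol * hi) {
        mid <- (lo + hi) / 2
        if (feasible(mid)) hi <- mid else lo <- mid
      }
      r <- hi
      prev_infeasible <- TRUE  # lo >= r * (1 - tol) tested infeasible
    }
  }
  list(threshold = r, selected = as.integer(run_at(r)$sel), mode = mode,
       prev_infeasible = prev_infeasible)
}

#' Grid presampling of an embedding
#'
#' Partitions the coordinate space into axis-aligned hypercubes of side `s`
#' and keeps one cell, chosen uniformly at random, per occupied cube. This is
#' the fast reduction stage of the hybrid pipeline: every original cell lies
#' within `s * sqrt(d)` (euclidean) of its cube's representative. Either the
#' side length is given directly, or a target representative count `m` is
#' given and the side length is found by bisection so that the number of
#' occupied cubes falls within `[m, 1.1 m]`, falling back to the closest
#' achievable count (e.g. when duplicates cap the number of occupied cubes).
#'
#' @inheritParams sketch_spherical
#' @param target_size desired number of representatives `m` (at most `n`).
#' @param side_length hypercube side `s` (> 0); give exactly one of
#'   `target_size` and `side_length`.
#' @param seed optional integer seed for the per-cube choice.
#' @return integer vector of representative cell indices (sorted), with
#'   attributes `side_length` and `n_cubes`.
#' @export
grid_presample <- function(data, target_size = NULL, side_length = NULL, seed = NULL) {
  X <- as_coord_matrix(data)
  if (!is.null(seed)) set.seed(seed)
  grid_presample_matrix(X, target_size, side_length)
}

grid_presample_matrix <- function(X, target_size = NULL, side_length = NULL) {
  if (is.null(target_size) == is.null(side_length))
    abort("give exactly one of `target_size` and `side_length`")
  n <- nrow(X)
  mins <- apply(X, 2L, min)
  span <- max(apply(X, 2L, max) - mins, 0)

  cube_keys <- function(s) {
    idx <- floor(sweep(X, 2L, mins, "-") / s)
    do.call(paste, c(as.data.frame(idx), sep = "_"))
  }

  if (!is.null(side_length)) {
    if (side_length <= 0) abort("`side_length` must be positive")
    s <- side_length
  } else {
    m <- as.integer(target_size)
    if (m > n) abort("`target_size` must be at most the number of cells")
    if (m < 1L) abort("`target_size` must be positive")
    n_distinct <- nrow(unique(X))
    if (span == 0) {
      s <- 1
    } else if (m >= n_distinct) {
      # every distinct point in its own cube
      s <- smallest_separating_side(X, span)
    } else {
      lo <- smallest_separating_side(X, span)  # occupancy = n_distinct
      hi <- span * (1 + 1e-9)                  # occupancy = 1
      s <- hi
      best <- c(s = hi, gap = Inf)
      for (iter in 1:60) {
        mid <- (lo + hi) / 2
        occ <- length(unique(cube_keys(mid)))
        gap <- if (occ >= m) occ - m else m - occ + 0.5  # prefer occ >= m
        if (gap < best[["gap"]]) best <- c(s = mid, gap = gap)
        if (occ >= m && occ <= ceiling(1.1 * m)) {
          best <- c(s = mid, gap = 0)
          break
        }
        if (occ > m) lo <- mid else hi <- mid
      }
      s <- best[["s"]]
    }
  }

  key <- cube_keys(s)
  groups <- split(seq_len(n), key)
  reps <- vapply(groups, function(g) {
    if (length(g) == 1L) g else g[sample.int(length(g), 1L)]
  }, integer(1))
  reps <- sort(unname(reps))
  attr(reps, "side_length") <- s
  attr(reps, "n_cubes") <- length(groups)
  reps
}

# a side small enough that no two distinct points share a cube: half the
# smallest positive coordinate difference in any dimension
smallest_separating_side <- function(X, span) {
  g <- Inf
  for (j in seq_len(ncol(X))) {
    v <- sort(unique(X[, j]))
    if (length(v) > 1L) g <- min(g, min(diff(v)))
  }
  if (!is.finite(g)) return(max(span, 1))
  g / 2
}

#' @export
print.spherical_sketch <- function(x, ...) {
  cat("Spherical sketch\n")
  cat(sprintf("  cells: %d  dims: %d  metric: %s  engine: %s\n",
              x$n, x$n_dims, x$metric, x$engine))
  cat(sprintf("  centers: %d (budget %d)\n", length(x$centers), x$k_requested))
  cat(sprintf("  covering radius: %.6g (threshold %.6g, %s search)\n",
              x$radius, x$radius_threshold, x$radius_mode))
  if (!is.null(x$grid))
    cat(sprintf("  hybrid: %d grid representatives, side %.4g\n",
                x$grid$n_representatives, x$grid$side_length))
  if (!is.null(x$fairness))
    cat(sprintf("  fairness: quotas on %d class(es)\n", length(x$fairness$quotas)))
  invisible(x)
}

#' Tidy a spherical sketch
#'
#' One row per selected center, in selection order, with the size of the cell
#' population each center represents (cells assigned to it) and the largest
#' distance within that sphere.
#'
#' @param x a `spherical_sketch`.
#' @param ... unused.
#' @return a tibble with columns `rank`, `cell`, `cell_id`, `n_assigned`,
#'   `max_dist`.
#' @export
tidy.spherical_sketch <- function(x, ...) {
  sizes <- table(factor(x$assignment, levels = x$centers))
  maxd <- vapply(x$centers, function(cc) {
    d <- x$dist_to_center[x$assignment == cc]
    if (length(d)) max(d) else 0
  }, numeric(1))
  tibble(
    rank = seq_along(x$centers),
    cell = as.integer(x$centers),
    cell_id = x$cell_ids[x$centers],
    n_assigned = as.integer(sizes),
    max_dist = maxd
  )
}

#' One-row summary of a spherical sketch
#'
#' @param x a `spherical_sketch`.
#' @param ... unused.
#' @export
glance.spherical_sketch <- function(x, ...) {
  tibble(
    n = x$n, n_dims = x$n_dims,
    k_requested = x$k_requested, n_centers = length(x$centers),
    radius = x$radius, radius_threshold = x$radius_threshold,
    metric = x$metric, engine = x$engine,
    hybrid = !is.null(x$grid)
  )
}

#' Plot a spherical sketch
#'
#' Scatter of the first two embedding dimensions with selected centers
#' highlighted; a quick visual check that the sketch spans the occupied space
#' rather than tracking population density.
#'
#' @param object a `spherical_sketch`.
#' @param dims which two coordinate dimensions to show.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.spherical_sketch <- function(object, dims = c(1, 2), ...) {
  d <- object$coords
  if (ncol(d) == 1L) d <- cbind(d, 0)
  dims <- pmin(dims, ncol(d))
  df <- tibble(
    x = d[, dims[1]], y = d[, dims[2]],
    center = seq_len(object$n) %in% object$centers
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(data = df[!df$center, ], colour = "grey70", size = 0.8) +
    ggplot2::geom_point(data = df[df$center, ], colour = "#b2182b", size = 1.8) +
    ggplot2::labs(
      x = paste0("dim ", dims[1]), y = paste0("dim ", dims[2]),
      title = sprintf("Spherical sketch: %d centers, radius %.3g (%s)",
                      length(object$centers), object$radius, object$metric)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
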