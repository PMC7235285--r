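#' Fixed-radius set cover instance
#'
#' Bundles a collection of candidate sets over a universe of cells. For
#' spherical sketching, candidate set `i` is the closed ball of `radius`
#' around cell `i` (see [ball_cover_instance()]), but arbitrary set systems
#' are accepted so the greedy engines can be exercised and benchmarked on
#' classical set cover inputs. A cover must exist: the union of all sets has
#' to equal the universe.
#'
#' @param sets list of integer vectors, 1-based element indices.
#' @param universe_size number of elements to cover.
#' @param radius optional radius annotation (for ball instances).
#' @return object of class `cover_instance`.
#' @export
cover_instance <- function(sets, universe_size, radius = NA_real_) {
  if (!is.list(sets) || length(sets) < 1L) abort("`sets` must be a nonempty list")
  sets <- lapply(sets, function(s) as.integer(sort(unique(s))))
  all_el <- unique(unlist(sets, use.names = FALSE))
  if (length(all_el) && (min(all_el) < 1L || max(all_el) > universe_size))
    abort("set elements must lie in 1..universe_size")
  if (length(all_el) != universe_size)
    abort("the union of all sets must equal the universe (a cover must exist)")
  structure(
    list(sets = sets, universe_size = as.integer(universe_size), radius = radius),
    class = "cover_instance"
  )
}

#' Ball cover instance from a distance matrix
#'
#' Builds the set system of closed balls at a fixed radius: set `i` contains
#' every cell within `radius` of cell `i`. Every cell covers itself (distance
#' 0), so a cover always exists.
#'
#' @param D symmetric distance matrix, e.g. from [pairwise_distances()].
#' @param radius nonnegative ball radius.
#' @export
ball_cover_instance <- function(D, radius) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) abort("`D` must be a square matrix")
  if (radius < 0) abort("`radius` must be nonnegative")
  sets <- lapply(seq_len(nrow(D)), function(i) ball_members(D[i, ], radius))
  cover_instance(sets, nrow(D), radius = radius)
}

#' Fairness quotas over cell classes
#'
#' A fairness specification requires the sketch to contain at least `quotas[j]`
#' centers of class `j` (for instance, a collection time point in a time-series
#' experiment). Quotas are satisfied structurally: each class carries a demand
#' of `quotas[j]` units, an unselected candidate of class `j` counts one extra
#' unit of residual coverage while demand remains, and selecting it consumes
#' one unit, so the greedy cannot terminate before every quota is met. With
#' all quotas zero the engine output is bit-identical to the unconstrained
#' run at the same seed.
#'
#' @param labels character vector, one class label per cell / candidate set.
#' @param quotas either a named integer vector (class -> minimum count) or a
#'   single unnamed integer applied to every class present in `labels`.
#' @return object of class `fairness_spec`.
#' @examples
#' fairness_spec(rep(c("t0", "t24", "t48", "t72"), 25), quotas = 4)
#' @export
fairness_spec <- function(labels, quotas) {
  labels <- as.character(labels)
  if (length(quotas) == 1L && is.null(names(quotas))) {
    quotas <- stats::setNames(rep(as.integer(quotas), length(unique(labels))),
                              sort(unique(labels)))
  }
  quotas <- stats::setNames(as.integer(quotas), names(quotas))
  if (is.null(names(quotas)) || any(!nzchar(names(quotas))))
    abort("`quotas` must be named by class (or be a single unnamed integer)")
  if (any(quotas < 0)) abort("quotas must be nonnegative")
  missing_cls <- setdiff(names(quotas), labels)
  if (length(missing_cls))
    abort(paste0("quota class(es) absent from labels: ",
                 paste(missing_cls, collapse = ", ")))
  tab <- table(labels)
  short <- names(quotas)[quotas > as.integer(tab[names(quotas)])]
  if (length(short))
    abort(paste0("unsatisfiable quota for class(es) ",
                 paste(short, collapse = ", "),
                 ": quota exceeds the number of cells of that class"))
  structure(list(labels = labels, quotas = quotas), class = "fairness_spec")
}

# -> list(set_class = 0-based ints, demand = per-class ints), or empty vectors
fairness_to_cpp <- function(fairness, n_sets) {
  if (is.null(fairness)) {
    return(list(set_class = integer(0), demand = integer(0)))
  }
  stopifnot(inherits(fairness, "fairness_spec"))
  if (length(fairness$labels) != n_sets)
    abort("fairness labels must have one entry per candidate set / cell")
  cls <- sort(unique(fairness$labels))
  demand <- integer(length(cls))
  names(demand) <- cls
  demand[names(fairness$quotas)] <- fairness$quotas
  list(set_class = match(fairness$labels, cls) - 1L, demand = unname(demand))
}

#' Greedy minimum set cover
#'
#' Selects candidate sets until the universe is covered. The `exact` engine is
#' the textbook greedy: each step takes a set covering the largest number of
#' still-uncovered elements, breaking ties between equal residual sizes
#' uniformly at random (the only randomness in the whole pipeline). The `dfg`
#' engine is the disk-friendly greedy: sets are grouped into geometric buckets
#' by residual size (bucket `k` holds sizes in `[p^k, p^{k+1})`), buckets are
#' processed from the largest downward in a seeded random order, and each
#' popped set has its residual recomputed lazily -- it is selected if it still
#' belongs to the current bucket and demoted otherwise. DFG trades at most a
#' factor `p` of the greedy's `(1 + ln n)` approximation guarantee for
#' sequential access; as `p` approaches 1 it degenerates to the exact greedy.
#'
#' @param instance a [cover_instance()].
#' @param engine `"exact"` or `"dfg"`.
#' @param p DFG bucket base, must be > 1. Default 1.05 (near-greedy quality).
#' @param fairness optional [fairness_spec()] with one label per candidate set.
#' @param seed optional integer; if given, `set.seed(seed)` is applied first.
#' @param max_size optional early-exit budget: if more than `max_size` sets
#'   would be needed, selection stops and the result carries
#'   `attr(, "infeasible") = TRUE`.
#' @return integer vector of selected set indices in selection order, with
#'   attribute `infeasible`.
#' @examples
#' inst <- cover_instance(list(c(1, 2, 3), c(3, 4), c(4, 5)), 5)
#' greedy_cover(inst, engine = "exact", seed = 1)
#' @export
greedy_cover <- function(instance, engine = c("dfg", "exact"), p = 1.05,
                         fairness = NULL, seed = NULL, max_size = Inf) {
  stopifnot(inherits(instance, "cover_instance"))
  engine <- match.arg(engine)
  if (engine == "dfg" && (!is.numeric(p) || p <= 1))
    abort("DFG bucket base `p` must be > 1")
  if (!is.null(seed)) set.seed(seed)
  fc <- fairness_to_cpp(fairness, length(instance$sets))
  kmax <- if (is.finite(max_size)) as.integer(max_size) else -1L
  cpp_greedy_cover(instance$sets, instance$universe_size,
                   engine = if (engine == "dfg") 1L else 0L, p = p,
                   set_class = fc$set_class, quota = fc$demand, kmax = kmax)
}

# internal: greedy ball cover straight from a distance matrix (no set
# materialization at the R level); same engines and fairness semantics.
greedy_cover_dist <- function(D, radius, engine = "dfg", p = 1.05,
                              fairness = NULL, max_size = Inf) {
  fc <- fairness_to_cpp(fairness, nrow(D))
  kmax <- if (is.finite(max_size)) as.integer(max_size) else -1L
  cpp_greedy_cover_dist(D, radius,
                        engine = if (engine == "dfg") 1L else 0L, p = p,
                        set_class = fc$set_class, quota = fc$demand,
                        kmax = kmax)
}
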