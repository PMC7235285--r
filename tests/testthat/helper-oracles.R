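# Independent brute-force oracles used to freeze expected values. These are
# deliberately naive (enumeration / double loops) and share no code with the
# package's engines.

# minimum set cover size by exhaustive enumeration over subcollections,
# smallest cardinality first
brute_force_min_cover <- function(sets, universe_size) {
  ids <- seq_along(sets)
  for (k in 1:length(sets)) {
    combos <- utils::combn(ids, k, simplify = FALSE)
    for (cmb in combos) {
      if (length(unique(unlist(sets[cmb]))) == universe_size) return(k)
    }
  }
  stop("no cover exists")
}

# optimal k-center radius: minimize over all center subsets of size k the
# maximum point-to-nearest-center distance
brute_force_kcenter_radius <- function(D, k) {
  n <- nrow(D)
  best <- Inf
  for (cmb in utils::combn(seq_len(n), k, simplify = FALSE)) {
    r <- max(apply(D[, cmb, drop = FALSE], 1, min))
    if (r < best) best <- r
  }
  best
}

# directed robust Hausdorff by an explicit double loop
brute_force_hausdorff <- function(X, idx, alpha, metric) {
  n <- nrow(X)
  mind <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in idx) {
      d <- switch(metric,
        euclidean = sqrt(sum((X[i, ] - X[j, ])^2)),
        manhattan = sum(abs(X[i, ] - X[j, ])),
        cosine = 1 - sum(X[i, ] * X[j, ]) /
          (sqrt(sum(X[i, ]^2)) * sqrt(sum(X[j, ]^2))),
        pearson = 1 - stats::cor(X[i, ], X[j, ])
      )
      if (d < best) best <- d
    }
    mind[i] <- best
  }
  srt <- sort(mind, decreasing = TRUE)
  max(srt[(floor(alpha * n) + 1):n])
}

# random set cover instance; any element left uncovered by the Bernoulli
# draws is attached to a random set, so a cover always exists
random_cover_instance <- function(n_sets, universe_size, p_member = 0.4) {
  sets <- lapply(seq_len(n_sets), function(i) {
    s <- which(stats::runif(universe_size) < p_member)
    if (length(s) == 0) s <- sample.int(universe_size, 1)
    s
  })
  missing <- setdiff(seq_len(universe_size), unlist(sets))
  for (e in missing) {
    j <- sample.int(n_sets, 1)
    sets[[j]] <- c(sets[[j]], e)
  }
  cover_instance(sets, universe_size)
}

# random covering instance with pairwise-distinct set sizes, built by drawing
# the distinct sizes first (patching uncovered elements into the largest set,
# which keeps sizes distinct)
random_distinct_size_instance <- function(n_sets, universe_size) {
  stopifnot(n_sets < universe_size)
  sizes <- sort(sample(seq_len(universe_size - 1), n_sets))
  sets <- lapply(sizes, function(s) sample.int(universe_size, s))
  missing <- setdiff(seq_len(universe_size), unlist(sets))
  big <- which.max(sizes)
  sets[[big]] <- unique(c(sets[[big]], missing))
  cover_instance(sets, universe_size)
}

random_points <- function(n, d, scale = 1) {
  matrix(stats::rnorm(n * d, sd = scale), nrow = n)
}
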