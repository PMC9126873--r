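# Shared fixtures: all synthetic, built in code.

# An exact m-cycle of maxima heights: m distinct values whose pairwise
# normalized separations all exceed the 0.1 closure threshold (true for
# m <= 8), repeated `reps` times in a fixed random order.
make_mcycle <- function(m, reps = 10, seed = 1) {
  set.seed(seed)
  heights <- ((seq_len(m) + 1) / (m + 1) * 30)[sample.int(m)]
  rep(heights, reps)
}

# Aperiodic maxima heights from the logistic map in its chaotic regime.
logistic_heights <- function(n = 200, r = 3.9, x0 = 0.2) {
  x <- numeric(n)
  x[1] <- x0
  for (i in 2:n) x[i] <- r * x[i - 1] * (1 - x[i - 1])
  x
}

# Group sorted heights into clusters separated by gaps larger than
# `gap_frac` of the largest height; returns the cluster count.
count_height_clusters <- function(heights, gap_frac = 0.05) {
  h <- sort(heights)
  sum(diff(h) > gap_frac * max(h)) + 1L
}

# Count distinct points of a return map: greedy clustering of the (y_i,
# y_next) pairs with a distance tolerance relative to the largest height.
count_map_points <- function(rmap, tol_frac = 0.02) {
  pts <- as.matrix(rmap)
  tol <- tol_frac * max(pts)
  centers <- pts[1, , drop = FALSE]
  for (i in seq_len(nrow(pts))[-1]) {
    d <- sqrt(rowSums((centers - matrix(pts[i, ], nrow(centers), 2,
                                        byrow = TRUE))^2))
    if (min(d) > tol) centers <- rbind(centers, pts[i, ])
  }
  nrow(centers)
}

# Forced-oscillator classifications are reused across test files; memoise
# them (helpers are sourced once per test run).
.forced_cache <- new.env(parent = emptyenv())
forced_point_cached <- function(lambda, n = 4, ...) {
  key <- paste(lambda, n, ..., sep = "_")
  if (is.null(.forced_cache[[key]])) {
    params <- preset_forced_oscillator(n = n)
    .forced_cache[[key]] <- classify_forced_point(params, lambda, ...)
  }
  .forced_cache[[key]]
}
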