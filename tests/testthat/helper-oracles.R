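# Independent oracles and fixture builders used across the test files.
# These are written against the definitions, not against package internals.

# Rao's spacing statistic by naive direct summation over sorted gaps,
# written independently of the package implementation.
oracle_rao_U <- function(angles) {
  n <- length(angles)
  s <- sort(angles %% 360)
  total <- 0
  for (i in seq_len(n - 1)) total <- total + abs((s[i + 1] - s[i]) - 360 / n)
  total <- total + abs((360 - s[n] + s[1]) - 360 / n)
  total / 2
}

# Kolmogorov-Smirnov distance of a sample to Uniform[0, 360).
oracle_ks_uniform <- function(x) {
  n <- length(x)
  s <- sort(x %% 360) / 360
  max(pmax(seq_len(n) / n - s, s - (seq_len(n) - 1) / n))
}

# Optimal frame-to-frame matching cost/assignment by exhaustive permutation
# search (points_a, points_b: n x 2 matrices, n <= 7).
oracle_optimal_assignment <- function(points_a, points_b, max_jump = Inf) {
  n <- nrow(points_a)
  stopifnot(n == nrow(points_b), n <= 7)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  d <- as.matrix(stats::dist(rbind(points_a, points_b)))[seq_len(n), n + seq_len(n)]
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    dd <- d[cbind(seq_len(n), p)]
    if (any(dd > max_jump)) next
    cost <- sum(dd)
    if (cost < best_cost) { best_cost <- cost; best <- p }
  }
  list(assignment = best, cost = best_cost)
}

# Render a Gaussian peak into a matrix (independent of the package's
# internal renderer).
oracle_add_gaussian <- function(img, row0, col0, sigma, amp) {
  rr <- matrix(0:(nrow(img) - 1), nrow(img), ncol(img))
  cc <- matrix(0:(ncol(img) - 1), nrow(img), ncol(img), byrow = TRUE)
  img + amp * exp(-((rr - row0)^2 + (cc - col0)^2) / (2 * sigma^2))
}

# Disk mask on an n x n canvas, 0-based center.
oracle_disk <- function(n, center_rc, radius) {
  rr <- matrix(0:(n - 1), n, n)
  cc <- matrix(0:(n - 1), n, n, byrow = TRUE)
  (rr - center_rc[1])^2 + (cc - center_rc[2])^2 <= radius^2
}
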