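# Independent brute-force oracles. These deliberately re-derive everything
# with plain loops and direct solves, sharing no assembly code with the
# package internals they check.

# all-pairs experimental variogram accumulation (optionally directional)
oracle_variogram <- function(x, y, z, lag_width, n_lags,
                             direction = NA, angle_tolerance = 22.5) {
  sums <- counts <- numeric(n_lags)
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]; dy <- y[j] - y[i]
      d <- sqrt(dx^2 + dy^2)
      if (d == 0) next
      if (!is.na(direction)) {
        az <- (atan2(dx, dy) * 180 / pi) %% 180
        delta <- abs(az - direction %% 180)
        if (min(delta, 180 - delta) > angle_tolerance) next
      }
      bin <- floor(d / lag_width) + 1
      if (bin > n_lags) next
      sums[bin] <- sums[bin] + (z[i] - z[j])^2
      counts[bin] <- counts[bin] + 1
    }
  }
  keep <- counts > 0
  data.frame(lag_center = ((seq_len(n_lags) - 0.5) * lag_width)[keep],
             gamma = sums[keep] / (2 * counts[keep]),
             n_pairs = counts[keep])
}

# all-pairs cross-variogram over co-located (z1, z2) observations
oracle_cross_variogram <- function(x, y, z1, z2, lag_width, n_lags) {
  sums <- counts <- numeric(n_lags)
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((x[j] - x[i])^2 + (y[j] - y[i])^2)
      if (d == 0) next
      bin <- floor(d / lag_width) + 1
      if (bin > n_lags) next
      sums[bin] <- sums[bin] + (z1[i] - z1[j]) * (z2[i] - z2[j])
      counts[bin] <- counts[bin] + 1
    }
  }
  keep <- counts > 0
  data.frame(lag_center = ((seq_len(n_lags) - 0.5) * lag_width)[keep],
             gamma = sums[keep] / (2 * counts[keep]),
             n_pairs = counts[keep])
}

# direct dense solve of the ordinary-kriging equations, built entry by entry
oracle_ok <- function(x, y, z, gamma_fun, tx, ty) {
  n <- length(x)
  A <- matrix(0, n + 1, n + 1)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    A[i, j] <- gamma_fun(x[i] - x[j], y[i] - y[j])
  }
  A[n + 1, seq_len(n)] <- 1
  A[seq_len(n), n + 1] <- 1
  b <- c(vapply(seq_len(n), function(i) gamma_fun(x[i] - tx, y[i] - ty), 0), 1)
  w <- solve(A, b)
  list(weights = w[seq_len(n)], lagrange = w[n + 1],
       estimate = sum(w[seq_len(n)] * z),
       variance = sum(w * b))
}

# direct dense solve of the ordinary co-kriging equations
oracle_ck <- function(px, py, pz, sx, sy, sz, g11, g22, g12, tx, ty) {
  n <- length(px); m <- length(sx)
  N <- n + m + 2
  A <- matrix(0, N, N)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    A[i, j] <- g11(px[i] - px[j], py[i] - py[j])
  }
  for (i in seq_len(m)) for (j in seq_len(m)) {
    A[n + i, n + j] <- g22(sx[i] - sx[j], sy[i] - sy[j])
  }
  for (i in seq_len(n)) for (j in seq_len(m)) {
    A[i, n + j] <- g12(px[i] - sx[j], py[i] - sy[j])
    A[n + j, i] <- A[i, n + j]
  }
  A[seq_len(n), n + m + 1] <- 1; A[n + m + 1, seq_len(n)] <- 1
  A[n + seq_len(m), n + m + 2] <- 1; A[n + m + 2, n + seq_len(m)] <- 1
  b <- c(vapply(seq_len(n), function(i) g11(px[i] - tx, py[i] - ty), 0),
         vapply(seq_len(m), function(j) g12(sx[j] - tx, sy[j] - ty), 0),
         1, 0)
  w <- solve(A, b)
  list(weights_primary = w[seq_len(n)],
       weights_secondary = w[n + seq_len(m)],
       estimate = sum(w[seq_len(n)] * pz) + sum(w[n + seq_len(m)] * sz),
       variance = sum(w * b))
}
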