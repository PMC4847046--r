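#' @title Ordinary kriging engine
#' @description Internal assembly of the ordinary-kriging system in
#' semivariance form. The (n+1) x (n+1) matrix carries model semivariances
#' between data points plus a Lagrange row/column enforcing that the weights
#' sum to one (the unbiasedness constraint of the ordinary-kriging predictor
#' `z* = sum(lambda_i * z_i)`); the system is solved densely.
#' @name kriging-internal
#' @keywords internal
NULL

DUP_TOL <- 1e-9   # metres within which two data locations count as duplicates

check_duplicates <- function(s, label = "samples") {
  if (nrow(s) < 2L) return(invisible())
  d <- as.matrix(stats::dist(cbind(s$x, s$y)))
  diag(d) <- Inf
  if (any(d < DUP_TOL)) {
    idx <- which(d < DUP_TOL, arr.ind = TRUE)[1, ]
    stop("duplicate coordinates in ", label, ": points '", s$id[idx[1]],
         "' and '", s$id[idx[2]], "' coincide within ", DUP_TOL, " m",
         call. = FALSE)
  }
  invisible()
}

ok_prepare <- function(samples, model) {
  n <- nrow(samples)
  check_duplicates(samples)
  dx <- outer(samples$x, samples$x, "-")
  dy <- outer(samples$y, samples$y, "-")
  G <- matrix(model_gamma(model, as.vector(dx), as.vector(dy)), n, n)
  # normalize the semivariance block so its magnitude matches the unit
  # constraint rows: kriging weights are invariant to scaling gamma, and the
  # mixed magnitudes otherwise ruin the conditioning for raw-scale data
  gscale <- max(max(abs(G)), .Machine$double.eps)
  A <- rbind(cbind(G / gscale, 1), c(rep(1, n), 0))
  A_inv <- solve_kriging_system(A, n, "ordinary-kriging")
  list(A_inv = A_inv, samples = samples, model = model, n = n, gscale = gscale)
}

# dense solve with a one-shot ridge rescue: gaussian variograms with weak
# nuggets can be singular to machine precision even for valid inputs; the
# ridge perturbs the data rows only (Lagrange rows stay exact)
solve_kriging_system <- function(A, n_data, label) {
  out <- tryCatch(solve(A), error = function(e) NULL)
  if (!is.null(out)) return(out)
  scale <- max(abs(A))
  for (eps_rel in c(1e-8, 1e-6, 1e-4)) {
    ridge <- diag(c(rep(eps_rel * scale, n_data), rep(0, nrow(A) - n_data)))
    out <- tryCatch(solve(A + ridge), error = function(e) NULL)
    if (!is.null(out)) {
      warning("near-singular ", label, " system regularized with ridge ",
              format(eps_rel * scale, digits = 3), call. = FALSE)
      return(out)
    }
  }
  stop("singular ", label, " system (check for duplicate or degenerate ",
       "data configurations)", call. = FALSE)
}

# predict at many targets from a prepared system; returns estimates, variances,
# Lagrange multipliers and (optionally) the weight matrix
ok_predict <- function(prep, tx, ty, keep_weights = FALSE) {
  n <- prep$n; s <- prep$samples; model <- prep$model
  m <- length(tx)
  B <- matrix(0, n + 1L, m)
  for (k in seq_len(m)) {
    B[seq_len(n), k] <- model_gamma(model, s$x - tx[k], s$y - ty[k]) / prep$gscale
  }
  B[n + 1L, ] <- 1
  W <- prep$A_inv %*% B
  est <- as.numeric(t(W[seq_len(n), , drop = FALSE]) %*% s$value)
  vr  <- colSums(W * B) * prep$gscale
  psi <- W[n + 1L, ] * prep$gscale
  # exact interpolation at data locations: force the limit values through
  for (k in seq_len(m)) {
    hit <- which(sqrt((s$x - tx[k])^2 + (s$y - ty[k])^2) < DUP_TOL)
    if (length(hit)) {
      est[k] <- s$value[hit[1]]; vr[k] <- 0; psi[k] <- 0
      if (keep_weights) { W[seq_len(n), k] <- 0; W[hit[1], k] <- 1 }
    }
  }
  if (any(vr < -1e-6 * max(1, prep$gscale))) {
    warning("kriging variance numerically negative (min ",
            format(min(vr), digits = 4), "); clamped to 0")
  }
  vr <- pmax(vr, 0)
  out <- list(estimate = est, variance = vr, lagrange = psi)
  if (keep_weights) out$weights <- W[seq_len(n), , drop = FALSE]
  out
}

neighborhood_subset <- function(samples, tx, ty, neighborhood) {
  if (is.null(neighborhood) || !is.finite(neighborhood$max_points %||% Inf) ||
      (neighborhood$max_points %||% Inf) >= nrow(samples)) {
    return(samples)
  }
  d <- sqrt((samples$x - tx)^2 + (samples$y - ty)^2)
  samples[order(d)[seq_len(neighborhood$max_points)], ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ordinary kriging at a single point
#'
#' Solves the ordinary-kriging system (model semivariances plus one Lagrange
#' multiplier for the sum-to-one weight constraint) and returns the weights,
#' estimate and kriging variance. Kriging is an exact interpolator: at a data
#' location the estimate equals the datum and the variance is zero.
#'
#' @param samples a [sample_set()] (the training data).
#' @param model a [variogram_model()] on the same scale as `samples$value`.
#' @param target numeric `c(x, y)` in metres.
#' @param neighborhood `NULL` for a global neighborhood (all data in the
#'   system; the intended regime for surveys of ~100 points) or
#'   `list(max_points = k)` to use only the k nearest data.
#' @return a `kriging_solution`: list with `weights_primary`,
#'   `weights_secondary` (empty), `lagrange_multipliers`, `estimate`,
#'   `kriging_variance`.
#' @export
krige_point <- function(samples, model, target, neighborhood = NULL) {
  stopifnot(inherits(samples, "sample_set"), length(target) == 2L)
  use <- neighborhood_subset(samples, target[1], target[2], neighborhood)
  prep <- ok_prepare(use, model)
  p <- ok_predict(prep, target[1], target[2], keep_weights = TRUE)
  structure(list(weights_primary = as.numeric(p$weights),
                 weights_secondary = numeric(),
                 lagrange_multipliers = p$lagrange,
                 estimate = p$estimate,
                 kriging_variance = p$variance),
            class = "kriging_solution")
}

#' Ordinary kriging over a grid
#'
#' Applies [krige_point()] at every cell centre (with one shared system
#' factorization when the neighborhood is global).
#'
#' @inheritParams krige_point
#' @param grid a [grid_spec()].
#' @return a [prediction_grid()] with estimate and variance layers.
#' @export
krige_grid <- function(samples, model, grid, neighborhood = NULL) {
  cc <- grid_centers(grid)
  p <- krige_points(samples, model, cc$x, cc$y, neighborhood)
  est <- matrix(p$estimate, grid$n_rows, grid$n_cols, byrow = TRUE)
  vr  <- matrix(p$variance, grid$n_rows, grid$n_cols, byrow = TRUE)
  prediction_grid(grid, est, vr, scale = "raw")
}

#' Ordinary kriging at arbitrary points (vectorized)
#'
#' @inheritParams krige_point
#' @param tx,ty target coordinate vectors.
#' @return list of `estimate`, `variance`, `lagrange` vectors.
#' @export
krige_points <- function(samples, model, tx, ty, neighborhood = NULL) {
  stopifnot(length(tx) == length(ty))
  global <- is.null(neighborhood) ||
    (neighborhood$max_points %||% Inf) >= nrow(samples)
  if (global) {
    prep <- ok_prepare(samples, model)
    return(ok_predict(prep, tx, ty))
  }
  est <- vr <- psi <- numeric(length(tx))
  for (k in seq_along(tx)) {
    use <- neighborhood_subset(samples, tx[k], ty[k], neighborhood)
    p <- ok_predict(ok_prepare(use, model), tx[k], ty[k])
    est[k] <- p$estimate; vr[k] <- p$variance; psi[k] <- p$lagrange
  }
  list(estimate = est, variance = vr, lagrange = psi)
}

#' Lognormal ordinary kriging
#'
#' Takes natural logs of strictly positive concentrations, kriges on the log
#' scale with a variogram fitted to the logs, and back-transforms each cell.
#' `naive_exp` back-transform is `exp(z*)` (median-type, keeps the map on a
#' defensible mg/kg scale and preserves exactness at data points);
#' `unbiased` is the classical lognormal-kriging correction
#' `exp(z* + sigma^2/2 - psi)` with `psi` the Lagrange multiplier.
#'
#' @param samples raw-scale (mg/kg) [sample_set()], all values > 0.
#' @param model a [variogram_model()] fitted to the *log* values.
#' @param grid a [grid_spec()].
#' @param back_transform `"naive_exp"` or `"unbiased"`.
#' @param neighborhood as in [krige_point()].
#' @return a [prediction_grid()] in mg/kg (variance layer kept on the log
#'   scale, flagged by its `scale` field).
#' @export
krige_lognormal <- function(samples, model, grid,
                            back_transform = c("naive_exp", "unbiased"),
                            neighborhood = NULL) {
  back_transform <- match.arg(back_transform)
  ls <- log_transform(samples)
  cc <- grid_centers(grid)
  p <- krige_points(ls, model, cc$x, cc$y, neighborhood)
  z <- backtransform_log(p, back_transform)
  est <- matrix(z, grid$n_rows, grid$n_cols, byrow = TRUE)
  vr  <- matrix(p$variance, grid$n_rows, grid$n_cols, byrow = TRUE)
  out <- prediction_grid(grid, est, vr, scale = "raw")
  out$variance_scale <- "log"
  out
}

backtransform_log <- function(p, back_transform) {
  switch(back_transform,
    naive_exp = exp(p$estimate),
    unbiased  = exp(p$estimate + p$variance / 2 - p$lagrange))
}
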