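ck_prepare <- function(primary, secondary, lmc) {
  check_duplicates(primary, "primary samples")
  check_duplicates(secondary, "secondary samples")
  n <- nrow(primary); m <- nrow(secondary)
  px <- primary$x; py <- primary$y; sx <- secondary$x; sy <- secondary$y
  g11 <- matrix(model_gamma(lmc$direct_primary,
                            as.vector(outer(px, px, "-")),
                            as.vector(outer(py, py, "-"))), n, n)
  g22 <- matrix(model_gamma(lmc$direct_secondary,
                            as.vector(outer(sx, sx, "-")),
                            as.vector(outer(sy, sy, "-"))), m, m)
  g12 <- matrix(model_gamma(lmc$cross,
                            as.vector(outer(px, sx, "-")),
                            as.vector(outer(py, sy, "-"))), n, m)
  # normalized as in ok_prepare (weights invariant to scaling gamma), with
  # two Lagrange rows: primary weights sum to 1, secondary weights sum to 0
  gscale <- max(abs(g11), abs(g22), abs(g12), .Machine$double.eps)
  A <- rbind(
    cbind(g11 / gscale,    g12 / gscale,    1, 0),
    cbind(t(g12) / gscale, g22 / gscale,    0, 1),
    c(rep(1, n), rep(0, m), 0, 0),
    c(rep(0, n), rep(1, m), 0, 0)
  )
  A_inv <- solve_kriging_system(A, n + m, "co-kriging")
  list(A_inv = A_inv, primary = primary, secondary = secondary, lmc = lmc,
       n = n, m = m, gscale = gscale)
}

ck_predict <- function(prep, tx, ty, keep_weights = FALSE) {
  n <- prep$n; m <- prep$m
  p <- prep$primary; s <- prep$secondary; lmc <- prep$lmc
  nt <- length(tx)
  B <- matrix(0, n + m + 2L, nt)
  for (k in seq_len(nt)) {
    B[seq_len(n), k] <- model_gamma(lmc$direct_primary,
                                    p$x - tx[k], p$y - ty[k]) / prep$gscale
    B[n + seq_len(m), k] <- model_gamma(lmc$cross,
                                        s$x - tx[k], s$y - ty[k]) / prep$gscale
  }
  B[n + m + 1L, ] <- 1
  W <- prep$A_inv %*% B
  lam <- W[seq_len(n), , drop = FALSE]
  kap <- W[n + seq_len(m), , drop = FALSE]
  est <- as.numeric(t(lam) %*% p$value + t(kap) %*% s$value)
  vr  <- colSums(W * B) * prep$gscale
  psi <- W[n + m + 1L, ] * prep$gscale
  for (k in seq_len(nt)) {
    hit <- which(sqrt((p$x - tx[k])^2 + (p$y - ty[k])^2) < DUP_TOL)
    if (length(hit)) { est[k] <- p$value[hit[1]]; vr[k] <- 0 }
  }
  if (any(vr < -1e-6 * max(1, prep$gscale))) {
    warning("co-kriging variance numerically negative (min ",
            format(min(vr), digits = 4), "); clamped to 0")
  }
  vr <- pmax(vr, 0)
  out <- list(estimate = est, variance = vr, lagrange = psi)
  if (keep_weights) {
    out$weights_primary <- lam
    out$weights_secondary <- kap
    out$lagrange2 <- W[n + m + 2L, ] * prep$gscale
  }
  out
}

#' Ordinary co-kriging at a single point
#'
#' Predicts the primary variable as `z* = sum(lambda_i z_i) + sum(k_j u_j)`
#' from primary data `z` and secondary data `u`, solving the ordinary
#' co-kriging system under a linear model of coregionalization with the two
#' unbiasedness constraints `sum(lambda) = 1` and `sum(k) = 0`. A secondary
#' variable spatially correlated with the primary can only reduce the
#' prediction variance relative to ordinary kriging of the primary alone.
#'
#' @param primary,secondary [sample_set()] objects (values on the same scale
#'   as the coregionalization model).
#' @param lmc a [cross_variogram_model()]; validated with [check_lmc()] unless
#'   `skip_lmc_check`.
#' @param target numeric `c(x, y)`.
#' @param neighborhood `NULL` (global) or `list(max_points = k)` applied to
#'   each set separately.
#' @param skip_lmc_check set `TRUE` to krige with a non-validated model
#'   (a warning is emitted).
#' @return a `kriging_solution` with both weight vectors and two Lagrange
#'   multipliers.
#' @export
cokrige_point <- function(primary, secondary, lmc, target, neighborhood = NULL,
                          skip_lmc_check = FALSE) {
  chk <- check_lmc(lmc)
  if (!chk$valid) {
    if (!skip_lmc_check) {
      stop("invalid coregionalization model: ",
           paste(chk$violations, collapse = "; "), call. = FALSE)
    }
    warning("co-kriging with a non-validated coregionalization model: ",
            paste(chk$violations, collapse = "; "))
  }
  pu <- neighborhood_subset(primary, target[1], target[2], neighborhood)
  su <- neighborhood_subset(secondary, target[1], target[2], neighborhood)
  prep <- ck_prepare(pu, su, lmc)
  p <- ck_predict(prep, target[1], target[2], keep_weights = TRUE)
  structure(list(weights_primary = as.numeric(p$weights_primary),
                 weights_secondary = as.numeric(p$weights_secondary),
                 lagrange_multipliers = c(p$lagrange, p$lagrange2),
                 estimate = p$estimate,
                 kriging_variance = p$variance),
            class = "kriging_solution")
}

#' Ordinary co-kriging over a grid
#'
#' @inheritParams cokrige_point
#' @param grid a [grid_spec()].
#' @return a [prediction_grid()] with estimate and variance layers.
#' @export
cokrige_grid <- function(primary, secondary, lmc, grid, neighborhood = NULL,
                         skip_lmc_check = FALSE) {
  cc <- grid_centers(grid)
  p <- cokrige_points(primary, secondary, lmc, cc$x, cc$y, neighborhood,
                      skip_lmc_check)
  est <- matrix(p$estimate, grid$n_rows, grid$n_cols, byrow = TRUE)
  vr  <- matrix(p$variance, grid$n_rows, grid$n_cols, byrow = TRUE)
  prediction_grid(grid, est, vr, scale = "raw")
}

#' Ordinary co-kriging at arbitrary points (vectorized)
#'
#' @inheritParams cokrige_point
#' @param tx,ty target coordinate vectors.
#' @return list of `estimate`, `variance`, `lagrange` vectors.
#' @export
cokrige_points <- function(primary, secondary, lmc, tx, ty,
                           neighborhood = NULL, skip_lmc_check = FALSE) {
  chk <- check_lmc(lmc)
  if (!chk$valid && !skip_lmc_check) {
    stop("invalid coregionalization model: ",
         paste(chk$violations, collapse = "; "), call. = FALSE)
  }
  global <- is.null(neighborhood) ||
    (neighborhood$max_points %||% Inf) >= max(nrow(primary), nrow(secondary))
  if (global) {
    prep <- ck_prepare(primary, secondary, lmc)
    return(ck_predict(prep, tx, ty))
  }
  est <- vr <- psi <- numeric(length(tx))
  for (k in seq_along(tx)) {
    pu <- neighborhood_subset(primary, tx[k], ty[k], neighborhood)
    su <- neighborhood_subset(secondary, tx[k], ty[k], neighborhood)
    p <- ck_predict(ck_prepare(pu, su, lmc), tx[k], ty[k])
    est[k] <- p$estimate; vr[k] <- p$variance; psi[k] <- p$lagrange
  }
  list(estimate = est, variance = vr, lagrange = psi)
}
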