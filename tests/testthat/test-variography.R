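test_that("experimental variogram matches hand-computed single-pair case", {
  s <- sample_set(c("a", "b"), c(0, 0), c(0, 10), c(2, 4))
  v <- experimental_variogram(s, lag_width = 10, n_lags = 2)
  # one pair at 10 m -> bin [10, 20), gamma = (2 - 4)^2 / 2 = 2
  expect_equal(v$gamma, 2.0)
  expect_equal(v$n_pairs, 1L)
  expect_equal(v$lag_center, 15)
})

test_that("constant field gives zero semivariance at every lag", {
  s <- random_sample_set(20, seed = 2)
  s$value <- rep(7, 20)
  v <- experimental_variogram(s, n_lags = 6)
  expect_true(all(v$gamma == 0))
})

test_that("experimental variogram equals the all-pairs oracle exactly", {
  for (seed in 1:8) {
    n <- sample(c(10, 25, 50), 1)
    s <- random_sample_set(n, seed = seed)
    lw <- 12; nl <- 5
    v <- experimental_variogram(s, lag_width = lw, n_lags = nl)
    o <- oracle_variogram(s$x, s$y, s$value, lw, nl)
    expect_equal(v$gamma, o$gamma, tolerance = 1e-12)
    expect_equal(v$n_pairs, as.integer(o$n_pairs))
    # directional class
    vd <- experimental_variogram(s, lag_width = lw, n_lags = nl,
                                 direction = 115, angle_tolerance = 22.5)
    od <- oracle_variogram(s$x, s$y, s$value, lw, nl, direction = 115)
    expect_equal(vd$gamma, od$gamma, tolerance = 1e-12)
  }
})

test_that("model_gamma follows the practical-range closed forms", {
  m <- variogram_model("gaussian", 0.6, 3.2, 90, sill_is_total = TRUE)
  expect_equal(model_gamma(m, 0, 0), 0)                       # exact at origin
  expect_equal(model_gamma(m, 0, 90), 0.6 + 2.6 * (1 - exp(-3)),
               tolerance = 1e-12)                             # ~3.0706 at range
  # nugget discontinuity just off the origin
  expect_gt(model_gamma(m, 1e-9, 0), 0.6 - 1e-6)
  # isotropic model is rotation-symmetric
  for (d in c(5, 40, 200)) {
    expect_equal(model_gamma(m, d, 0), model_gamma(m, 0, d))
  }
  # spherical reaches the sill exactly at the range; exponential ~95%
  sph <- variogram_model("spherical", 0.2, 1.2, 50, sill_is_total = TRUE)
  expect_equal(model_gamma(sph, 50, 0), 1.2)
  expect_equal(model_gamma(sph, 500, 0), 1.2)
  ex <- variogram_model("exponential", 0, 1, 50, sill_is_total = TRUE)
  expect_equal(model_gamma(ex, 0, 50), 1 - exp(-3), tolerance = 1e-12)
})

test_that("model_gamma is non-decreasing in effective distance", {
  for (type in c("gaussian", "spherical", "exponential")) {
    m <- variogram_model(type, 0.3, 2, 60, 30, 45, sill_is_total = TRUE)
    h <- seq(0.1, 200, length.out = 300)
    g <- model_gamma(m, h * sin(pi / 5), h * cos(pi / 5))
    expect_true(all(diff(g) > -1e-12), info = type)
  }
})

test_that("anisotropic model is frame-equivariant under joint rotation", {
  m1 <- variogram_model("gaussian", 0.1, 1.5, 80, 30, 20, sill_is_total = TRUE)
  rot <- 37
  m2 <- variogram_model("gaussian", 0.1, 1.5, 80, 30, 20 + rot,
                        sill_is_total = TRUE)
  set.seed(9)
  for (k in 1:20) {
    d <- runif(1, 1, 150); az <- runif(1, 0, 360)
    # lag azimuth az in frame 1; same lag rotated by `rot` in frame 2
    g1 <- model_gamma(m1, d * sin(az * pi / 180), d * cos(az * pi / 180))
    g2 <- model_gamma(m2, d * sin((az + rot) * pi / 180),
                      d * cos((az + rot) * pi / 180))
    expect_equal(g1, g2, tolerance = 1e-12)
  }
})

test_that("fit_variogram recovers parameters from noise-free model points", {
  truth <- variogram_model("gaussian", 0.4, 1.3, 70, sill_is_total = FALSE)
  lags <- seq(5, 120, by = 5)
  v <- structure(
    data.frame(lag_center = lags,
               gamma = model_gamma(truth, 0, lags),
               n_pairs = rep(50L, length(lags))),
    direction = NA, angle_tolerance = 22.5, lag_width = 5,
    class = c("experimental_variogram", "data.frame"))
  fit <- fit_variogram(v, "gaussian")
  expect_equal(fit$nugget, truth$nugget, tolerance = 0.01)
  expect_equal(fit$partial_sill, truth$partial_sill, tolerance = 0.01)
  expect_equal(fit$range_major, truth$range_major, tolerance = 0.01)

  # anisotropic recovery from two noise-free directional variograms
  tru2 <- variogram_model("gaussian", 0.2, 1.0, 70, 35, 115,
                          sill_is_total = FALSE)
  mk <- function(azim) {
    th <- azim * pi / 180
    structure(
      data.frame(lag_center = lags,
                 gamma = model_gamma(tru2, lags * sin(th), lags * cos(th)),
                 n_pairs = rep(50L, length(lags))),
      direction = azim, angle_tolerance = 22.5, lag_width = 5,
      class = c("experimental_variogram", "data.frame"))
  }
  fit2 <- fit_variogram(list(mk(115), mk(205)), "gaussian",
                        fixed_azimuth = 115)
  expect_equal(fit2$range_major, 70, tolerance = 0.7)
  expect_equal(fit2$range_minor, 35, tolerance = 0.35)
})

test_that("flat experimental variogram yields a pure-nugget fit", {
  v <- structure(
    data.frame(lag_center = c(10, 20, 30, 40), gamma = rep(0.8, 4),
               n_pairs = rep(10L, 4)),
    direction = NA, angle_tolerance = 22.5, lag_width = 10,
    class = c("experimental_variogram", "data.frame"))
  fit <- fit_variogram(v, "gaussian")
  # all structure collapses to an effective constant: nugget + near-origin sill
  expect_equal(model_gamma(fit, 0, 5), 0.8, tolerance = 0.05)
  expect_equal(model_gamma(fit, 0, 40), 0.8, tolerance = 0.05)
})

test_that("cross-variogram reduces to the direct variogram and negates", {
  p <- random_sample_set(12, seed = 5)
  v_direct <- experimental_variogram(p, lag_width = 15, n_lags = 5)
  v_cross <- experimental_cross_variogram(p, p, lag_width = 15, n_lags = 5)
  expect_equal(v_cross$gamma, v_direct$gamma, tolerance = 1e-12)

  neg <- p; neg$value <- -p$value
  v_neg <- experimental_cross_variogram(p, neg, lag_width = 15, n_lags = 5)
  expect_equal(v_neg$gamma, -v_direct$gamma, tolerance = 1e-12)
})

test_that("cross-variogram matches the all-pairs oracle on co-located data", {
  set.seed(11)
  p <- random_sample_set(12, seed = 11)
  s <- p
  s$value <- 2 * p$value + rnorm(12, 0, 5)
  s$instrument <- "secondary"
  v <- experimental_cross_variogram(p, s, lag_width = 15, n_lags = 5)
  o <- oracle_cross_variogram(p$x, p$y, p$value, s$value, 15, 5)
  expect_equal(v$gamma, o$gamma, tolerance = 1e-12)
})

test_that("cross-variography requires co-located points", {
  p <- random_sample_set(5, seed = 1)
  q <- random_sample_set(5, seed = 99)
  expect_error(experimental_cross_variogram(p, q), "co-located")
})

test_that("check_lmc flags Cauchy-Schwarz violations and passes valid models", {
  mk <- function(psill, nug = 0) {
    variogram_model("gaussian", nug, psill, 90, sill_is_total = FALSE)
  }
  bad <- cross_variogram_model(mk(2.6, 0.6), mk(1.1, 0.5), mk(2.2))
  res <- check_lmc(bad)
  expect_false(res$valid)     # 2.2 > sqrt(2.6 * 1.1) ~ 1.69
  expect_match(res$violations, "cross partial sill", all = FALSE)

  zero <- cross_variogram_model(mk(2.6), mk(1.1), mk(0))
  expect_true(check_lmc(zero)$valid)

  same <- cross_variogram_model(mk(1.5, 0.2), mk(1.5, 0.2), mk(1.5, 0.2))
  expect_true(check_lmc(same)$valid)     # equality case

  shr <- cross_variogram_model(
    mk(2), mk(2),
    variogram_model("gaussian", 0, 1, 50, sill_is_total = FALSE))
  expect_false(check_lmc(shr)$valid)     # ranges differ
})
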