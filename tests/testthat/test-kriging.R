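gauss_iso <- function(nugget = 0.2, psill = 1.5, range = 40) {
  variogram_model("gaussian", nugget, psill, range, sill_is_total = FALSE)
}

test_that("single datum and symmetric pairs give forced weights", {
  s1 <- sample_set("a", 10, 10, 42)
  k <- krige_point(s1, gauss_iso(), c(50, 50))
  expect_equal(k$weights_primary, 1)
  expect_equal(k$estimate, 42)

  s2 <- sample_set(c("a", "b"), c(-10, 10), c(0, 0), c(3, 9))
  k2 <- krige_point(s2, gauss_iso(), c(0, 0))
  expect_equal(k2$weights_primary, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(k2$estimate, 6)
})

test_that("pure-nugget kriging reduces to the arithmetic mean", {
  s <- random_sample_set(8, seed = 3)
  pure <- variogram_model("gaussian", 1, 0, 40, sill_is_total = FALSE)
  k <- krige_point(s, pure, c(37, 61))
  expect_equal(k$weights_primary, rep(1 / 8, 8), tolerance = 1e-10)
  expect_equal(k$estimate, mean(s$value), tolerance = 1e-10)
})

test_that("kriging is exact at data locations with zero variance", {
  s <- random_sample_set(10, seed = 6)
  m <- gauss_iso()
  p <- krige_points(s, m, s$x, s$y)
  expect_equal(p$estimate, s$value, tolerance = 1e-9)
  expect_equal(p$variance, rep(0, 10))
})

test_that("OK weights match the independent dense-solve oracle", {
  for (seed in 1:10) {
    s <- random_sample_set(10, seed = 100 + seed)
    m <- gauss_iso(range = 50)
    tx <- runif(1, 0, 100); ty <- runif(1, 0, 100)
    k <- krige_point(s, m, c(tx, ty))
    o <- oracle_ok(s$x, s$y, s$value, gamma_fun_of(m), tx, ty)
    expect_equal(k$weights_primary, o$weights, tolerance = 1e-8)
    expect_equal(k$estimate, o$estimate, tolerance = 1e-8)
    expect_equal(k$kriging_variance, o$variance, tolerance = 1e-8)
    expect_equal(sum(k$weights_primary), 1, tolerance = 1e-8)
  }
})

test_that("duplicate data locations are rejected by name", {
  s <- sample_set(c("a", "b", "c"), c(0, 0, 5), c(0, 0, 5), c(1, 2, 3))
  expect_error(krige_point(s, gauss_iso(), c(2, 2)),
               "duplicate coordinates.*'[ab]' and '[ab]'")
})

test_that("krige_grid agrees with per-cell point kriging and masks nothing", {
  s <- random_sample_set(12, seed = 8)
  m <- gauss_iso()
  gs <- grid_spec(0, 0, 25, 3, 3)
  g <- krige_grid(s, m, gs)
  cc <- grid_centers(gs)
  for (i in c(1, 5, 9)) {
    k <- krige_point(s, m, c(cc$x[i], cc$y[i]))
    expect_equal(g$estimates[cc$row[i], cc$col[i]], k$estimate,
                 tolerance = 1e-10)
  }
  # constant data -> constant surface (sum-to-one weights)
  s$value <- rep(11, 12)
  gc <- krige_grid(s, m, gs)
  expect_equal(as.numeric(gc$estimates), rep(11, 9), tolerance = 1e-9)
})

test_that("sample order does not affect predictions", {
  s <- random_sample_set(15, seed = 12)
  m <- gauss_iso()
  p1 <- krige_points(s, m, c(30, 70), c(40, 20))
  perm <- s[sample.int(15), ]
  p2 <- krige_points(perm, m, c(30, 70), c(40, 20))
  expect_equal(p1$estimate, p2$estimate, tolerance = 1e-10)
  expect_equal(p1$variance, p2$variance, tolerance = 1e-10)
})

test_that("nearest-neighbour search restricts the kriging system", {
  s <- random_sample_set(20, seed = 13)
  m <- gauss_iso()
  k <- krige_point(s, m, c(50, 50), neighborhood = list(max_points = 6))
  expect_length(k$weights_primary, 6)
  expect_equal(sum(k$weights_primary), 1, tolerance = 1e-8)
})

test_that("lognormal kriging respects exactness and handles constants", {
  # zero-variance field: a flat variogram fitted to constant data makes both
  # back-transforms return the constant everywhere
  s <- random_sample_set(9, seed = 21)
  s$value <- rep(250, 9)
  m <- gauss_iso(nugget = 1e-10, psill = 1e-10)
  gs <- grid_spec(0, 0, 50, 2, 2)
  for (bt in c("naive_exp", "unbiased")) {
    g <- krige_lognormal(s, m, gs, back_transform = bt)
    expect_equal(as.numeric(g$estimates), rep(250, 4), tolerance = 1e-6)
  }
  m <- gauss_iso(nugget = 0.01, psill = 0.5)
  # naive back-transform is exact at a datum location
  s2 <- random_sample_set(9, seed = 22)
  gs2 <- grid_spec(s2$x[1] - 2.5, s2$y[1] - 2.5, 5, 1, 1)  # cell centre = datum
  g2 <- krige_lognormal(s2, m, gs2, back_transform = "naive_exp")
  expect_equal(g2$estimates[1, 1], s2$value[1], tolerance = 1e-9)
})

test_that("unbiased back-transform beats naive exp on mean bias", {
  # simulated stationary lognormal field: median-type naive exp must show a
  # larger downward mean bias than the lognormal-kriging correction
  model <- variogram_model("gaussian", 0.05, 0.8, 50, sill_is_total = FALSE)
  cfg <- scenario_config(domain = grid_spec(0, 0, 10, 12, 10),
                         field_model = model, sources = NULL,
                         mean_log = 4, n_primary = 25, n_colocated = 0,
                         n_secondary = 0, n_validation = 0,
                         primary_noise_sd_log = 0)
  sim <- field_simulator(cfg)
  bias <- matrix(NA_real_, 50, 2)
  for (r in 1:50) {
    truth <- sim(400 + r)
    set.seed(800 + r)
    cc <- grid_centers(cfg$domain)
    tv <- as.numeric(t(truth$estimates))
    idx <- sample.int(length(tv), 25)
    tgt <- sample(setdiff(seq_along(tv), idx), 40)
    s <- sample_set(paste0("p", 1:25), cc$x[idx], cc$y[idx], tv[idx])
    p <- krige_points(log_transform(s), model, cc$x[tgt], cc$y[tgt])
    bias[r, 1] <- mean(exp(p$estimate) - tv[tgt])
    bias[r, 2] <- mean(exp(p$estimate + p$variance / 2 - p$lagrange) - tv[tgt])
  }
  expect_lt(abs(mean(bias[, 2])), abs(mean(bias[, 1])))
  expect_lt(mean(bias[, 1]), 0)   # naive exp biased low
})

test_that("co-kriging weights match the independent dense-solve oracle", {
  for (seed in 1:6) {
    set.seed(300 + seed)
    lmc <- random_lmc(300 + seed)
    p <- random_sample_set(5, seed = 400 + seed)
    s <- random_sample_set(20, seed = 500 + seed, extent = 100)
    s$instrument <- "secondary"
    tx <- runif(1, 0, 100); ty <- runif(1, 0, 100)
    k <- cokrige_point(p, s, lmc, c(tx, ty))
    o <- oracle_ck(p$x, p$y, p$value, s$x, s$y, s$value,
                   gamma_fun_of(lmc$direct_primary),
                   gamma_fun_of(lmc$direct_secondary),
                   gamma_fun_of(lmc$cross), tx, ty)
    expect_equal(k$weights_primary, o$weights_primary, tolerance = 1e-8)
    expect_equal(k$weights_secondary, o$weights_secondary, tolerance = 1e-8)
    expect_equal(k$estimate, o$estimate, tolerance = 1e-8)
    expect_equal(sum(k$weights_primary), 1, tolerance = 1e-8)
    expect_equal(sum(k$weights_secondary), 0, tolerance = 1e-8)
  }
})

test_that("zero cross-structure decouples co-kriging from the secondary", {
  p <- random_sample_set(8, seed = 31)
  s <- random_sample_set(15, seed = 32)
  s$instrument <- "secondary"
  direct <- gauss_iso()
  lmc <- cross_variogram_model(
    direct, direct,
    variogram_model("gaussian", 0, 0, direct$range_major,
                    sill_is_total = FALSE))
  k <- cokrige_point(p, s, lmc, c(45, 55))
  ok <- krige_point(p, direct, c(45, 55))
  expect_equal(k$estimate, ok$estimate, tolerance = 1e-8)
  expect_equal(max(abs(k$weights_secondary)), 0, tolerance = 1e-8)
})

test_that("co-kriging never increases the variance relative to OK", {
  for (seed in 1:10) {
    lmc <- random_lmc(600 + seed)
    p <- random_sample_set(6, seed = 700 + seed)
    s <- random_sample_set(18, seed = 800 + seed)
    s$instrument <- "secondary"
    set.seed(900 + seed)
    tx <- runif(5, 0, 100); ty <- runif(5, 0, 100)
    vck <- cokrige_points(p, s, lmc, tx, ty)$variance
    vok <- krige_points(p, lmc$direct_primary, tx, ty)$variance
    expect_true(all(vck <= vok + 1e-8 * (1 + vok)))
  }
})

test_that("invalid LMC is rejected unless explicitly overridden", {
  p <- random_sample_set(5, seed = 41)
  s <- random_sample_set(8, seed = 42)
  mk <- function(psill) variogram_model("gaussian", 0.1, psill, 60,
                                        sill_is_total = FALSE)
  bad <- cross_variogram_model(mk(1), mk(1), mk(3))
  expect_error(cokrige_point(p, s, bad, c(0, 0)), "coregionalization")
  expect_warning(cokrige_point(p, s, bad, c(0, 0), skip_lmc_check = TRUE),
                 "non-validated")
})
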