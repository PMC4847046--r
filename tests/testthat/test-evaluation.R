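test_that("summary statistics reproduce the published survey values", {
  tab <- assay_table()
  cu <- summary_stats(tab$cu)
  expect_equal(round(cu$mean, 1), 1212.8)
  expect_equal(cu$max, 4437)
  expect_equal(cu$min, 17)
  pb <- summary_stats(tab$pb)
  expect_equal(round(pb$mean, 1), 410.9)
  ec <- summary_stats(tab$ec)
  expect_equal(round(ec$mean, 2), 34.63)
  expect_equal(ec$sd, 13.44, tolerance = 5e-4)  # printed value truncated
  ph <- summary_stats(tab$ph)
  expect_equal(round(ph$mean, 2), 5.07)

  one <- summary_stats(42)
  expect_equal(one$min, 42); expect_equal(one$max, 42)
  expect_equal(one$mean, 42); expect_true(is.na(one$sd))
  expect_error(summary_stats(numeric()), "empty")
})

test_that("skewness screen matches symmetry and flags skewed assays", {
  sym <- skewness_screen(c(-1, 0, 1))
  expect_equal(sym$skewness, 0)
  expect_false(sym$recommend_log)

  cu <- skewness_screen(assay_table()$cu)
  expect_gt(cu$skewness, 1)
  expect_true(cu$recommend_log)

  set.seed(10)
  v <- exp(rnorm(100, 4, 1))
  expect_true(skewness_screen(v)$recommend_log)
  expect_false(skewness_screen(log(v))$recommend_log)

  expect_error(skewness_screen(rep(3, 10)), "zero variance")
  expect_error(skewness_screen(c(1, 2)), "n >= 3")
})

test_that("correlation screen computes r, p and flags significant pairs", {
  d <- data.frame(a = 1:10, b = 2 * (1:10))
  cs <- correlation_screen(d)
  expect_equal(cs$r["a", "b"], 1)
  expect_lt(cs$p["a", "b"], 1e-10)
  expect_equal(nrow(cs$flagged), 1L)

  # the ancillary soil properties are uncorrelated with the metals in the
  # bundled assay table (computed, not assumed)
  tab <- assay_table()
  cs2 <- correlation_screen(tab[, c("cu", "pb", "ec", "ph")])
  anc <- expand.grid(m = c("cu", "pb"), v = c("ec", "ph"),
                     stringsAsFactors = FALSE)
  for (k in seq_len(nrow(anc))) {
    expect_gt(cs2$p[anc$m[k], anc$v[k]], 0.05)
  }
  expect_error(correlation_screen(data.frame(a = rep(1, 5), b = 1:5)),
               "constant")
})

test_that("correlation screen holds its nominal type-I rate", {
  set.seed(123)
  hits <- 0L
  n_rep <- 1000
  for (r in seq_len(n_rep)) {
    d <- data.frame(a = rnorm(20), b = rnorm(20))
    if (correlation_screen(d)$p["a", "b"] < 0.05) hits <- hits + 1L
  }
  expect_equal(hits / n_rep, 0.05, tolerance = 0.4)  # binomial MC slack
})

test_that("LOO with constant data gives zero errors", {
  s <- random_sample_set(6, seed = 71)
  s$value <- rep(30, 6)
  m <- variogram_model("gaussian", 0.1, 1, 40, sill_is_total = FALSE)
  rep_ <- cross_validate_loo(s, m, method = "ok")
  expect_equal(rep_$me, 0, tolerance = 1e-10)
  expect_equal(rep_$rmse, 0, tolerance = 1e-10)
})

test_that("LOO under a pure-nugget model is leave-one-out mean prediction", {
  s <- random_sample_set(9, seed = 72)
  pure <- variogram_model("gaussian", 1, 0, 40, sill_is_total = FALSE)
  rep_ <- cross_validate_loo(s, pure, method = "ok")
  res <- vapply(seq_len(9), function(i) s$value[i] - mean(s$value[-i]), 0)
  expect_equal(rep_$me, mean(res), tolerance = 1e-9)
  expect_equal(rep_$rmse, sqrt(mean(res^2)), tolerance = 1e-9)
})

test_that("LOO agrees with a per-fold brute-force oracle", {
  s <- random_sample_set(12, seed = 73)
  m <- variogram_model("gaussian", 0.4, 2.6, 70, sill_is_total = FALSE)
  rep_ <- cross_validate_loo(s, m, method = "ok")
  res <- vapply(seq_len(12), function(i) {
    o <- oracle_ok(s$x[-i], s$y[-i], s$value[-i], gamma_fun_of(m),
                   s$x[i], s$y[i])
    s$value[i] - o$estimate
  }, 0)
  expect_equal(rep_$me, mean(res), tolerance = 1e-8)
  expect_equal(rep_$rmse, sqrt(mean(res^2)), tolerance = 1e-8)
  expect_gte(rep_$rmse, abs(rep_$me))
})

test_that("co-kriging LOO keeps the secondary set and returns finite metrics", {
  lmc <- random_lmc(81)
  p <- random_sample_set(6, seed = 82)
  s <- random_sample_set(15, seed = 83)
  s$instrument <- "secondary"
  rep_ <- cross_validate_loo(p, method = "ck", lmc = lmc, secondary = s)
  expect_true(is.finite(rep_$me) && is.finite(rep_$rmse))
  expect_equal(rep_$n, 6L)
})

test_that("holdout validation scores predictors and degenerate cases", {
  val <- random_sample_set(8, seed = 91)
  val$role <- "validation"
  perfect <- function(x, y) val$value[match(paste(x, y),
                                            paste(val$x, val$y))]
  r1 <- validate_holdout(perfect, val)
  expect_equal(r1$rmse, 0)
  expect_equal(r1$pearson_r, 1)

  expect_warning(r2 <- validate_holdout(function(x, y) rep(5, length(x)), val),
                 "undefined")
  expect_true(is.na(r2$pearson_r))
  expect_gte(r2$rmse, abs(r2$me))

  # prediction_grid predictor uses nearest-cell lookup
  g <- prediction_grid(grid_spec(0, 0, 100, 1, 1), matrix(50))
  r3 <- suppressWarnings(validate_holdout(g, val))
  expect_equal(r3$me, mean(val$value) - 50)
})
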