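#' Configuration of one mapping approach
#'
#' The four approaches compared by the package:
#' \describe{
#'   \item{1}{ordinary kriging of the sparse primary (lab) data alone;}
#'   \item{2}{ordinary kriging of the dense secondary (field) data alone, on
#'     its own biased scale;}
#'   \item{3}{linear calibration of the secondary onto the primary scale,
#'     primary-preference merge, then ordinary kriging of the fused set;}
#'   \item{4}{ordinary co-kriging with the primary as target variable and the
#'     secondary as covariable.}
#' }
#'
#' @param approach_id 1-4.
#' @param analyte `"Cu"` or `"Pb"`.
#' @param variograms `NULL` to fit from the data, or an explicit
#'   [variogram_model()] (approaches 1-3) / [cross_variogram_model()]
#'   (approach 4) on the analysis (possibly log) scale.
#' @param log_transform `"auto"` (apply logs when the skewness screen
#'   recommends them), `TRUE`, or `FALSE`.
#' @param grid a [grid_spec()] for the output map, or `NULL` for no map.
#' @param back_transform `"unbiased"` (default; the approximately unbiased
#'   lognormal-kriging back-transform, the GIS-workflow convention) or
#'   `"naive_exp"` (median-type `exp(z*)`). The choice matters: the naive
#'   back-transform under-predicts on the original scale, which flatters a
#'   positively biased instrument in validation comparisons.
#' @param model_type variogram model family used when fitting from data.
#' @param azimuth major-axis azimuth for anisotropic fits (approaches 2-3);
#'   `NULL` for isotropic fitting.
#' @param colocation_tolerance metres, for calibration pairs and the merge.
#' @param seed seed recorded for reproducibility.
#' @return an `approach_config` list.
#' @export
approach_config <- function(approach_id, analyte = "Cu", variograms = NULL,
                            log_transform = "auto", grid = NULL,
                            back_transform = "unbiased",
                            model_type = "gaussian", azimuth = 115,
                            colocation_tolerance = 0.5, seed = 1L) {
  stopifnot(approach_id %in% 1:4)
  structure(list(approach_id = approach_id, analyte = analyte,
                 variograms = variograms, log_transform = log_transform,
                 grid = grid, back_transform = back_transform,
                 model_type = model_type, azimuth = azimuth,
                 colocation_tolerance = colocation_tolerance, seed = seed),
            class = "approach_config")
}

# omnidirectional isotropic fit, or two directional variograms + fixed-azimuth
# anisotropic fit; falls back to the isotropic fit when the directional bins
# are too sparse. The fitted nugget is floored at 1% of the partial sill:
# gaussian-model kriging matrices with a (near-)zero nugget are numerically
# singular at realistic survey sizes
fit_variogram_from_data <- function(samples, model_type = "gaussian",
                                    azimuth = NULL, n_lags = 10) {
  fit <- local({
    omni <- experimental_variogram(samples, n_lags = n_lags)
    if (is.null(azimuth)) return(fit_variogram(omni, model_type))
    vlist <- tryCatch({
      list(experimental_variogram(samples, n_lags = n_lags, direction = azimuth),
           experimental_variogram(samples, n_lags = n_lags,
                                  direction = azimuth + 90))
    }, error = function(e) NULL)
    if (is.null(vlist) || any(vapply(vlist, nrow, 1L) < 3L)) {
      return(fit_variogram(omni, model_type))
    }
    fit_variogram(vlist, model_type, fixed_azimuth = azimuth)
  })
  stabilize_nugget(fit)
}

stabilize_nugget <- function(model, floor_frac = 0.01) {
  model$nugget <- max(model$nugget, floor_frac * abs(model$partial_sill))
  model
}

# weighted linear LS for (nugget, partial sill) with the ranges held fixed;
# the model is linear in both once the range is known
fit_sills_given_range <- function(exp_v, model_type, range_major,
                                  range_minor = range_major, azimuth = 0) {
  shape <- variogram_model(model_type, 0, 1, range_major, range_minor,
                           azimuth, sill_is_total = FALSE)
  th <- azimuth * pi / 180
  g0 <- model_gamma(shape, exp_v$lag_center * sin(th),
                    exp_v$lag_center * cos(th))
  w <- exp_v$n_pairs
  X <- cbind(1, g0)
  beta <- tryCatch(
    solve(crossprod(X, w * X), crossprod(X, w * exp_v$gamma)),
    error = function(e) matrix(c(0, max(mean(exp_v$gamma), 1e-8)), 2))
  nugget <- max(beta[1], 0)
  psill <- max(beta[2], 1e-8)
  variogram_model(model_type, nugget, psill, range_major, range_minor,
                  azimuth, sill_is_total = FALSE)
}

#' Fit a pragmatic coregionalization model from dual-instrument data
#'
#' Constructs a valid LMC for co-kriging the way a primary-variable-led
#' workflow does it: the primary (target) variable's direct variogram is
#' fitted first — isotropically, since a dozen lab samples cannot support
#' directional variography — and its range becomes the shared range of all
#' three structures; the secondary's sills are then re-estimated at that
#' range by weighted linear least squares, and the cross partial sill is set
#' proportionally to the co-located correlation,
#' `c12 = rho * sqrt(c11 * c22)` (|rho| capped at 0.97: at rho -> 1 with
#' co-located points the co-kriging matrix loses rank), with zero
#' cross-nugget. With only a dozen co-located pairs a free WLS fit of the
#' cross-structure is unstable; tying it to the co-located correlation keeps
#' the model positive semi-definite by construction. Note the sparse primary
#' variography limits the whole model — the structural reason co-kriging
#' underperforms calibration fusion when the primary set is small.
#'
#' @param primary,secondary [sample_set()]s on the analysis scale.
#' @param model_type variogram family.
#' @param colocation_tolerance metres.
#' @return a [cross_variogram_model()] passing [check_lmc()].
#' @export
fit_lmc_from_data <- function(primary, secondary, model_type = "gaussian",
                              colocation_tolerance = 0.5) {
  direct_primary <- fit_variogram_from_data(primary, model_type)
  exp_s <- experimental_variogram(secondary, n_lags = 10)
  direct_secondary <- stabilize_nugget(fit_sills_given_range(
    exp_s, model_type, direct_primary$range_major,
    direct_primary$range_minor, direct_primary$azimuth_major))
  # cross partial sill: WLS on the experimental cross-variogram of the
  # co-located pairs (zero cross-nugget, one free sill at the shared range),
  # then clipped inside the Cauchy-Schwarz bound so the LMC stays valid;
  # falls back to the co-located correlation when pairs are too few
  c_max <- 0.97 * sqrt(direct_primary$partial_sill *
                       direct_secondary$partial_sill)
  c12 <- tryCatch({
    xv <- experimental_cross_variogram(primary, secondary, n_lags = 8,
                                       colocation_tolerance = colocation_tolerance)
    shape <- variogram_model(model_type, 0, 1, direct_primary$range_major,
                             direct_primary$range_minor,
                             direct_primary$azimuth_major,
                             sill_is_total = FALSE)
    th <- direct_primary$azimuth_major * pi / 180
    g0 <- model_gamma(shape, xv$lag_center * sin(th), xv$lag_center * cos(th))
    sum(xv$n_pairs * g0 * xv$gamma) / sum(xv$n_pairs * g0^2)
  }, error = function(e) {
    m <- match_colocated(primary, secondary, colocation_tolerance)
    if (nrow(m) >= 3) {
      stats::cor(primary$value[m$i], secondary$value[m$j]) *
        sqrt(direct_primary$partial_sill * direct_secondary$partial_sill)
    } else 0.9 * sqrt(direct_primary$partial_sill *
                      direct_secondary$partial_sill)
  })
  # |c12| capped below the bound: at full correlation with co-located points
  # the co-kriging matrix loses rank
  c12 <- sign(c12) * min(abs(c12), c_max)
  cross <- variogram_model(model_type, 0, c12,
                           direct_primary$range_major,
                           direct_primary$range_minor,
                           direct_primary$azimuth_major,
                           sill_is_total = FALSE)
  cross_variogram_model(direct_primary, direct_secondary, cross)
}

#' Run one mapping approach end to end
#'
#' Selects/constructs the input data for the approach, decides the log
#' transform (skewness screen in `"auto"` mode, applied consistently to
#' kriging and back-transform), obtains variogram models (fitted from the
#' data unless supplied), and produces the map plus leave-one-out and holdout
#' validation reports.
#'
#' @param config an [approach_config()].
#' @param primary,secondary,validation [sample_set()]s on the raw mg/kg scale
#'   (secondary may be `NULL` for approach 1; validation may be `NULL` to skip
#'   holdout scoring).
#' @param compute_grid,compute_loo switches to skip the map or the
#'   leave-one-out pass (used by replicate studies for speed).
#' @return list with `grid` ([prediction_grid()] or `NULL`), `loo` and
#'   `holdout` (`validation_report`s), `predictor` (vectorized
#'   `f(x, y) -> mg/kg`), `models`, `calibration` (approach 3), `used_log`.
#' @export
run_approach <- function(config, primary, secondary = NULL, validation = NULL,
                         compute_grid = TRUE, compute_loo = TRUE) {
  stopifnot(inherits(config, "approach_config"))
  id <- config$approach_id
  if (id %in% 2:4 && is.null(secondary)) {
    stop("approach ", id, " requires secondary data")
  }
  if (id == 4 && !is.null(config$variograms) &&
      !inherits(config$variograms, "cross_variogram_model")) {
    stop("approach 4 requires a cross_variogram_model in config$variograms")
  }
  calibration <- NULL
  if (id == 1) {
    train <- primary
  } else if (id == 2) {
    train <- secondary
  } else if (id == 3) {
    pairs <- colocated_pairs(primary, secondary, config$colocation_tolerance)
    if (nrow(pairs) < 2) stop("approach 3 requires co-located calibration pairs")
    calibration <- fit_calibration(pairs)
    trans <- transform_secondary(calibration, secondary)
    train <- merge_primary_preference(primary, trans,
                                      config$colocation_tolerance)
  } else {
    train <- primary
  }

  use_log <- switch(as.character(config$log_transform),
    "auto" = skewness_screen(train$value)$recommend_log,
    "TRUE" = TRUE, "FALSE" = FALSE, isTRUE(config$log_transform))
  to_analysis <- function(s) if (use_log) log_transform(s) else s
  from_analysis <- if (use_log) exp else identity

  if (id == 4) {
    p_an <- to_analysis(primary); s_an <- to_analysis(secondary)
    lmc <- config$variograms %||%
      fit_lmc_from_data(p_an, s_an, config$model_type,
                        config$colocation_tolerance)
    predictor <- function(x, y) {
      from_analysis(cokrige_points(p_an, s_an, lmc, x, y,
                                   skip_lmc_check = TRUE)$estimate)
    }
    grid <- NULL
    if (compute_grid && !is.null(config$grid)) {
      g <- cokrige_grid(p_an, s_an, lmc, config$grid, skip_lmc_check = TRUE)
      g$estimates <- from_analysis(g$estimates)
      grid <- g
    }
    loo <- if (compute_loo) {
      cross_validate_loo(primary, method = if (use_log) "ck-log" else "ck",
                         lmc = lmc, secondary = secondary,
                         approach_id = id, analyte = config$analyte)
    }
    models <- lmc
  } else {
    t_an <- to_analysis(train)
    azim <- if (id == 1) NULL else config$azimuth
    model <- config$variograms %||%
      fit_variogram_from_data(t_an, config$model_type, azimuth = azim)
    predictor <- function(x, y) {
      p <- krige_points(t_an, model, x, y)
      if (use_log) backtransform_log(p, config$back_transform) else p$estimate
    }
    grid <- NULL
    if (compute_grid && !is.null(config$grid)) {
      grid <- if (use_log) {
        krige_lognormal(train, model, config$grid, config$back_transform)
      } else {
        krige_grid(train, model, config$grid)
      }
    }
    loo <- if (compute_loo) {
      cross_validate_loo(train, model,
                         method = if (use_log) "ok-log" else "ok",
                         back_transform = config$back_transform,
                         approach_id = id, analyte = config$analyte)
    }
    models <- model
  }
  holdout <- if (!is.null(validation)) {
    validate_holdout(predictor, validation, approach_id = id)
  }
  list(grid = grid, loo = loo, holdout = holdout, predictor = predictor,
       models = models, calibration = calibration, used_log = use_log)
}

#' Rank approaches by holdout error
#'
#' Sorts validation reports by RMSE ascending, breaking ties by |ME| then by
#' approach id, and returns a machine-readable ranking table.
#'
#' @param reports list of `validation_report`s sharing analyte and mode.
#' @return data frame `rank, approach_id, analyte, mode, me, rmse, pearson_r, n`.
#' @export
compare_approaches <- function(reports) {
  stopifnot(length(reports) >= 2L)
  an <- unique(vapply(reports, `[[`, "", "analyte"))
  if (length(an) != 1L) stop("cannot rank reports of mixed analytes: ",
                             paste(an, collapse = ", "))
  md <- unique(vapply(reports, `[[`, "", "mode"))
  if (length(md) != 1L) stop("cannot rank reports of mixed validation modes")
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(approach_id = r$approach_id, analyte = r$analyte, mode = r$mode,
               me = r$me, rmse = r$rmse, pearson_r = r$pearson_r, n = r$n)
  }))
  df <- df[order(df$rmse, abs(df$me), df$approach_id), ]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}

#' Replicated synthetic comparison of the four approaches
#'
#' Draws `n_replicates` independent surveys from the scenario, runs all four
#' approaches on each (holdout scoring only), and tallies which approach wins
#' (lowest holdout RMSE) and which loses (highest) per replicate. This is the
#' package's stochastic surrogate for the field comparison: with a sparse
#' accurate instrument and a dense biased one, calibration fusion (approach 3)
#' should win and kriging the sparse data alone (approach 1) should lose in a
#' majority of replicates.
#'
#' @param config a [scenario_config()].
#' @param n_replicates number of independent surveys.
#' @param seed base seed; replicate r uses seeds `seed + 2r`, `seed + 2r + 1`.
#' @param approaches subset of 1:4 to run.
#' @return list with `rmse` (replicate x approach matrix), `wins` and `losses`
#'   (named counts), and `rankings` (list of per-replicate orderings).
#' @export
replicate_study <- function(config = scenario_config(), n_replicates = 50,
                            seed = config$seed, approaches = 1:4) {
  sim <- field_simulator(config)
  rmse <- matrix(NA_real_, n_replicates, length(approaches),
                 dimnames = list(NULL, paste0("approach_", approaches)))
  rankings <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    truth <- sim(seed + 2 * r)
    svy <- sample_survey(truth, config, seed + 2 * r + 1)
    reports <- list()
    for (k in seq_along(approaches)) {
      a <- approaches[k]
      cfg <- approach_config(a, analyte = config$analyte,
                             azimuth = config$field_model$azimuth_major)
      res <- tryCatch(
        run_approach(cfg, svy$primary, svy$secondary, svy$validation,
                     compute_grid = FALSE, compute_loo = FALSE),
        error = function(e) NULL)
      if (!is.null(res)) {
        rmse[r, k] <- res$holdout$rmse
        reports[[length(reports) + 1L]] <- res$holdout
      }
    }
    if (length(reports) >= 2) {
      rankings[[r]] <- compare_approaches(reports)$approach_id
    }
  }
  win <- apply(rmse, 1, function(v) approaches[which.min(v)])
  lose <- apply(rmse, 1, function(v) approaches[which.max(v)])
  tally <- function(x) {
    t <- table(factor(x, levels = approaches))
    stats::setNames(as.integer(t), paste0("approach_", approaches))
  }
  list(rmse = rmse, wins = tally(win), losses = tally(lose),
       rankings = rankings)
}
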