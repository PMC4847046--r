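#' Descriptive summary of assay values
#'
#' @param values numeric vector (mg/kg, uS/cm, ...).
#' @return list with `min`, `max`, `mean`, `sd` (n-1 denominator; `NA` for
#'   n < 2) and `n`.
#' @export
summary_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("empty input")
  list(min = min(values), max = max(values), mean = mean(values),
       sd = if (length(values) >= 2L) stats::sd(values) else NA_real_,
       n = length(values))
}

#' Skewness screen for the log-transform decision
#'
#' Computes the adjusted Fisher-Pearson sample skewness
#' `G1 = sqrt(n(n-1))/(n-2) * m3/m2^(3/2)` and recommends a natural-log
#' transform when the distribution is clearly positively skewed
#' (`G1 > threshold`). The variogram is sensitive to strong departures from
#' normality because a few large values dominate the squared differences;
#' logging strongly right-skewed concentrations stabilizes it.
#'
#' @param values numeric vector, n >= 3.
#' @param threshold skewness above which a log transform is recommended.
#' @return list with `skewness` and `recommend_log`.
#' @export
skewness_screen <- function(values, threshold = 1.0) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L) stop("skewness needs n >= 3")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop("skewness undefined: zero variance")
  g1 <- mean((values - m)^3) / m2^1.5
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  list(skewness = G1, recommend_log = G1 > threshold)
}

#' Pairwise correlation screen
#'
#' Pearson correlations with two-sided t-test p-values for every column pair
#' of an assay table (e.g. Cu, Pb, EC, pH), flagging pairs significant at
#' `alpha`. Used to check whether ancillary soil properties co-vary with the
#' contaminants.
#'
#' @param table data frame of numeric columns; complete cases are used.
#' @param alpha significance level for flagging.
#' @return list with matrices `r` and `p`, and data frame `flagged`
#'   (pairs with p < alpha).
#' @export
correlation_screen <- function(table, alpha = 0.05) {
  table <- as.data.frame(table)
  table <- table[stats::complete.cases(table), , drop = FALSE]
  if (nrow(table) < 3L) stop("correlation screen needs >= 3 complete cases")
  if (any(vapply(table, stats::sd, 1) == 0)) stop("constant column in table")
  k <- ncol(table)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(names(table), names(table)))
  flagged <- data.frame(var1 = character(), var2 = character(),
                        r = numeric(), p = numeric())
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    ct <- stats::cor.test(table[[i]], table[[j]])
    r[i, j] <- unname(ct$estimate); p[i, j] <- ct$p.value
    if (i < j && ct$p.value < alpha) {
      flagged <- rbind(flagged, data.frame(var1 = names(table)[i],
                                           var2 = names(table)[j],
                                           r = unname(ct$estimate),
                                           p = ct$p.value))
    }
  }
  list(r = r, p = p, flagged = flagged)
}

validation_report <- function(approach_id, analyte, mode, me, rmse,
                              pearson_r = NA_real_, n = NA_integer_) {
  structure(list(approach_id = approach_id, analyte = analyte, mode = mode,
                 me = me, rmse = rmse, pearson_r = pearson_r, n = n),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> approach %s, %s, %s: ME %.4g, RMSE %.4g%s (n = %d)\n",
              as.character(x$approach_id), x$analyte, x$mode, x$me, x$rmse,
              if (is.na(x$pearson_r)) "" else sprintf(", R %.3f", x$pearson_r),
              x$n))
  invisible(x)
}

#' Leave-one-out cross-validation of a kriging configuration
#'
#' Withholds each training point in turn and predicts it from the rest with
#' the *same* variogram parameters (no per-fold refit: the model is treated as
#' a fixed description of spatial structure, the convention when a single
#' fitted parameter set is reported per map). Mean error uses the
#' observed - predicted sign convention, so positive ME means underestimation.
#' Errors are computed in mg/kg: for `"ok-log"`, predictions are
#' back-transformed before the residual is formed. For `"ck"` only the primary
#' point is withheld; the secondary set stays intact.
#'
#' @param samples training [sample_set()] (raw mg/kg scale).
#' @param model a [variogram_model()] (log-scale model for `"ok-log"`;
#'   ignored for the co-kriging methods, which use `lmc`).
#' @param method `"ok"`, `"ok-log"`, `"ck"` or `"ck-log"` (co-kriging of the
#'   logs with a naive exp back-transform).
#' @param lmc,secondary required when `method` is `"ck"` / `"ck-log"`
#'   (`secondary` on the raw scale; it is logged internally for `"ck-log"`).
#' @param back_transform back-transform for `"ok-log"`.
#' @param approach_id,analyte labels carried into the report.
#' @return a `validation_report` with `mode = "cross_validation"`.
#' @export
cross_validate_loo <- function(samples, model = NULL,
                               method = c("ok", "ok-log", "ck", "ck-log"),
                               lmc = NULL, secondary = NULL,
                               back_transform = "naive_exp",
                               approach_id = NA, analyte = attr(samples, "analyte")) {
  method <- match.arg(method)
  if (method %in% c("ck", "ck-log") && (is.null(lmc) || is.null(secondary))) {
    stop("method '", method, "' needs lmc and secondary")
  }
  sec_use <- if (method == "ck-log") log_transform(secondary) else secondary
  n <- nrow(samples)
  if (n < 3L) stop("leave-one-out needs at least 3 samples")
  pred <- rep(NA_real_, n)
  skipped <- 0L
  for (i in seq_len(n)) {
    train <- samples[-i, ]
    target <- c(samples$x[i], samples$y[i])
    p <- tryCatch({
      if (method == "ok") {
        krige_points(train, model, target[1], target[2])$estimate
      } else if (method == "ok-log") {
        pl <- krige_points(log_transform(train), model, target[1], target[2])
        backtransform_log(pl, back_transform)
      } else if (method == "ck") {
        cokrige_points(train, sec_use, lmc, target[1], target[2],
                       skip_lmc_check = TRUE)$estimate
      } else {
        exp(cokrige_points(log_transform(train), sec_use, lmc,
                           target[1], target[2],
                           skip_lmc_check = TRUE)$estimate)
      }
    }, error = function(e) NA_real_)
    if (is.na(p)) skipped <- skipped + 1L else pred[i] <- p
  }
  if (skipped > 0) {
    warning(skipped, " leave-one-out fold(s) skipped (singular system)")
  }
  ok <- !is.na(pred)
  res <- samples$value[ok] - pred[ok]
  validation_report(approach_id, analyte, "cross_validation",
                    me = mean(res), rmse = sqrt(mean(res^2)), n = sum(ok))
}

#' Score predictions against an independent validation set
#'
#' Predicts at the exact validation coordinates (avoiding raster
#' discretization error) and reports ME, RMSE and the Pearson correlation
#' between observed and predicted values, the standard scorecard for
#' comparing interpolation strategies on hold-out assays.
#'
#' @param predictor either a function `f(x, y) -> predicted mg/kg` (vectorized)
#'   or a [prediction_grid()] (nearest-cell lookup).
#' @param validation a [sample_set()] of hold-out assays (raw mg/kg).
#' @param approach_id label carried into the report.
#' @return a `validation_report` with `mode = "holdout"`; `pearson_r` is `NA`
#'   with a warning when the predictions are constant.
#' @export
validate_holdout <- function(predictor, validation, approach_id = NA) {
  stopifnot(inherits(validation, "sample_set"))
  if (nrow(validation) < 1L) stop("empty validation set")
  pred <- if (is.function(predictor)) {
    predictor(validation$x, validation$y)
  } else if (inherits(predictor, "prediction_grid")) {
    grid_lookup(predictor, validation$x, validation$y)
  } else {
    stop("predictor must be a function or a prediction_grid")
  }
  res <- validation$value - pred
  r <- if (stats::sd(pred) == 0 || stats::sd(validation$value) == 0) {
    warning("constant predictions or observations: Pearson R undefined")
    NA_real_
  } else {
    stats::cor(validation$value, pred)
  }
  validation_report(approach_id, attr(validation, "analyte"), "holdout",
                    me = mean(res), rmse = sqrt(mean(res^2)),
                    pearson_r = r, n = nrow(validation))
}

# nearest-cell raster lookup
grid_lookup <- function(grid, x, y) {
  s <- grid$spec
  col <- pmin(pmax(floor((x - s$x_min) / s$cell_size) + 1L, 1L), s$n_cols)
  row <- pmin(pmax(floor((y - s$y_min) / s$cell_size) + 1L, 1L), s$n_rows)
  grid$estimates[cbind(row, col)]
}
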