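#' Fit a linear inter-instrument calibration
#'
#' Ordinary least squares of the accurate primary assay on the rapid secondary
#' assay (`primary = slope * secondary + intercept`), the inverse-calibration
#' direction: the fitted line is used to predict primary-equivalent values
#' from secondary readings. A Deming (errors-in-variables) option is provided
#' for when the secondary noise is too large to ignore in the regression.
#'
#' @param pairs data frame with columns `secondary` and `primary` (co-located
#'   assay pairs, mg/kg), or two-column matrix in that order.
#' @param method `"ols"` (default) or `"deming"` (variance-ratio 1).
#' @return a `calibration_model`: list with `slope`, `intercept`, `r_squared`,
#'   `n_pairs`, `analyte`, `method`.
#' @export
fit_calibration <- function(pairs, method = c("ols", "deming")) {
  method <- match.arg(method)
  pairs <- as.data.frame(pairs)
  if (!all(c("secondary", "primary") %in% names(pairs))) {
    names(pairs)[1:2] <- c("secondary", "primary")
  }
  u <- pairs$secondary; z <- pairs$primary
  if (length(u) < 2L) stop("calibration needs at least 2 pairs")
  if (stats::sd(u) == 0) {
    stop("degenerate calibration design: all secondary values identical")
  }
  if (method == "ols") {
    fit <- stats::lm(z ~ u)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    # computed directly: summary.lm() warns on exact fits
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((z - mean(z))^2)
  } else {
    # Deming with error-variance ratio 1 (orthogonal regression)
    sxx <- stats::var(u); syy <- stats::var(z); sxy <- stats::cov(u, z)
    slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
    intercept <- mean(z) - slope * mean(u)
    r2 <- stats::cor(u, z)^2
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 n_pairs = length(u),
                 analyte = attr(pairs, "analyte") %||% NA_character_,
                 method = method),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> primary = %.4g * secondary + %.4g (R2 = %.4f, n = %d, %s)\n",
              x$slope, x$intercept, x$r_squared, x$n_pairs, x$method))
  invisible(x)
}

#' Map secondary assays onto the primary scale
#'
#' Applies `slope * value + intercept` to every point of a secondary sample
#' set. Calibrated values driven to zero or below are floored at
#' `min_value` (concentrations must stay positive for log-scale work); the
#' number of floored points is reported via a message.
#'
#' @param cal a [fit_calibration()] model.
#' @param secondary a secondary-instrument [sample_set()].
#' @param min_value floor for non-positive calibrated values, mg/kg.
#' @return a [sample_set()] of calibrated values (instrument label kept as
#'   `"secondary"` so provenance is preserved).
#' @export
transform_secondary <- function(cal, secondary, min_value = 1) {
  stopifnot(inherits(cal, "calibration_model"), inherits(secondary, "sample_set"))
  if (!is.na(cal$analyte) && cal$analyte != attr(secondary, "analyte")) {
    stop("calibration analyte (", cal$analyte, ") does not match sample set (",
         attr(secondary, "analyte"), ")")
  }
  v <- cal$slope * secondary$value + cal$intercept
  n_floor <- sum(v <= 0)
  if (n_floor > 0) {
    message(n_floor, " calibrated value(s) <= 0 floored at ", min_value, " mg/kg")
    v[v <= 0] <- min_value
  }
  out <- secondary
  out$value <- v
  out
}

#' Merge primary and calibrated secondary data with primary preference
#'
#' Union of the two point sets in which the primary (accurate) assay wins
#' wherever both instruments measured the same location: any secondary point
#' within `colocation_tolerance` of a primary point is dropped. Provenance is
#' retained in the `instrument` column of the merged set. The operation is
#' idempotent.
#'
#' @param primary,transformed_secondary [sample_set()]s of the same analyte.
#' @param colocation_tolerance metres; default 0.5 m treats survey re-occupations
#'   of the same station as co-located.
#' @return a merged [sample_set()].
#' @export
merge_primary_preference <- function(primary, transformed_secondary,
                                     colocation_tolerance = 0.5) {
  stopifnot(inherits(primary, "sample_set"),
            inherits(transformed_secondary, "sample_set"))
  if (attr(primary, "analyte") != attr(transformed_secondary, "analyte")) {
    stop("analyte mismatch between primary and secondary sets")
  }
  keep <- vapply(seq_len(nrow(transformed_secondary)), function(j) {
    d <- sqrt((primary$x - transformed_secondary$x[j])^2 +
              (primary$y - transformed_secondary$y[j])^2)
    all(d > colocation_tolerance)
  }, logical(1))
  merged <- rbind(as.data.frame(primary),
                  as.data.frame(transformed_secondary[keep, ]))
  rownames(merged) <- NULL
  structure(merged,
            analyte = attr(primary, "analyte"),
            log_transformed = attr(primary, "log_transformed"),
            class = c("sample_set", "data.frame"))
}

#' Extract co-located assay pairs from two sample sets
#'
#' @param primary,secondary [sample_set()]s.
#' @param tolerance co-location tolerance in metres.
#' @return data frame with `secondary`, `primary` value columns (and the
#'   matched coordinates), suitable for [fit_calibration()].
#' @export
colocated_pairs <- function(primary, secondary, tolerance = 0.5) {
  m <- match_colocated(primary, secondary, tolerance)
  out <- data.frame(x = primary$x[m$i], y = primary$y[m$i],
                    secondary = secondary$value[m$j],
                    primary = primary$value[m$i])
  attr(out, "analyte") <- attr(primary, "analyte")
  out
}
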