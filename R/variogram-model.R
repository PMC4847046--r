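#' Theoretical variogram model with geometric anisotropy
#'
#' Parameterizes gamma(h) by a nugget, a partial sill, and a major/minor range
#' pair with an azimuth. Geometric anisotropy: the lag vector is rotated into
#' the (major, minor) frame and scaled by the two ranges to an isotropic
#' effective distance. Azimuths are degrees clockwise from north (grid +y),
#' the usual geostatistical convention.
#'
#' `sill` is interpreted as the *total* sill (nugget + partial sill) when
#' `sill_is_total = TRUE` (the default, the common reporting convention in GIS
#' software), otherwise as the partial sill alone. A negative cross-structure
#' sill is permitted so the same class can carry cross-variograms.
#'
#' @param model_type `"gaussian"`, `"spherical"`, or `"exponential"`.
#' @param nugget nugget variance (>= 0; `NA` is treated as 0 for
#'   cross-structures reported as "N/A").
#' @param sill sill (see `sill_is_total`).
#' @param range_major practical range along the major axis, metres (> 0).
#' @param range_minor practical range along the minor axis; defaults to
#'   `range_major` (isotropic).
#' @param azimuth_major azimuth of the major axis, degrees clockwise from north.
#' @param sill_is_total logical; how to read `sill`.
#' @return a `variogram_model` object with fields `model_type, nugget,
#'   partial_sill, range_major, range_minor, azimuth_major`.
#' @export
variogram_model <- function(model_type = c("gaussian", "spherical", "exponential"),
                            nugget, sill, range_major,
                            range_minor = range_major,
                            azimuth_major = 0,
                            sill_is_total = TRUE) {
  model_type <- match.arg(model_type)
  if (is.na(nugget)) nugget <- 0
  partial_sill <- if (sill_is_total) sill - nugget else sill
  if (nugget < 0) stop("nugget must be >= 0")
  if (sill_is_total && abs(partial_sill) > 0 && partial_sill < 0) {
    stop("total sill smaller than nugget")
  }
  if (range_major <= 0 || range_minor <= 0) stop("ranges must be > 0")
  if (range_minor > range_major + 1e-12) {
    stop("range_minor must not exceed range_major")
  }
  structure(list(model_type = model_type, nugget = nugget,
                 partial_sill = partial_sill,
                 range_major = range_major, range_minor = range_minor,
                 azimuth_major = azimuth_major),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  aniso <- if (x$range_major == x$range_minor) "isotropic" else
    sprintf("anisotropic (az %.4g deg)", x$azimuth_major)
  cat(sprintf("<variogram_model> %s, nugget %.4g, partial sill %.4g, range %.4g/%.4g m, %s\n",
              x$model_type, x$nugget, x$partial_sill,
              x$range_major, x$range_minor, aniso))
  invisible(x)
}

# effective isotropic distance of lag vectors under geometric anisotropy;
# 1 corresponds to the practical range in every direction
effective_distance <- function(model, dx, dy) {
  th <- model$azimuth_major * pi / 180
  h_maj <- dx * sin(th) + dy * cos(th)
  h_min <- dx * cos(th) - dy * sin(th)
  sqrt((h_maj / model$range_major)^2 + (h_min / model$range_minor)^2)
}

#' Evaluate a variogram model at lag vectors
#'
#' Practical-range convention: gamma reaches ~95% of the sill at the stated
#' range for the gaussian (`1 - exp(-3 he^2)`) and exponential
#' (`1 - exp(-3 he)`) forms, and exactly the sill for the spherical form.
#' gamma(0) = 0 exactly: the nugget is a discontinuity applying only to h > 0,
#' which makes kriging an exact interpolator at data locations.
#'
#' @param model a [variogram_model()].
#' @param dx,dy lag-vector components in metres (vectorized).
#' @return semivariances, same length as `dx`.
#' @export
model_gamma <- function(model, dx, dy) {
  stopifnot(inherits(model, "variogram_model"))
  he <- effective_distance(model, dx, dy)
  g <- switch(model$model_type,
    gaussian    = model$partial_sill * (1 - exp(-3 * he^2)),
    exponential = model$partial_sill * (1 - exp(-3 * he)),
    spherical   = model$partial_sill *
      ifelse(he >= 1, 1, 1.5 * he - 0.5 * he^3)
  )
  out <- model$nugget + g
  out[he == 0] <- 0
  out
}

#' Coregionalization model for co-kriging
#'
#' Bundles the two direct variograms and the cross-variogram of a primary /
#' secondary instrument pair. A valid linear model of coregionalization (LMC)
#' requires the three structures to share model type, ranges and azimuth, and
#' the coregionalization matrix per structure to be positive semi-definite.
#'
#' @param direct_primary,direct_secondary,cross [variogram_model()] objects.
#' @return a `cross_variogram_model` object.
#' @export
cross_variogram_model <- function(direct_primary, direct_secondary, cross) {
  for (m in list(direct_primary, direct_secondary, cross)) {
    stopifnot(inherits(m, "variogram_model"))
  }
  structure(list(direct_primary = direct_primary,
                 direct_secondary = direct_secondary,
                 cross = cross),
            class = "cross_variogram_model")
}

#' Check linear-model-of-coregionalization validity
#'
#' Verifies that the three structures share type/ranges/azimuth and that both
#' the nugget and partial-sill coregionalization matrices satisfy the
#' Cauchy-Schwarz condition `|c12| <= sqrt(c11 * c22)`.
#'
#' @param lmc a [cross_variogram_model()].
#' @return list with `valid` (logical) and `violations` (character vector).
#' @export
check_lmc <- function(lmc) {
  stopifnot(inherits(lmc, "cross_variogram_model"))
  p <- lmc$direct_primary; s <- lmc$direct_secondary; x <- lmc$cross
  v <- character()
  if (length(unique(c(p$model_type, s$model_type, x$model_type))) != 1L) {
    v <- c(v, "model types differ across structures")
  }
  if (max(abs(c(p$range_major - s$range_major, p$range_major - x$range_major))) > 1e-9 ||
      max(abs(c(p$range_minor - s$range_minor, p$range_minor - x$range_minor))) > 1e-9 ||
      max(abs(c(p$azimuth_major - s$azimuth_major, p$azimuth_major - x$azimuth_major))) > 1e-9) {
    v <- c(v, "ranges/azimuth differ across structures (LMC requires shared basic structures)")
  }
  if (abs(x$partial_sill) > sqrt(p$partial_sill * s$partial_sill) + 1e-12) {
    v <- c(v, sprintf(
      "cross partial sill %.4g exceeds sqrt(%.4g * %.4g) = %.4g (not positive semi-definite)",
      x$partial_sill, p$partial_sill, s$partial_sill,
      sqrt(p$partial_sill * s$partial_sill)))
  }
  if (abs(x$nugget) > sqrt(p$nugget * s$nugget) + 1e-12) {
    v <- c(v, sprintf("cross nugget %.4g exceeds sqrt(%.4g * %.4g)",
                      x$nugget, p$nugget, s$nugget))
  }
  list(valid = length(v) == 0L, violations = v)
}
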