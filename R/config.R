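#' Variogram parameters to/from config lists
#'
#' Serializes a [variogram_model()] in the layout used by survey reports and
#' the YAML configs: model family, nugget, sill, major/minor range, major
#' direction. `sill_is_total` controls how the `sill` entry is read: `TRUE`
#' (default) reads it as nugget + partial sill, the common reporting
#' convention; `FALSE` as the partial sill alone. Both readings are accepted
#' because published parameter tables rarely say which they use.
#'
#' @param cfg named list with `model`, `nugget`, `sill`, `range_major` (or
#'   `range`), optional `range_minor`, `azimuth`, `sill_is_total`.
#' @return a [variogram_model()].
#' @export
variogram_from_config <- function(cfg) {
  rng <- cfg$range_major %||% cfg$range
  if (is.null(rng)) stop("variogram config needs 'range_major' (or 'range')")
  variogram_model(
    model_type = cfg$model %||% "gaussian",
    nugget = cfg$nugget %||% 0,
    sill = cfg$sill,
    range_major = rng,
    range_minor = cfg$range_minor %||% rng,
    azimuth_major = cfg$azimuth %||% 0,
    sill_is_total = isTRUE(cfg$sill_is_total %||% TRUE)
  )
}

#' @rdname variogram_from_config
#' @param model a [variogram_model()].
#' @export
variogram_to_config <- function(model) {
  list(model = model$model_type,
       nugget = model$nugget,
       sill = model$nugget + model$partial_sill,
       range_major = model$range_major,
       range_minor = model$range_minor,
       azimuth = model$azimuth_major,
       sill_is_total = TRUE)
}

grid_from_config <- function(cfg) {
  grid_spec(cfg$x_min %||% 0, cfg$y_min %||% 0, cfg$cell_size %||% 5,
            cfg$n_cols %||% 40, cfg$n_rows %||% 30)
}

#' Read a scenario configuration from YAML
#'
#' The YAML mirrors [scenario_config()]: top-level keys `domain`, `field`
#' (with `variogram`, `mean_log`, `sources`), `sampling`, `instruments`,
#' `analyte`, `seed`; all keys optional, missing ones take the package
#' defaults.
#'
#' @param path YAML file.
#' @return a [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  defaults <- scenario_config()
  src <- cfg$field$sources
  sources <- if (is.null(src)) defaults$sources else
    do.call(rbind, lapply(src, as.data.frame))
  scenario_config(
    domain = if (is.null(cfg$domain)) defaults$domain else grid_from_config(cfg$domain),
    field_model = if (is.null(cfg$field$variogram)) defaults$field_model else
      variogram_from_config(cfg$field$variogram),
    mean_log = cfg$field$mean_log %||% defaults$mean_log,
    sources = sources,
    n_primary = cfg$sampling$n_primary %||% defaults$n_primary,
    n_secondary = cfg$sampling$n_secondary %||% defaults$n_secondary,
    n_validation = cfg$sampling$n_validation %||% defaults$n_validation,
    n_colocated = cfg$sampling$n_colocated %||% defaults$n_colocated,
    primary_noise_sd_log = cfg$instruments$primary_noise_sd_log %||%
      defaults$primary_noise_sd_log,
    secondary_slope = cfg$instruments$secondary_slope %||% defaults$secondary_slope,
    secondary_intercept = cfg$instruments$secondary_intercept %||%
      defaults$secondary_intercept,
    secondary_noise_sd = cfg$instruments$secondary_noise_sd %||%
      defaults$secondary_noise_sd,
    secondary_noise_exponent = cfg$instruments$secondary_noise_exponent %||%
      defaults$secondary_noise_exponent,
    analyte = cfg$analyte %||% defaults$analyte,
    seed = cfg$seed %||% defaults$seed
  )
}

#' Write a calibration model to YAML
#'
#' @param cal a [fit_calibration()] model.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "calibration_model"))
  yaml::write_yaml(unclass(cal), path)
  invisible(path)
}

#' Read a calibration model from YAML
#'
#' @param path YAML written by [write_calibration()].
#' @return a `calibration_model`.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  structure(list(slope = cfg$slope, intercept = cfg$intercept,
                 r_squared = cfg$r_squared, n_pairs = cfg$n_pairs,
                 analyte = cfg$analyte %||% NA_character_,
                 method = cfg$method %||% "ols"),
            class = "calibration_model")
}
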