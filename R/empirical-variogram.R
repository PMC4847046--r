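#' Experimental (semi-)variogram
#'
#' Accumulates half the mean squared difference of values over point pairs
#' binned by separation distance (and optionally by direction): for each class,
#' `gamma = sum((z_i - z_j)^2) / (2 * n_pairs)`.
#'
#' Directional classes keep the pairs whose separation azimuth lies within
#' `angle_tolerance` of `direction` (azimuths are taken modulo 180, as the
#' variogram is symmetric in h). Bandwidth is unbounded. Lags with no pairs
#' are dropped.
#'
#' @param samples a [sample_set()].
#' @param lag_width bin width in metres; default `max distance / (2 * n_lags)`.
#' @param n_lags number of distance classes.
#' @param direction azimuth in degrees clockwise from north, or `NA` for an
#'   omnidirectional variogram.
#' @param angle_tolerance half-width of the angular class, degrees.
#' @return an `experimental_variogram`: data frame with `lag_center`, `gamma`,
#'   `n_pairs`, and attributes `direction`, `angle_tolerance`, `lag_width`.
#' @export
experimental_variogram <- function(samples, lag_width = NULL, n_lags = 12,
                                   direction = NA, angle_tolerance = 22.5) {
  stopifnot(inherits(samples, "sample_set"))
  if (nrow(samples) < 2L) stop("need at least 2 points for a variogram")
  ij <- utils::combn(nrow(samples), 2L)
  dx <- samples$x[ij[2, ]] - samples$x[ij[1, ]]
  dy <- samples$y[ij[2, ]] - samples$y[ij[1, ]]
  d  <- sqrt(dx^2 + dy^2)
  dz2 <- (samples$value[ij[1, ]] - samples$value[ij[2, ]])^2
  if (!is.na(direction)) {
    az <- (atan2(dx, dy) * 180 / pi) %% 180
    delta <- abs(az - direction %% 180)
    keep <- pmin(delta, 180 - delta) <= angle_tolerance & d > 0
    d <- d[keep]; dz2 <- dz2[keep]
  }
  if (is.null(lag_width)) lag_width <- max(d) / (2 * n_lags)
  bin <- floor(d / lag_width) + 1L
  bin[bin > n_lags] <- NA_integer_     # beyond the cutoff
  bin[d == 0] <- NA_integer_                        # co-located duplicates excluded
  gamma <- tapply(dz2, bin, sum)
  n_pairs <- tapply(dz2, bin, length)
  if (length(gamma) == 0L) {
    stop("empty variogram: no pair falls in any lag/direction class")
  }
  idx <- as.integer(names(gamma))
  out <- data.frame(
    lag_center = (idx - 0.5) * lag_width,
    gamma = as.numeric(gamma) / (2 * as.numeric(n_pairs)),
    n_pairs = as.integer(n_pairs)
  )
  out <- out[order(out$lag_center), ]
  rownames(out) <- NULL
  structure(out, direction = direction, angle_tolerance = angle_tolerance,
            lag_width = lag_width, class = c("experimental_variogram", "data.frame"))
}

#' Experimental cross-variogram of two co-located sample sets
#'
#' For point pairs within each lag class,
#' `gamma12 = sum((z1_i - z1_j) * (z2_i - z2_j)) / (2 * n_pairs)`, computed
#' over locations where both variables are observed (co-located within
#' `colocation_tolerance`). Cross-variography requires such co-located data;
#' the pseudo cross-variogram of displaced pairs is not implemented.
#'
#' @param primary,secondary [sample_set()] objects.
#' @param lag_width,n_lags,direction,angle_tolerance as in
#'   [experimental_variogram()].
#' @param colocation_tolerance metres within which two points count as the
#'   same location.
#' @return an `experimental_variogram` of cross-semivariances (which may be
#'   negative for negatively related variables).
#' @export
experimental_cross_variogram <- function(primary, secondary, lag_width = NULL,
                                         n_lags = 12, direction = NA,
                                         angle_tolerance = 22.5,
                                         colocation_tolerance = 1e-9) {
  stopifnot(inherits(primary, "sample_set"), inherits(secondary, "sample_set"))
  m <- match_colocated(primary, secondary, colocation_tolerance)
  if (nrow(m) < 2L) {
    stop("cross-variography needs at least 2 co-located points; found ",
         nrow(m), ". Secondary points must coincide with primary points.")
  }
  x <- primary$x[m$i]; y <- primary$y[m$i]
  z1 <- primary$value[m$i]; z2 <- secondary$value[m$j]
  ij <- utils::combn(length(x), 2L)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  d  <- sqrt(dx^2 + dy^2)
  cp <- (z1[ij[1, ]] - z1[ij[2, ]]) * (z2[ij[1, ]] - z2[ij[2, ]])
  if (!is.na(direction)) {
    az <- (atan2(dx, dy) * 180 / pi) %% 180
    delta <- abs(az - direction %% 180)
    keep <- pmin(delta, 180 - delta) <= angle_tolerance & d > 0
    d <- d[keep]; cp <- cp[keep]
  }
  if (is.null(lag_width)) lag_width <- max(d) / (2 * n_lags)
  bin <- floor(d / lag_width) + 1L
  bin[bin > n_lags] <- NA_integer_     # beyond the cutoff
  bin[d == 0] <- NA_integer_
  gsum <- tapply(cp, bin, sum)
  n_pairs <- tapply(cp, bin, length)
  if (length(gsum) == 0L) stop("empty cross-variogram: no pairs in any class")
  idx <- as.integer(names(gsum))
  out <- data.frame(
    lag_center = (idx - 0.5) * lag_width,
    gamma = as.numeric(gsum) / (2 * as.numeric(n_pairs)),
    n_pairs = as.integer(n_pairs)
  )
  out <- out[order(out$lag_center), ]
  rownames(out) <- NULL
  structure(out, direction = direction, angle_tolerance = angle_tolerance,
            lag_width = lag_width, class = c("experimental_variogram", "data.frame"))
}

# index pairs (i in primary, j in secondary) of co-located points
match_colocated <- function(primary, secondary, tol = 1e-9) {
  i_out <- integer(); j_out <- integer()
  for (i in seq_len(nrow(primary))) {
    d <- sqrt((secondary$x - primary$x[i])^2 + (secondary$y - primary$y[i])^2)
    j <- which(d <= tol)
    if (length(j)) { i_out <- c(i_out, i); j_out <- c(j_out, j[1]) }
  }
  data.frame(i = i_out, j = j_out)
}
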