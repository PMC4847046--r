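#' Regular prediction-grid geometry
#'
#' Cells are square, `cell_size` metres on a side; `(x_min, y_min)` is the
#' lower-left corner of the raster. The default cell size is 5 m, matching the
#' DEM spacing typical of 1:5000 topographic products used for mine-site work.
#'
#' @param x_min,y_min lower-left corner, metres.
#' @param cell_size cell edge, metres (> 0).
#' @param n_cols,n_rows raster dimensions (>= 1).
#' @return a `grid_spec` object.
#' @export
grid_spec <- function(x_min = 0, y_min = 0, cell_size = 5, n_cols = 40, n_rows = 30) {
  stopifnot(cell_size > 0, n_cols >= 1, n_rows >= 1)
  structure(list(x_min = x_min, y_min = y_min, cell_size = cell_size,
                 n_cols = as.integer(n_cols), n_rows = as.integer(n_rows)),
            class = "grid_spec")
}

#' Cell-centre coordinates of a grid
#'
#' @param spec a [grid_spec()].
#' @return data frame of `x`, `y`, `row`, `col`; row 1 is the southernmost.
#' @export
grid_centers <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  xs <- spec$x_min + (seq_len(spec$n_cols) - 0.5) * spec$cell_size
  ys <- spec$y_min + (seq_len(spec$n_rows) - 0.5) * spec$cell_size
  expand.grid(col = seq_len(spec$n_cols), row = seq_len(spec$n_rows))[, 2:1] ->
    idx
  data.frame(x = xs[idx$col], y = ys[idx$row], row = idx$row, col = idx$col)
}

#' Kriged raster container
#'
#' @param spec a [grid_spec()].
#' @param estimates numeric matrix `n_rows x n_cols` of estimates (mg/kg), row 1
#'   = southernmost row; `NA` marks masked cells.
#' @param variances matrix of kriging variances (same shape, >= 0), or `NULL`.
#' @param scale `"raw"` (mg/kg) or `"log"`.
#' @return a `prediction_grid` object.
#' @export
prediction_grid <- function(spec, estimates, variances = NULL, scale = "raw") {
  stopifnot(inherits(spec, "grid_spec"),
            nrow(estimates) == spec$n_rows, ncol(estimates) == spec$n_cols)
  if (!is.null(variances)) {
    stopifnot(all(dim(variances) == dim(estimates)))
    if (any(variances < 0, na.rm = TRUE)) stop("negative kriging variance")
  }
  structure(list(spec = spec, estimates = estimates, variances = variances,
                 scale = scale),
            class = "prediction_grid")
}

#' @export
print.prediction_grid <- function(x, ...) {
  cat(sprintf("<prediction_grid> %d x %d cells of %.3g m (%s scale)\n",
              x$spec$n_rows, x$spec$n_cols, x$spec$cell_size, x$scale))
  cat(sprintf("  estimates: [%.4g, %.4g], %d masked\n",
              suppressWarnings(min(x$estimates, na.rm = TRUE)),
              suppressWarnings(max(x$estimates, na.rm = TRUE)),
              sum(is.na(x$estimates))))
  invisible(x)
}

#' Write a raster as an Esri ASCII grid
#'
#' Writes the `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header
#' followed by values in row-major order from the northern row down, the
#' convention of the .asc format. Round-trips through [read_grid_ascii()].
#'
#' @param grid a [prediction_grid()] (its estimates layer is written).
#' @param path output path (.asc).
#' @param nodata sentinel written for `NA` cells.
#' @param digits significant digits to print.
#' @return `path`, invisibly.
#' @export
write_grid_ascii <- function(grid, path, nodata = -9999, digits = 10) {
  stopifnot(inherits(grid, "prediction_grid"))
  s <- grid$spec
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", s$n_cols), paste("nrows", s$n_rows),
    paste("xllcorner", format(s$x_min, digits = 15)),
    paste("yllcorner", format(s$y_min, digits = 15)),
    paste("cellsize", format(s$cell_size, digits = 15)),
    paste("NODATA_value", nodata)
  ), con)
  m <- grid$estimates
  for (r in rev(seq_len(s$n_rows))) {          # north to south
    v <- m[r, ]
    v_chr <- ifelse(is.na(v), as.character(nodata),
                    formatC(v, digits = digits, format = "g"))
    writeLines(paste(v_chr, collapse = " "), con)
  }
  invisible(path)
}

#' Read an Esri ASCII grid
#'
#' @param path an .asc file written by [write_grid_ascii()] or compatible.
#' @return a [prediction_grid()] with `NA` at NODATA cells (no variances).
#' @export
read_grid_ascii <- function(path) {
  if (!file.exists(path)) stop("raster not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  }
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = " "),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc,
         call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE]     # back to south-first rows
  m[m == nodata] <- NA_real_
  prediction_grid(grid_spec(hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nc, nr), m)
}
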