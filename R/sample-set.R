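#' Construct a sample set of point assays
#'
#' A `sample_set` is the basic data container of the package: a set of point
#' observations of a single analyte made by a single class of instrument
#' ("primary" = accurate laboratory assay, ICP-AES-like; "secondary" = rapid
#' field assay, PXRF-like), with planar coordinates in metres. Concentrations
#' are in mg/kg and must be strictly positive so that a natural-log transform
#' is always available.
#'
#' @param id character vector of sample labels.
#' @param x,y numeric coordinates in metres (local Cartesian frame, x = easting,
#'   y = northing).
#' @param value numeric concentrations in mg/kg (or natural logs thereof when
#'   `log_transformed = TRUE`).
#' @param instrument `"primary"` or `"secondary"`; recycled if length 1.
#' @param analyte `"Cu"` or `"Pb"`; a set is homogeneous in analyte.
#' @param role `"train"` or `"validation"`; recycled if length 1.
#' @param ec,ph optional per-sample electrical conductivity (uS/cm) and pH.
#' @param log_transformed logical flag: are `value`s natural logs?
#'
#' @return An object of class `sample_set`: a data frame with columns
#'   `id, x, y, value, instrument, analyte, role, ec, ph` and attributes
#'   `analyte` and `log_transformed`.
#' @export
sample_set <- function(id, x, y, value, instrument = "primary",
                       analyte = "Cu", role = "train",
                       ec = NA_real_, ph = NA_real_,
                       log_transformed = FALSE) {
  n <- length(x)
  df <- data.frame(
    id = as.character(id),
    x = as.numeric(x), y = as.numeric(y),
    value = as.numeric(value),
    instrument = rep_len(as.character(instrument), n),
    analyte = rep_len(as.character(analyte), n),
    role = rep_len(as.character(role), n),
    ec = rep_len(as.numeric(ec), n),
    ph = rep_len(as.numeric(ph), n),
    stringsAsFactors = FALSE
  )
  structure(df,
    analyte = unique(df$analyte),
    log_transformed = isTRUE(log_transformed),
    class = c("sample_set", "data.frame")
  )
}

validate_sample_set <- function(s, require_positive = !attr(s, "log_transformed")) {
  if (nrow(s) < 1L) stop("no samples", call. = FALSE)
  if (length(unique(s$analyte)) != 1L) {
    stop("sample_set must be homogeneous in analyte; found: ",
         paste(unique(s$analyte), collapse = ", "), call. = FALSE)
  }
  if (!all(s$instrument %in% c("primary", "secondary"))) {
    stop("instrument must be 'primary' or 'secondary'", call. = FALSE)
  }
  if (!all(s$role %in% c("train", "validation"))) {
    stop("role must be 'train' or 'validation'", call. = FALSE)
  }
  if (any(!is.finite(s$x)) || any(!is.finite(s$y))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (require_positive && any(!is.finite(s$value) | s$value <= 0)) {
    bad <- which(!is.finite(s$value) | s$value <= 0)
    stop("non-positive or non-finite concentration at row(s) ",
         paste(bad, collapse = ", "),
         " (values must be > 0 mg/kg for the log transform)", call. = FALSE)
  }
  key <- paste(s$x, s$y, s$instrument, s$analyte, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicate (x, y, instrument, analyte) at row(s) ",
         paste(dup, collapse = ", "), " [id: ",
         paste(s$id[dup], collapse = ", "), "]", call. = FALSE)
  }
  invisible(s)
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d points, analyte %s%s\n", nrow(x),
              attr(x, "analyte"),
              if (attr(x, "log_transformed")) " (log scale)" else ""))
  print(as.data.frame(x), ...)
  invisible(x)
}

# subsetting keeps the class and attributes
#' @export
`[.sample_set` <- function(x, i, ...) {
  out <- as.data.frame(x)[i, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
    analyte = attr(x, "analyte"),
    log_transformed = attr(x, "log_transformed"),
    class = c("sample_set", "data.frame")
  )
}

#' Natural-log transform of a sample set
#'
#' @param s a `sample_set` on the raw mg/kg scale.
#' @return the set with `value = log(value)` and the `log_transformed` flag set.
#' @export
log_transform <- function(s) {
  stopifnot(inherits(s, "sample_set"))
  if (attr(s, "log_transformed")) return(s)
  validate_sample_set(s, require_positive = TRUE)
  s$value <- log(s$value)
  attr(s, "log_transformed") <- TRUE
  s
}

#' Read a sample table from delimited text
#'
#' Expects a header with columns `id, x, y, value, instrument, analyte, role`
#' (plus optional `ec`, `ph`). Column names can be remapped through `schema`,
#' e.g. `schema = c(value = "cu_mgkg")`. The delimiter is inferred from the
#' file extension (`.tsv` = tab, otherwise comma).
#'
#' @param path path to a CSV/TSV file.
#' @param schema named character vector mapping canonical column names to the
#'   names used in the file.
#' @param analyte if the file holds several analytes, keep only this one.
#' @return a validated [sample_set()].
#' @export
read_samples <- function(path, schema = character(), analyte = NULL) {
  if (!file.exists(path)) stop("sample file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  canon <- c("id", "x", "y", "value", "instrument", "analyte", "role")
  for (col in canon) {
    src <- if (col %in% names(schema)) schema[[col]] else col
    if (!src %in% names(raw)) {
      if (col %in% c("instrument", "role")) next   # defaulted below
      stop("missing required column '", src, "' in ", path, call. = FALSE)
    }
    names(raw)[names(raw) == src] <- col
  }
  if (nrow(raw) == 0L) stop("no samples in ", path, call. = FALSE)
  if (!"instrument" %in% names(raw)) raw$instrument <- "primary"
  if (!"role" %in% names(raw)) raw$role <- "train"
  for (col in c("ec", "ph")) {
    src <- if (col %in% names(schema)) schema[[col]] else col
    if (src %in% names(raw)) names(raw)[names(raw) == src] <- col else raw[[col]] <- NA_real_
  }
  if (!is.null(analyte)) raw <- raw[raw$analyte == analyte, , drop = FALSE]
  if (nrow(raw) == 0L) stop("no samples in ", path, call. = FALSE)
  bad <- which(!is.finite(suppressWarnings(as.numeric(raw$value))) |
               suppressWarnings(as.numeric(raw$value)) <= 0)
  if (length(bad)) {
    stop("non-positive or malformed concentration in ", path, " at data row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  s <- sample_set(raw$id, raw$x, raw$y, raw$value, raw$instrument,
                  raw$analyte, raw$role, raw$ec, raw$ph)
  validate_sample_set(s)
}

#' Write a sample set to CSV
#'
#' Inverse of [read_samples()]: `read_samples(write_samples(s, f))` restores
#' the set field-for-field.
#'
#' @param s a `sample_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(s, path) {
  stopifnot(inherits(s, "sample_set"))
  utils::write.csv(as.data.frame(s), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled example assay table
#'
#' Returns the path to a small CSV of 23 soil samples assayed by ICP-AES for
#' Cu and Pb (with EC and pH) from an abandoned iron-mine survey: 12 training
#' samples co-assayed with a field PXRF instrument and 11 independent
#' validation samples. Assay values are as published; the x/y coordinates in
#' the file are synthetic placeholders (the survey coordinates were never
#' published) and are suitable only for exercising the API.
#'
#' @return file path of the bundled CSV.
#' @export
example_assay_path <- function() {
  system.file("extdata", "mine_survey_icp_synthetic_coords.csv",
              package = "duokrig", mustWork = TRUE)
}
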