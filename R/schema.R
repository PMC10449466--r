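#' Crop kinds and their seasonal weather windows
#'
#' The five crops the toolkit models, with the harvest season and the
#' inclusive month window whose weather drives each crop. Two windows wrap
#' the calendar year (aman: December--January; wheat: November--March); a
#' wrapping window is attributed to the harvest fiscal year of its later
#' months, so e.g. aman for harvest year \eqn{Y} covers December of
#' \eqn{Y-1} and January of \eqn{Y}.
#'
#' @return A data.frame with one row per crop and columns `crop`, `season`
#'   (`"kharif"` or `"rabi"`), `start_month`, `end_month` and `wraps`
#'   (logical; whether the window crosses the year boundary).
#' @export
#' @examples
#' crop_kinds()
crop_kinds <- function() {
  data.frame(
    crop        = c("aus", "aman", "boro", "potato", "wheat"),
    season      = c("kharif", "rabi", "kharif", "kharif", "rabi"),
    start_month = c(6L, 12L, 3L, 2L, 11L),
    end_month   = c(8L, 1L, 5L, 3L, 3L),
    wraps       = c(FALSE, TRUE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Resolve a crop's weather window to calendar (year, month) pairs
#'
#' @param crop One of `"aus"`, `"aman"`, `"boro"`, `"potato"`, `"wheat"`.
#' @param year Harvest fiscal year (integer). For wrapping windows the
#'   months before January fall in `year - 1`.
#' @return data.frame with columns `year` and `month`, in chronological order.
#' @export
crop_window_months <- function(crop, year) {
  kinds <- crop_kinds()
  row <- kinds[kinds$crop == crop, ]
  if (nrow(row) != 1L) {
    stop("unknown crop: ", crop, call. = FALSE)
  }
  year <- as.integer(year)
  if (row$wraps) {
    early <- row$start_month:12L
    late <- 1L:row$end_month
    data.frame(
      year  = c(rep(year - 1L, length(early)), rep(year, length(late))),
      month = c(early, late)
    )
  } else {
    data.frame(year = year, month = row$start_month:row$end_month)
  }
}

# Fixed machine-readable column layout shared by every pipeline stage.
schema_columns <- function() {
  c("district", "year", "crop",
    weather_columns(), "area", "production")
}

#' Column-name helpers for the crop dataset schema
#'
#' `weather_columns()` returns the seven seasonal weather averages,
#' `predictor_columns()` those seven plus cultivation `area` (the eight
#' model inputs), and `numeric_columns()` the predictors plus the
#' `production` target.
#' @return Character vector of column names.
#' @export
weather_columns <- function() {
  c("rainfall", "temp_max", "temp_min", "humidity",
    "wind_speed", "cloud_coverage", "sunshine")
}

#' @rdname weather_columns
#' @export
predictor_columns <- function() c(weather_columns(), "area")

#' @rdname weather_columns
#' @export
numeric_columns <- function() c(predictor_columns(), "production")

#' Construct a crop dataset from a data.frame
#'
#' A crop dataset is a data.frame with one row per (district, year, crop)
#' observation: key columns `district`, `year`, `crop`, the seven seasonal
#' weather averages, cultivation `area` (acres) and the `production` target
#' (tons). Missing values are `NA`. The object carries a normalization
#' state (`"raw"` or `"normalized"`) and, once normalized, the per-column
#' min/max parameters needed to invert the transform.
#'
#' @param df data.frame holding at least the schema columns (any order).
#' @param normalization `"raw"` or `"normalized"`.
#' @param norm_params `NULL` or a parameter table from [minmax_fit()].
#' @return An object of class `crop_dataset` (a data.frame).
#' @export
as_crop_dataset <- function(df, normalization = "raw", norm_params = NULL) {
  cols <- schema_columns()
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- df[, cols, drop = FALSE]
  out$district <- as.character(out$district)
  out$crop <- as.character(out$crop)
  out$year <- as.integer(out$year)
  for (cl in numeric_columns()) out[[cl]] <- as.numeric(out[[cl]])
  rownames(out) <- NULL
  structure(out,
    class = c("crop_dataset", "data.frame"),
    schema_version = "1.0",
    normalization = match.arg(normalization, c("raw", "normalized")),
    norm_params = norm_params
  )
}

#' @export
print.crop_dataset <- function(x, ...) {
  cat(sprintf("<crop_dataset> %d records, %s scale\n",
              nrow(x), attr(x, "normalization")))
  NextMethod()
}

parse_numeric_cell <- function(x) {
  # tolerate surrounding whitespace and thousands separators ("1,250")
  suppressWarnings(as.numeric(gsub("[ ,]", "", x)))
}

#' Read a crop dataset from CSV
#'
#' Reads an RFC-4180-style CSV (UTF-8, header row mandatory, `.` decimal
#' separator) into a [crop_dataset][as_crop_dataset]. Empty cells become
#' `NA`. Numeric cells are parsed after stripping whitespace and thousands
#' separators; cells that still fail to parse become `NA` when
#' `strict = FALSE` (and are counted, see [validate_crop_dataset()]) or
#' raise an error when `strict = TRUE`. Column order is normalized to the
#' schema order. If a normalization sidecar written by
#' [write_crop_dataset()] sits next to the file, it is restored too.
#'
#' @param path Path to the CSV file.
#' @param strict If `TRUE`, unparsable numeric cells are an error.
#' @return A `crop_dataset`. The count of unparsable cells is carried in
#'   the `n_unparsable` attribute.
#' @export
read_crop_dataset <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = "")
  if (ncol(raw) == 0L) stop("empty-input error: no columns in ", path,
                            call. = FALSE)
  missing_cols <- setdiff(schema_columns(), names(raw))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n_unparsable <- 0L
  for (cl in numeric_columns()) {
    parsed <- parse_numeric_cell(raw[[cl]])
    bad <- !is.na(raw[[cl]]) & is.na(parsed)
    if (any(bad)) {
      if (strict) {
        stop("unparsable value(s) in column '", cl, "' at row(s) ",
             paste(which(bad), collapse = ", "), call. = FALSE)
      }
      n_unparsable <- n_unparsable + sum(bad)
    }
    raw[[cl]] <- parsed
  }
  year_parsed <- parse_numeric_cell(raw[["year"]])
  bad_year <- !is.na(raw[["year"]]) & is.na(year_parsed)
  if (any(bad_year)) {
    if (strict) stop("unparsable year at row(s) ",
                     paste(which(bad_year), collapse = ", "), call. = FALSE)
    n_unparsable <- n_unparsable + sum(bad_year)
  }
  raw[["year"]] <- year_parsed

  norm_params <- NULL
  normalization <- "raw"
  sidecar <- norm_sidecar_path(path)
  if (file.exists(sidecar)) {
    np <- jsonlite::fromJSON(sidecar)
    norm_params <- data.frame(column = np$column, min = np$min, max = np$max,
                              stringsAsFactors = FALSE)
    normalization <- "normalized"
  }
  ds <- as_crop_dataset(raw, normalization = normalization,
                        norm_params = norm_params)
  attr(ds, "n_unparsable") <- n_unparsable
  ds
}

norm_sidecar_path <- function(path) paste0(path, ".norm.json")

#' Write a crop dataset to CSV
#'
#' Values round-trip through [read_crop_dataset()] to at least 12
#' significant digits; missing values are written as empty cells. When the
#' dataset is normalized, the stored min/max parameters are written to a
#' JSON sidecar (`<path>.norm.json`) so the transform stays invertible.
#'
#' @param ds A `crop_dataset`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_crop_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "crop_dataset"))
  out <- as.data.frame(ds)
  for (cl in numeric_columns()) {
    out[[cl]] <- ifelse(is.na(out[[cl]]), NA,
                        sprintf("%.15g", out[[cl]]))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  np <- attr(ds, "norm_params")
  if (identical(attr(ds, "normalization"), "normalized") && !is.null(np)) {
    jsonlite::write_json(as.list(np), norm_sidecar_path(path),
                         auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

#' Validate a crop dataset against the schema invariants
#'
#' Checks, without modifying the data: humidity in \[0, 100\];
#' `temp_min <= temp_max`; non-negative area, production, wind speed and
#' cloud coverage; year within \[1969, 2100\]; and uniqueness of the
#' (district, year, crop) key. Missing cells are counted per column, and
#' the reader's unparsable-cell count is surfaced.
#'
#' @param ds A `crop_dataset`.
#' @return An object of class `validation_report`: a list with
#'   `n_records`, `n_missing_by_column`, `n_unparsable` and a `violations`
#'   data.frame of (record index, rule).
#' @export
validate_crop_dataset <- function(ds) {
  stopifnot(inherits(ds, "crop_dataset"))
  viol <- list()
  add <- function(idx, rule) {
    if (length(idx) > 0L) {
      viol[[length(viol) + 1L]] <<- data.frame(index = idx, rule = rule,
                                               stringsAsFactors = FALSE)
    }
  }
  chk <- function(col, bad, rule) {
    x <- ds[[col]]
    add(which(!is.na(x) & bad(x)), rule)
  }
  chk("humidity", function(x) x < 0 | x > 100, "humidity must be in [0, 100]")
  chk("area", function(x) x < 0, "area must be >= 0")
  chk("production", function(x) x < 0, "production must be >= 0")
  chk("wind_speed", function(x) x < 0, "wind_speed must be >= 0")
  chk("cloud_coverage", function(x) x < 0, "cloud_coverage must be >= 0")
  chk("year", function(x) x < 1969 | x > 2100, "year must be in [1969, 2100]")
  both <- !is.na(ds$temp_min) & !is.na(ds$temp_max) & ds$temp_min > ds$temp_max
  add(which(both), "temp_min must be <= temp_max")
  if (!is.element("crop", names(ds)) || nrow(ds) > 0L) {
    bad_crop <- !is.na(ds$crop) & !(ds$crop %in% crop_kinds()$crop)
    add(which(bad_crop), "crop must be one of aus/aman/boro/potato/wheat")
    key <- paste(ds$district, ds$year, ds$crop, sep = "\r")
    add(which(duplicated(key)), "(district, year, crop) key must be unique")
  }
  violations <- if (length(viol) > 0L) {
    do.call(rbind, viol)
  } else {
    data.frame(index = integer(0), rule = character(0),
               stringsAsFactors = FALSE)
  }
  n_unparsable <- attr(ds, "n_unparsable")
  structure(
    list(
      n_records = nrow(ds),
      n_missing_by_column = vapply(numeric_columns(),
                                   function(cl) sum(is.na(ds[[cl]])),
                                   integer(1)),
      n_unparsable = if (is.null(n_unparsable)) 0L else n_unparsable,
      violations = violations
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %d records, %d unparsable cells, %d violations\n",
              x$n_records, x$n_unparsable, nrow(x$violations)))
  miss <- x$n_missing_by_column[x$n_missing_by_column > 0]
  if (length(miss) > 0) {
    cat("missing cells:",
        paste(sprintf("%s=%d", names(miss), miss), collapse = ", "), "\n")
  }
  if (nrow(x$violations) > 0) {
    tab <- table(x$violations$rule)
    for (r in names(tab)) cat(sprintf("  %s: %d record(s)\n", r, tab[[r]]))
  }
  invisible(x)
}
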