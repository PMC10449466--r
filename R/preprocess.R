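#' Default plausibility bounds for the numeric columns
#'
#' Physically motivated plausibility ranges used by [coerce_and_filter()].
#' Values outside their column's range are treated as recording errors and
#' set missing. Wind speed and cloud coverage carry opaque recorded units,
#' so their bounds are deliberately loose.
#'
#' @return Named list of `c(lower, upper)` pairs, one per numeric column.
#' @export
default_bounds <- function() {
  list(
    rainfall       = c(0, 10000),
    temp_max       = c(-10, 60),
    temp_min       = c(-20, 50),
    humidity       = c(0, 100),
    wind_speed     = c(0, 300),
    cloud_coverage = c(0, 100),
    sunshine       = c(0, 24),
    area           = c(0, 1e8),
    production     = c(0, 1e9)
  )
}

new_cleaning_report <- function(n_imputed_by_column = integer(0),
                                n_coerced = 0L,
                                n_dropped_duplicates = 0L,
                                n_dropped_junk = 0L) {
  structure(
    list(n_imputed_by_column = n_imputed_by_column,
         n_coerced = as.integer(n_coerced),
         n_dropped_duplicates = as.integer(n_dropped_duplicates),
         n_dropped_junk = as.integer(n_dropped_junk)),
    class = "cleaning_report"
  )
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(
    "<cleaning_report> imputed=%d coerced-to-missing=%d duplicates-dropped=%d junk-dropped=%d\n",
    sum(x$n_imputed_by_column), x$n_coerced,
    x$n_dropped_duplicates, x$n_dropped_junk))
  invisible(x)
}

#' Coerce malformed numerics and blank out implausible values
#'
#' Cleans wrong-format and wrong-data cells: character-typed numeric
#' columns are parsed after stripping whitespace and thousands separators;
#' values outside their plausibility bounds are set missing and counted;
#' rows where `temp_min > temp_max` have both temperatures set missing
#' (the pair is contradictory and neither can be trusted). Row order is
#' preserved and nothing is dropped.
#'
#' @param ds A `crop_dataset` (numeric columns may be character-typed if
#'   built from raw input).
#' @param bounds Named list of `c(lower, upper)` per numeric column; see
#'   [default_bounds()].
#' @return List with elements `dataset` (cleaned `crop_dataset`) and
#'   `report` (a `cleaning_report`; out-of-bounds and cross-field blanks
#'   are counted in `n_coerced`).
#' @export
coerce_and_filter <- function(ds, bounds = default_bounds()) {
  stopifnot(inherits(ds, "crop_dataset"))
  missing_bounds <- setdiff(numeric_columns(), names(bounds))
  if (length(missing_bounds) > 0L) {
    stop("bounds must cover all numeric columns; missing: ",
         paste(missing_bounds, collapse = ", "), call. = FALSE)
  }
  n_coerced <- 0L
  for (cl in numeric_columns()) {
    x <- ds[[cl]]
    if (!is.numeric(x)) x <- parse_numeric_cell(x)
    b <- bounds[[cl]]
    out_of_range <- !is.na(x) & (x < b[1] | x > b[2])
    n_coerced <- n_coerced + sum(out_of_range)
    x[out_of_range] <- NA_real_
    ds[[cl]] <- x
  }
  crossed <- !is.na(ds$temp_min) & !is.na(ds$temp_max) &
    ds$temp_min > ds$temp_max
  if (any(crossed)) {
    n_coerced <- n_coerced + 2L * sum(crossed)
    ds$temp_min[crossed] <- NA_real_
    ds$temp_max[crossed] <- NA_real_
  }
  list(dataset = ds, report = new_cleaning_report(n_coerced = n_coerced))
}

#' Impute missing numeric cells
#'
#' The default `"mean"` strategy replaces every missing numeric cell with
#' the arithmetic mean of the observed (non-missing) values of that
#' column; it is idempotent and preserves each column's mean. The
#' `"neighbor"` strategy exploits the temporal continuity of agro-climate
#' series: within each (district, crop) series ordered by year, a missing
#' cell becomes the mean of the nearest observed value before and after it
#' (one-sided at the series edges), falling back to the column mean for
#' all-missing series.
#'
#' @param ds A `crop_dataset` with numeric columns already coerced.
#' @param strategy `"mean"` (default) or `"neighbor"`.
#' @return List with `dataset` and `report` (`n_imputed_by_column` filled).
#' @export
impute_missing <- function(ds, strategy = c("mean", "neighbor")) {
  stopifnot(inherits(ds, "crop_dataset"))
  strategy <- match.arg(strategy)
  cols <- numeric_columns()
  n_imputed <- vapply(cols, function(cl) sum(is.na(ds[[cl]])), integer(1))
  all_missing <- cols[vapply(cols, function(cl) nrow(ds) > 0L &&
                               all(is.na(ds[[cl]])), logical(1))]
  if (length(all_missing) > 0L && any(n_imputed[all_missing] > 0L)) {
    stop("imputation error: column(s) entirely missing: ",
         paste(all_missing, collapse = ", "), call. = FALSE)
  }
  if (strategy == "mean") {
    for (cl in cols) {
      x <- ds[[cl]]
      if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
      ds[[cl]] <- x
    }
  } else {
    grp <- paste(ds$district, ds$crop, sep = "\r")
    for (cl in cols) {
      x <- ds[[cl]]
      if (!anyNA(x)) next
      col_mean <- mean(x, na.rm = TRUE)
      for (g in unique(grp[is.na(x)])) {
        idx <- which(grp == g)
        idx <- idx[order(ds$year[idx])]
        xi <- x[idx]
        for (j in which(is.na(xi))) {
          before <- which(!is.na(xi[seq_len(j - 1L)]))
          after <- which(!is.na(xi[-seq_len(j)])) + j
          neigh <- c(
            if (length(before) > 0L) xi[max(before)],
            if (length(after) > 0L) xi[min(after)]
          )
          x[idx[j]] <- if (length(neigh) > 0L) mean(neigh) else col_mean
        }
      }
      ds[[cl]] <- x
    }
  }
  list(dataset = ds,
       report = new_cleaning_report(n_imputed_by_column = n_imputed))
}

#' Aggregate monthly weather over a crop's seasonal window
#'
#' Given a monthly weather table (one row per district, year, month), takes
#' the arithmetic mean of each of the seven weather variables over the
#' months of the crop's window, resolving windows that wrap the year
#' boundary to the harvest fiscal year (see [crop_window_months()]).
#'
#' @param wx data.frame with columns `district`, `year`, `month` and the
#'   seven weather columns; at most one row per (district, year, month).
#' @param crop,district,year The observation key to aggregate for.
#' @return Named numeric vector of length 7 (the seasonal averages).
#' @export
aggregate_weather <- function(wx, crop, district, year) {
  window <- crop_window_months(crop, year)
  sel <- merge(window, wx[wx$district == district, ],
               by = c("year", "month"))
  if (nrow(sel) < nrow(window)) {
    have <- paste(sel$year, sel$month)
    want <- paste(window$year, window$month)
    miss <- window[!(want %in% have), , drop = FALSE]
    stop("aggregation error: missing month(s) for ", district, "/", crop,
         ": ", paste(sprintf("(%d, %d)", miss$year, miss$month),
                     collapse = ", "), call. = FALSE)
  }
  vapply(weather_columns(), function(cl) mean(sel[[cl]]), numeric(1))
}

#' Integrate weather, area and production tables into one dataset
#'
#' Inner-joins the cultivation-area and production tables on
#' (district, year, crop), then attaches each key's seasonal weather
#' averages computed with [aggregate_weather()]. Keys whose weather window
#' is not fully covered by the monthly table are excluded, consistent with
#' inner-join semantics. An empty result is a warning, not an error.
#'
#' @param wx Monthly weather table (see [aggregate_weather()]).
#' @param areas data.frame with columns `district`, `year`, `crop`, `area`.
#' @param productions data.frame with columns `district`, `year`, `crop`,
#'   `production`.
#' @return A `crop_dataset`.
#' @export
integrate_tables <- function(wx, areas, productions) {
  for (nm in c("district", "year", "crop")) {
    if (!nm %in% names(areas) || !nm %in% names(productions)) {
      stop("key column '", nm, "' missing from input tables", call. = FALSE)
    }
  }
  joined <- merge(areas[, c("district", "year", "crop", "area")],
                  productions[, c("district", "year", "crop", "production")],
                  by = c("district", "year", "crop"))
  rows <- vector("list", nrow(joined))
  keep <- logical(nrow(joined))
  for (i in seq_len(nrow(joined))) {
    w <- tryCatch(
      aggregate_weather(wx, joined$crop[i], joined$district[i],
                        joined$year[i]),
      error = function(e) NULL
    )
    if (!is.null(w)) {
      keep[i] <- TRUE
      rows[[i]] <- data.frame(
        district = joined$district[i], year = joined$year[i],
        crop = joined$crop[i], as.list(w),
        area = joined$area[i], production = joined$production[i],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!any(keep)) {
    warning("integration produced an empty dataset (no matching keys ",
            "with complete weather windows)", call. = FALSE)
    empty <- as.data.frame(
      stats::setNames(rep(list(numeric(0)), length(schema_columns())),
                      schema_columns()))
    empty$district <- character(0)
    empty$crop <- character(0)
    empty$year <- integer(0)
    return(as_crop_dataset(empty))
  }
  as_crop_dataset(do.call(rbind, rows[keep]))
}

#' Remove duplicate and junk rows
#'
#' Drops exact duplicate rows (first occurrence kept), then rows whose
#' every predictor is missing (junk), then any remaining rows repeating an
#' earlier (district, year, crop) key, so the output key is unique. Row
#' order is otherwise stable; row count never increases.
#'
#' @param ds A `crop_dataset`.
#' @return List with `dataset` and `report` (`n_dropped_duplicates`,
#'   `n_dropped_junk` filled).
#' @export
reduce_dataset <- function(ds) {
  stopifnot(inherits(ds, "crop_dataset"))
  dup <- duplicated(as.data.frame(ds))
  n_dup <- sum(dup)
  ds <- ds[!dup, , drop = FALSE]

  pred <- as.data.frame(ds)[, predictor_columns(), drop = FALSE]
  junk <- nrow(ds) > 0L & rowSums(!is.na(pred)) == 0L
  n_junk <- sum(junk)
  ds <- ds[!junk, , drop = FALSE]

  key <- paste(ds$district, ds$year, ds$crop, sep = "\r")
  key_dup <- duplicated(key)
  n_dup <- n_dup + sum(key_dup)
  ds <- ds[!key_dup, , drop = FALSE]

  rownames(ds) <- NULL
  list(dataset = ds,
       report = new_cleaning_report(n_dropped_duplicates = n_dup,
                                    n_dropped_junk = n_junk))
}

#' Fit, apply and invert min--max normalization
#'
#' `minmax_fit()` records each numeric column's observed min and max;
#' `minmax_apply()` maps values to `(x - min) / (max - min)` (constant
#' columns, where `max == min`, map to 0 with a warning); `minmax_invert()`
#' undoes the transform. Parameters are typically fitted on the training
#' split only and reused on the test split, so test-set values may fall
#' outside \[0, 1\]; they are deliberately not clipped.
#'
#' @param ds A `crop_dataset` with no missing numeric cells (`minmax_fit`)
#'   or any `crop_dataset` (`minmax_apply`, `minmax_invert`).
#' @param params Parameter table from `minmax_fit()`.
#' @return `minmax_fit`: data.frame with columns `column`, `min`, `max`.
#'   `minmax_apply` / `minmax_invert`: a `crop_dataset` with its
#'   normalization state updated.
#' @export
minmax_fit <- function(ds) {
  stopifnot(inherits(ds, "crop_dataset"))
  cols <- numeric_columns()
  has_na <- cols[vapply(cols, function(cl) anyNA(ds[[cl]]), logical(1))]
  if (length(has_na) > 0L) {
    stop("minmax_fit requires complete data; missing values in: ",
         paste(has_na, collapse = ", "), " (run impute_missing first)",
         call. = FALSE)
  }
  data.frame(
    column = cols,
    min = vapply(cols, function(cl) min(ds[[cl]]), numeric(1)),
    max = vapply(cols, function(cl) max(ds[[cl]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @rdname minmax_fit
#' @export
minmax_apply <- function(ds, params) {
  stopifnot(inherits(ds, "crop_dataset"))
  missing_cols <- setdiff(numeric_columns(), params$column)
  if (length(missing_cols) > 0L) {
    stop("normalization parameters missing for: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(params))) {
    cl <- params$column[i]
    rng <- params$max[i] - params$min[i]
    if (rng == 0) {
      warning("column '", cl, "' is constant (max == min); mapped to 0",
              call. = FALSE)
      ds[[cl]] <- ifelse(is.na(ds[[cl]]), NA_real_, 0)
    } else {
      ds[[cl]] <- (ds[[cl]] - params$min[i]) / rng
    }
  }
  attr(ds, "normalization") <- "normalized"
  attr(ds, "norm_params") <- params
  ds
}

#' @rdname minmax_fit
#' @export
minmax_invert <- function(ds, params = attr(ds, "norm_params")) {
  stopifnot(inherits(ds, "crop_dataset"))
  if (is.null(params)) {
    stop("no normalization parameters available to invert", call. = FALSE)
  }
  for (i in seq_len(nrow(params))) {
    cl <- params$column[i]
    ds[[cl]] <- ds[[cl]] * (params$max[i] - params$min[i]) + params$min[i]
  }
  attr(ds, "normalization") <- "raw"
  attr(ds, "norm_params") <- NULL
  ds
}

#' Run the full cleaning pipeline
#'
#' Convenience wrapper chaining [coerce_and_filter()], [impute_missing()],
#' [reduce_dataset()] and, optionally, min--max normalization fitted on the
#' data itself. For leakage-free modelling, normalize with parameters
#' fitted on the training split instead (see [minmax_fit()]).
#'
#' @param ds A `crop_dataset`.
#' @param bounds Plausibility bounds, see [default_bounds()].
#' @param impute `"mean"` or `"neighbor"`.
#' @param normalize If `TRUE`, apply min--max normalization fitted on the
#'   cleaned data.
#' @return List with `dataset`, `report` (merged `cleaning_report`) and
#'   `norm_params` (`NULL` unless `normalize = TRUE`).
#' @export
preprocess_pipeline <- function(ds, bounds = default_bounds(),
                                impute = "mean", normalize = FALSE) {
  step1 <- coerce_and_filter(ds, bounds)
  step2 <- impute_missing(step1$dataset, strategy = impute)
  step3 <- reduce_dataset(step2$dataset)
  report <- new_cleaning_report(
    n_imputed_by_column = step2$report$n_imputed_by_column,
    n_coerced = step1$report$n_coerced,
    n_dropped_duplicates = step3$report$n_dropped_duplicates,
    n_dropped_junk = step3$report$n_dropped_junk
  )
  out <- step3$dataset
  norm_params <- NULL
  if (normalize) {
    norm_params <- minmax_fit(out)
    out <- minmax_apply(out, norm_params)
  }
  list(dataset = out, report = report, norm_params = norm_params)
}
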