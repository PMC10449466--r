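#' Build a threshold table for the crop recommender
#'
#' Expert-supplied minimum production levels: one row per
#' (region, season, crop) giving the threshold `tau` in tons at or above
#' which the crop is worth recommending. Thresholds come from local
#' agricultural authorities and are treated as opaque inputs.
#'
#' @param df data.frame with columns `region`, `season`
#'   (`"kharif"`/`"rabi"`), `crop` and `tau` (tons, >= 0).
#' @return A validated `threshold_table` (data.frame).
#' @export
threshold_table <- function(df) {
  needed <- c("region", "season", "crop", "tau")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("threshold table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, needed]
  if (any(!df$season %in% c("kharif", "rabi"))) {
    stop("season must be 'kharif' or 'rabi'", call. = FALSE)
  }
  if (any(!df$crop %in% crop_kinds()$crop)) {
    stop("unknown crop in threshold table", call. = FALSE)
  }
  if (any(df$tau < 0)) stop("tau must be >= 0", call. = FALSE)
  key <- paste(df$region, df$season, df$crop)
  if (anyDuplicated(key)) {
    stop("duplicate (region, season, crop) entries in threshold table",
         call. = FALSE)
  }
  structure(df, class = c("threshold_table", "data.frame"))
}

#' Recommend crops whose predicted production meets the expert threshold
#'
#' For each candidate crop of the query season, predicts production from
#' the crop's model and feature vector, keeps crops whose prediction meets
#' or exceeds the (region, season, crop) threshold, and ranks the
#' qualifying crops by relative margin
#' \eqn{(\hat P - \tau) / \max(\tau, 10^{-9})} in descending order (ties
#' broken alphabetically by crop name). The relative margin keeps
#' high-volume crops (rice, thousands of tons) from trivially dominating
#' low-volume crops (wheat). The top pick is the first qualifying crop, or
#' none if no crop qualifies.
#'
#' Candidates are the crops present in `features` whose harvest season
#' matches `season` (crops of other seasons are not comparable and are
#' ignored). Every candidate must have a model and a threshold entry.
#'
#' @param models Named list (by crop) of `fitted_regressor` or `krr_model`
#'   objects.
#' @param features Named list (by crop) of numeric feature vectors on each
#'   model's training scale (the seven seasonal weather averages plus
#'   area, in schema order).
#' @param thresholds A [threshold_table()].
#' @param region,season The query land unit and harvest season.
#' @return An object of class `recommendation`: `qualifying` (data.frame
#'   of crop, predicted production, tau, margin, sorted), `top_pick`
#'   (crop name or `NA`), `predictions` (all candidates), `region`,
#'   `season`.
#' @export
recommend_crops <- function(models, features, thresholds, region, season) {
  stopifnot(inherits(thresholds, "threshold_table"))
  season <- match.arg(season, c("kharif", "rabi"))
  kinds <- crop_kinds()
  candidates <- intersect(names(features),
                          kinds$crop[kinds$season == season])
  candidates <- sort(candidates)
  if (length(candidates) == 0L) {
    stop("configuration error: no candidate crop of season '", season,
         "' among the supplied features", call. = FALSE)
  }
  preds <- numeric(length(candidates))
  taus <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    crop <- candidates[i]
    if (is.null(models[[crop]])) {
      stop("configuration error: no model for crop '", crop, "'",
           call. = FALSE)
    }
    row <- thresholds[thresholds$region == region &
                        thresholds$season == season &
                        thresholds$crop == crop, ]
    if (nrow(row) != 1L) {
      stop("configuration error: no threshold for (", region, ", ", season,
           ", ", crop, ")", call. = FALSE)
    }
    x <- features[[crop]]
    preds[i] <- stats::predict(models[[crop]], matrix(as.numeric(x),
                                                      nrow = 1L))
    taus[i] <- row$tau
  }
  margin <- (preds - taus) / pmax(taus, 1e-9)
  all_preds <- data.frame(crop = candidates, predicted_production = preds,
                          tau = taus, margin = margin,
                          stringsAsFactors = FALSE)
  qual <- all_preds[all_preds$predicted_production >= all_preds$tau, ,
                    drop = FALSE]
  # descending margin; `order` on (-margin, crop) makes ties alphabetical
  qual <- qual[order(-qual$margin, qual$crop), , drop = FALSE]
  rownames(qual) <- NULL
  structure(list(
    qualifying = qual,
    top_pick = if (nrow(qual) > 0L) qual$crop[1L] else NA_character_,
    predictions = all_preds,
    region = region,
    season = season
  ), class = "recommendation")
}

#' @export
print.recommendation <- function(x, ...) {
  cat(sprintf("<recommendation> region=%s season=%s\n", x$region, x$season))
  if (nrow(x$qualifying) == 0L) {
    cat("  no crop qualifies\n")
  } else {
    cat("  top pick:", x$top_pick, "\n")
    print(x$qualifying, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Render a recommendation as text and JSON
#'
#' @param rec A `recommendation` from [recommend_crops()].
#' @return List with `text` (human-readable lines) and `json` (a JSON
#'   string that [recommendation_from_json()] parses back to an equal
#'   recommendation).
#' @export
recommend_report <- function(rec) {
  stopifnot(inherits(rec, "recommendation"))
  lines <- c(sprintf("Recommendation for region '%s', %s season",
                     rec$region, rec$season))
  if (nrow(rec$qualifying) == 0L) {
    lines <- c(lines, "no crop qualifies")
  } else {
    lines <- c(lines, sprintf("top pick: %s", rec$top_pick),
               sprintf("  %-8s predicted=%.3f tau=%.3f margin=%.3f",
                       rec$qualifying$crop,
                       rec$qualifying$predicted_production,
                       rec$qualifying$tau, rec$qualifying$margin))
  }
  json <- jsonlite::toJSON(list(
    region = rec$region, season = rec$season,
    top_pick = rec$top_pick, qualifying = rec$qualifying,
    predictions = rec$predictions
  ), auto_unbox = TRUE, digits = NA, na = "null")
  list(text = lines, json = as.character(json))
}

#' @rdname recommend_report
#' @param json A JSON string produced by [recommend_report()].
#' @export
recommendation_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  fix <- function(df) {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) {
      df <- data.frame(crop = character(0),
                       predicted_production = numeric(0),
                       tau = numeric(0), margin = numeric(0),
                       stringsAsFactors = FALSE)
    }
    rownames(df) <- NULL
    df
  }
  structure(list(
    qualifying = fix(obj$qualifying),
    top_pick = if (is.null(obj$top_pick)) NA_character_ else obj$top_pick,
    predictions = fix(obj$predictions),
    region = obj$region,
    season = obj$season
  ), class = "recommendation")
}
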