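# A model that predicts a fixed value everywhere: ridge on a constant
# target collapses to its intercept.
make_const_model <- function(value) {
  fit_regressor(regressor_spec("ridge"), matrix(c(1, 2, 3), ncol = 1),
                rep(value, 3))
}

dummy_features <- function(crops) {
  stats::setNames(lapply(crops, function(cr) 0), crops)
}

make_thresholds <- function(taus, region = "north", season = "kharif") {
  threshold_table(data.frame(region = region, season = season,
                             crop = names(taus), tau = unname(taus),
                             stringsAsFactors = FALSE))
}

test_that("crops qualifying their threshold are recommended, best first", {
  models <- list(aus = make_const_model(5), boro = make_const_model(1))
  thr <- make_thresholds(c(aus = 4, boro = 2))
  rec <- recommend_crops(models, dummy_features(c("aus", "boro")), thr,
                         region = "north", season = "kharif")
  expect_equal(rec$qualifying$crop, "aus")
  expect_equal(rec$top_pick, "aus")

  # nothing qualifies
  thr_high <- make_thresholds(c(aus = 50, boro = 50))
  rec2 <- recommend_crops(models, dummy_features(c("aus", "boro")),
                          thr_high, region = "north", season = "kharif")
  expect_equal(nrow(rec2$qualifying), 0L)
  expect_true(is.na(rec2$top_pick))
})

test_that("ranking uses the relative margin with alphabetical ties", {
  models <- list(aus = make_const_model(10), boro = make_const_model(10))
  thr <- make_thresholds(c(aus = 5, boro = 8))
  rec <- recommend_crops(models, dummy_features(c("aus", "boro")), thr,
                         region = "north", season = "kharif")
  expect_equal(rec$qualifying$crop, c("aus", "boro"))
  expect_equal(rec$qualifying$margin, c(1, 0.25), tolerance = 1e-12)

  # equal margins: alphabetical order decides
  thr_tie <- make_thresholds(c(aus = 5, boro = 5))
  rec_tie <- recommend_crops(models, dummy_features(c("aus", "boro")),
                             thr_tie, region = "north", season = "kharif")
  expect_equal(rec_tie$qualifying$crop, c("aus", "boro"))
})

test_that("candidates are restricted to the query season and must be configured", {
  models <- list(aus = make_const_model(5), wheat = make_const_model(5),
                 aman = make_const_model(5))
  feats <- dummy_features(c("aus", "wheat", "aman"))
  thr <- threshold_table(data.frame(
    region = "north", season = c("rabi", "rabi"),
    crop = c("wheat", "aman"), tau = c(1, 2), stringsAsFactors = FALSE))
  rec <- recommend_crops(models, feats, thr, region = "north",
                         season = "rabi")
  expect_setequal(rec$predictions$crop, c("wheat", "aman"))

  # a candidate without a threshold entry is a configuration error
  thr_partial <- threshold_table(data.frame(
    region = "north", season = "rabi", crop = "wheat", tau = 1,
    stringsAsFactors = FALSE))
  expect_error(recommend_crops(models, feats, thr_partial,
                               region = "north", season = "rabi"),
               "configuration error")
  # and so is a candidate without a model
  expect_error(recommend_crops(models["aus"],
                               dummy_features(c("aus", "boro")),
                               make_thresholds(c(aus = 1, boro = 1)),
                               region = "north", season = "kharif"),
               "configuration error")
})

test_that("recommendation equals a brute-force filter-and-sort oracle", {
  withr::local_seed(55)
  crops <- c("aus", "boro", "potato")  # the kharif candidates
  for (i in 1:300) {
    preds <- round(runif(3, 0, 10), 2)
    taus <- round(runif(3, 0, 10), 2)
    # force occasional exact ties and boundary hits
    if (i %% 7 == 0) taus[2] <- preds[2]
    if (i %% 11 == 0) {
      preds[3] <- preds[1]
      taus[3] <- taus[1]
    }
    names(preds) <- crops
    names(taus) <- crops
    models <- lapply(preds, make_const_model)
    rec <- recommend_crops(models, dummy_features(crops),
                           make_thresholds(taus),
                           region = "north", season = "kharif")
    # oracle: filter then sort by (-margin, crop)
    margin <- (preds - taus) / pmax(taus, 1e-9)
    keep <- names(preds)[preds >= taus]
    oracle <- keep[order(-margin[keep], keep)]
    expect_equal(rec$qualifying$crop, oracle)
    expect_equal(rec$top_pick,
                 if (length(oracle) > 0) oracle[1] else NA_character_)
    expect_equal(rec$qualifying$margin, unname(margin[oracle]),
                 tolerance = 1e-9)
  }
})

test_that("raising a crop's threshold never improves its standing", {
  models <- list(aus = make_const_model(8), boro = make_const_model(6))
  feats <- dummy_features(c("aus", "boro"))
  rank_of <- function(tau_aus) {
    rec <- recommend_crops(models, feats,
                           make_thresholds(c(aus = tau_aus, boro = 3)),
                           region = "north", season = "kharif")
    match("aus", rec$qualifying$crop)  # NA when excluded
  }
  ranks <- vapply(c(2, 4, 5.9, 8.5), rank_of, numeric(1))
  expect_equal(ranks[1], 1)  # large margin: first
  expect_true(is.na(ranks[4]))  # above the prediction: excluded
  expect_true(all(diff(ranks[!is.na(ranks)]) >= 0))
})

test_that("reports round-trip through JSON", {
  models <- list(aus = make_const_model(5), boro = make_const_model(1))
  thr <- make_thresholds(c(aus = 4, boro = 2))
  rec <- recommend_crops(models, dummy_features(c("aus", "boro")), thr,
                         region = "north", season = "kharif")
  rep <- recommend_report(rec)
  expect_true(any(grepl("top pick: aus", rep$text)))
  back <- recommendation_from_json(rep$json)
  expect_equal(back$qualifying, rec$qualifying)
  expect_equal(back$top_pick, rec$top_pick)
  expect_equal(back$region, rec$region)

  # empty recommendation is explicit
  rec0 <- recommend_crops(models, dummy_features(c("aus", "boro")),
                          make_thresholds(c(aus = 50, boro = 50)),
                          region = "north", season = "kharif")
  rep0 <- recommend_report(rec0)
  expect_true(any(grepl("no crop qualifies", rep0$text)))
  back0 <- recommendation_from_json(rep0$json)
  expect_equal(nrow(back0$qualifying), 0L)
  expect_true(is.na(back0$top_pick))
})
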