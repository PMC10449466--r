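test_that("mean imputation replaces missing cells with the observed mean", {
  ds <- make_tiny_dataset(3L)
  ds$rainfall <- c(4, NA, 8)
  res <- impute_missing(ds)
  expect_equal(res$dataset$rainfall, c(4, 6, 8))
  expect_equal(unname(res$report$n_imputed_by_column[["rainfall"]]), 1L)

  # identity on complete data
  clean <- make_tiny_dataset()
  res2 <- impute_missing(clean)
  expect_equal(as.data.frame(res2$dataset), as.data.frame(clean))
  expect_equal(sum(res2$report$n_imputed_by_column), 0L)

  # idempotence and mean preservation
  once <- impute_missing(ds)$dataset
  twice <- impute_missing(once)$dataset
  expect_identical(as.data.frame(once), as.data.frame(twice))
  expect_equal(mean(once$rainfall), mean(c(4, 8)))
})

test_that("an entirely missing column is an imputation error naming it", {
  ds <- make_tiny_dataset(2L)
  ds$sunshine <- c(NA_real_, NA_real_)
  expect_error(impute_missing(ds), "sunshine")
})

test_that("neighbor imputation averages the adjacent years within a series", {
  ds <- make_tiny_dataset(5L)
  ds$district <- "d01"
  ds$crop <- "aus"
  ds$year <- 2001:2005
  ds$rainfall <- c(10, NA, 30, NA, NA)
  res <- impute_missing(ds, strategy = "neighbor")
  # interior gap: mean of nearest observed before (10) and after (30)
  expect_equal(res$dataset$rainfall[2], 20)
  # trailing edge: only a preceding neighbour exists
  expect_equal(res$dataset$rainfall[4], 30)
  expect_equal(res$dataset$rainfall[5], 30)
})

test_that("coercion strips formatting, applies bounds, and crosses temps", {
  ds <- make_tiny_dataset(3L)
  ds$area <- c("1,250", " 99 ", "2000")  # wrong-format cells
  ds$humidity[1] <- 150                  # out of bounds
  ds$temp_min[2] <- 25
  ds$temp_max[2] <- 20                   # contradictory pair
  res <- coerce_and_filter(ds)
  expect_equal(res$dataset$area, c(1250, 99, 2000))
  expect_true(is.na(res$dataset$humidity[1]))
  expect_true(is.na(res$dataset$temp_min[2]))
  expect_true(is.na(res$dataset$temp_max[2]))
  expect_equal(res$report$n_coerced, 3L)  # 1 bound + 2 cross-field blanks
})

test_that("weather aggregation means the window months, resolving wraps", {
  wx <- make_weather_table(years = rep(2010L, 3), months = 6:8,
                           rainfall = c(100, 200, 300))
  out <- aggregate_weather(wx, "aus", "dhaka", 2010L)
  expect_equal(unname(out["rainfall"]), 200)
  expect_equal(unname(out["temp_max"]), 30)

  # aman's December belongs to the previous calendar year
  wx2 <- make_weather_table(years = c(2009L, 2010L), months = c(12L, 1L),
                            rainfall = c(10, 30))
  out2 <- aggregate_weather(wx2, "aman", "dhaka", 2010L)
  expect_equal(unname(out2["rainfall"]), 20)

  # missing month is an error naming the gap
  expect_error(aggregate_weather(wx, "aus", "dhaka", 2011L),
               "aggregation error")
  expect_error(
    aggregate_weather(make_weather_table(years = rep(2010L, 2),
                                         months = 6:7),
                      "aus", "dhaka", 2010L),
    "\\(2010, 8\\)")
})

test_that("integration inner-joins area, production and weather", {
  wx <- rbind(
    make_weather_table("dhaka", rep(2010L, 3), 6:8, rainfall = 100),
    make_weather_table("khulna", rep(2010L, 3), 6:8, rainfall = 400)
  )
  areas <- data.frame(district = c("dhaka", "khulna", "dhaka"),
                      year = 2010L, crop = "aus",
                      area = c(1000, 2000, 3000))
  areas$year[3] <- 2011L  # no production row for this one
  prods <- data.frame(district = c("dhaka", "khulna"), year = 2010L,
                      crop = "aus", production = c(900, 1800))
  ds <- integrate_tables(wx, areas, prods)
  expect_s3_class(ds, "crop_dataset")
  expect_equal(nrow(ds), 2L)  # unmatched area row excluded
  expect_equal(ds$rainfall[ds$district == "dhaka"], 100)
  expect_equal(ds$rainfall[ds$district == "khulna"], 400)
  expect_equal(nrow(validate_crop_dataset(ds)$violations), 0L)

  expect_warning(
    integrate_tables(wx, areas[0, ], prods),
    "empty")
})

test_that("reduction drops exact duplicates and all-missing-predictor junk", {
  ds <- make_tiny_dataset(3L)
  dup <- as_crop_dataset(rbind(as.data.frame(ds), as.data.frame(ds)[2, ]))
  res <- reduce_dataset(dup)
  expect_equal(nrow(res$dataset), 3L)
  expect_equal(res$report$n_dropped_duplicates, 1L)

  junk <- make_tiny_dataset(3L)
  junk[2, predictor_columns()] <- NA_real_
  res2 <- reduce_dataset(junk)
  expect_equal(nrow(res2$dataset), 2L)
  expect_equal(res2$report$n_dropped_junk, 1L)

  # identity on clean data; keys unique afterwards
  res3 <- reduce_dataset(ds)
  expect_equal(as.data.frame(res3$dataset), as.data.frame(ds))
  key <- with(res3$dataset, paste(district, year, crop))
  expect_false(anyDuplicated(key) > 0)
})

test_that("min-max normalization maps to [0,1], handles constants, inverts", {
  ds <- make_tiny_dataset(3L)
  ds$rainfall <- c(2, 4, 6)
  params <- minmax_fit(ds)
  p_rain <- params[params$column == "rainfall", ]
  expect_equal(p_rain$min, 2)
  expect_equal(p_rain$max, 6)

  norm <- minmax_apply(ds, params)
  expect_equal(norm$rainfall, c(0, 0.5, 1))
  for (cl in numeric_columns()) {
    expect_true(all(norm[[cl]] >= 0 & norm[[cl]] <= 1), info = cl)
  }

  back <- minmax_invert(norm, params)
  expect_equal(back$rainfall, ds$rainfall, tolerance = 1e-12)
  expect_equal(back$production, ds$production, tolerance = 1e-12)

  const <- ds
  const$sunshine <- rep(5, 3)
  expect_warning(normc <- minmax_apply(const, minmax_fit(const)),
                 "constant")
  expect_equal(normc$sunshine, rep(0, 3))

  ds_na <- ds
  ds_na$rainfall[1] <- NA
  expect_error(minmax_fit(ds_na), "impute_missing")
})

test_that("test-set values outside the training range are not clipped", {
  train <- make_tiny_dataset(3L)
  train$rainfall <- c(2, 4, 6)
  params <- minmax_fit(train)
  test <- make_tiny_dataset(3L)
  test$rainfall <- c(0, 4, 10)
  norm <- minmax_apply(test, params)
  expect_equal(norm$rainfall, c(-0.5, 0.5, 2))
})

test_that("the full cleaning chain is deterministic", {
  gen <- generate_crop_data(synthetic_config(n_per_crop = 40L,
                                             missing_rate = 0.1,
                                             seed = 3L))
  r1 <- preprocess_pipeline(gen$dataset, normalize = TRUE)
  r2 <- preprocess_pipeline(gen$dataset, normalize = TRUE)
  expect_identical(as.data.frame(r1$dataset), as.data.frame(r2$dataset))
  expect_identical(r1$norm_params, r2$norm_params)
})
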