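# Shared fixtures, all built in code.

# A small fully populated dataset with unique keys and valid values.
make_tiny_dataset <- function(n = 6L) {
  kinds <- crop_kinds()$crop
  as_crop_dataset(data.frame(
    district = sprintf("d%02d", seq_len(n)),
    year = 2000L + seq_len(n),
    crop = rep_len(kinds, n),
    rainfall = seq(100, 200, length.out = n),
    temp_max = seq(28, 33, length.out = n),
    temp_min = seq(15, 20, length.out = n),
    humidity = seq(60, 85, length.out = n),
    wind_speed = seq(3, 8, length.out = n),
    cloud_coverage = seq(1, 6, length.out = n),
    sunshine = seq(5, 8, length.out = n),
    area = seq(1000, 2000, length.out = n),
    production = seq(900, 2100, length.out = n),
    stringsAsFactors = FALSE
  ))
}

# Monthly weather table covering the given months for one district.
make_weather_table <- function(district = "dhaka", years, months,
                               rainfall = 100) {
  stopifnot(length(years) == length(months))
  n <- length(months)
  data.frame(
    district = district, year = years, month = months,
    rainfall = rep_len(rainfall, n),
    temp_max = 30, temp_min = 20, humidity = 75,
    wind_speed = 5, cloud_coverage = 3, sunshine = 6,
    stringsAsFactors = FALSE
  )
}

# Noisy linear regression data where ridge should do well.
make_linear_xy <- function(n = 100L, p = 3L, noise_sd = 0.1, seed = 7L) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p)
    beta <- seq_len(p)
    y <- drop(X %*% beta) + stats::rnorm(n, 0, noise_sd)
    list(X = X, y = y, beta = beta)
  })
}

# A small preprocessed synthetic dataset for model-level tests.
make_model_dataset <- function(n_per_crop = 60L, seed = 11L) {
  gen <- generate_crop_data(synthetic_config(n_per_crop = n_per_crop,
                                             seed = seed))
  res <- preprocess_pipeline(gen$dataset, normalize = TRUE)
  res$dataset
}
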