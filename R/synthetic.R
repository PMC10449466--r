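#' Default per-crop weather climatology for the simulator
#'
#' Means and standard deviations of each of the seven seasonal weather
#' averages for each crop, loosely shaped like a South-Asian monsoon
#' climate: the monsoon crop (aus, June--August) is hot, wet, humid and
#' cloudy; the winter crops (aman, wheat, potato) are cool, dry and sunny;
#' boro (March--May) sits between. Standard deviations are sized so that
#' the simulator's +/- 3 sd truncation keeps every draw physically valid
#' (humidity within \[0, 100\], non-negative rainfall, wind and cloud, and
#' `temp_min` below `temp_max`). These are design defaults for generating
#' plausible data, not a calibration to any real climatology.
#'
#' @return data.frame with columns `crop`, `variable`, `mean`, `sd`
#'   (5 crops x 7 variables = 35 rows).
#' @export
default_weather_profile <- function() {
  row <- function(crop, rainfall, temp_max, temp_min, humidity,
                  wind_speed, cloud_coverage, sunshine) {
    vars <- weather_columns()
    vals <- rbind(rainfall, temp_max, temp_min, humidity, wind_speed,
                  cloud_coverage, sunshine)
    data.frame(crop = crop, variable = vars,
               mean = vals[, 1L], sd = vals[, 2L],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  rbind(
    #            rainfall      temp_max     temp_min     humidity    wind        cloud        sunshine
    row("aus",    c(450, 120), c(32, 1.5), c(25, 0.8), c(85, 4), c(8, 2),   c(6, 1),    c(5, 1)),
    row("aman",   c(15, 5),    c(26, 1.5), c(14, 2),   c(75, 5), c(5, 1.5), c(2, 0.6),  c(7, 1)),
    row("boro",   c(180, 60),  c(33, 2),   c(21, 1.8), c(75, 5), c(7, 2),   c(4, 1),    c(7, 1)),
    row("potato", c(40, 13),   c(28, 2),   c(16, 1.8), c(70, 5), c(6, 1.5), c(2.5, 0.8), c(8, 1)),
    row("wheat",  c(25, 8),    c(26, 2),   c(12, 2),   c(70, 5), c(5, 1.5), c(2, 0.6),  c(7.5, 1))
  )
}

#' Default log-yield coefficients for the simulator
#'
#' Per-standard-deviation effects of each weather variable on log yield
#' (tons per acre), shared across crops, plus a quadratic heat penalty on
#' the maximum-temperature z-score encoding a concave yield response to
#' heat. Rain and sunshine help, humidity, wind and cloud cover hurt
#' mildly, and extreme heat hurts quadratically.
#'
#' @return List with `beta` (named vector over the seven weather
#'   variables), `beta_quad_tmax` (>= 0), and `beta0` (named per-crop log
#'   baseline yield in tons/acre).
#' @export
default_yield_coefficients <- function() {
  list(
    beta = c(rainfall = 0.10, temp_max = 0.05, temp_min = 0.03,
             humidity = -0.04, wind_speed = -0.03,
             cloud_coverage = -0.05, sunshine = 0.08),
    beta_quad_tmax = 0.04,
    beta0 = log(c(aus = 0.9, aman = 1.0, boro = 1.4, potato = 3.5,
                  wheat = 1.1))
  )
}

#' Configuration for the synthetic crop-data generator
#'
#' The defaults emulate the structure of the kind of national crop archive
#' the pipeline targets: five crops with 1,400 records each (7,000 total)
#' spread over 23 districts and harvest years 1969--2021, eight predictors
#' and a production target.
#'
#' Each crop's records carry distinct (district, year) keys — drawn
#' uniformly without replacement from the district-by-year grid — so a
#' clean draw satisfies the dataset's unique-key invariant; the grid
#' (`n_districts` times the number of years) must therefore be at least
#' `n_per_crop`. The default of 27 districts is the smallest round count
#' that accommodates 1,400 records per crop over 53 years.
#'
#' @param n_per_crop Records per crop (default 1400).
#' @param n_districts Number of districts (default 27).
#' @param years Inclusive year range, `c(first, last)` (default 1969--2021).
#' @param weather_profile Per-(crop, variable) means/sds; see
#'   [default_weather_profile()].
#' @param area_lognormal data.frame of per-crop `meanlog`, `sdlog` for the
#'   lognormal cultivation-area draw (acres).
#' @param yield Coefficients, see [default_yield_coefficients()].
#' @param district_sd Standard deviation of the per-district log-yield
#'   effect (default 0.10).
#' @param trend_per_year Linear drift of log yield per year since the
#'   first year (default 0.004).
#' @param noise_sd Standard deviation of the log-yield noise
#'   (default 0.10).
#' @param missing_rate,duplicate_rate Corruption rates applied by
#'   [generate_crop_data()] via [inject_missing()] and
#'   [inject_duplicates()] (defaults 0).
#' @param seed Integer seed; generation is deterministic given the config.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_crop = 1400L,
                             n_districts = 27L,
                             years = c(1969L, 2021L),
                             weather_profile = default_weather_profile(),
                             area_lognormal = data.frame(
                               crop = c("aus", "aman", "boro", "potato",
                                        "wheat"),
                               meanlog = c(9.0, 9.5, 9.3, 7.5, 7.8),
                               sdlog = c(0.8, 0.8, 0.8, 0.8, 0.8)),
                             yield = default_yield_coefficients(),
                             district_sd = 0.10,
                             trend_per_year = 0.004,
                             noise_sd = 0.10,
                             missing_rate = 0,
                             duplicate_rate = 0,
                             seed = 42L) {
  stopifnot(n_per_crop >= 1L, n_districts >= 1L,
            length(years) == 2L, years[1] <= years[2],
            all(weather_profile$sd >= 0), all(area_lognormal$sdlog >= 0),
            district_sd >= 0, noise_sd >= 0,
            missing_rate >= 0, missing_rate <= 1,
            duplicate_rate >= 0, duplicate_rate <= 1)
  n_keys <- n_districts * (years[2] - years[1] + 1L)
  if (n_per_crop > n_keys) {
    stop("configuration error: n_per_crop (", n_per_crop, ") exceeds the ",
         "number of distinct (district, year) keys (", n_keys, ")",
         call. = FALSE)
  }
  structure(list(
    n_per_crop = as.integer(n_per_crop),
    n_districts = as.integer(n_districts),
    years = as.integer(years),
    weather_profile = weather_profile,
    area_lognormal = area_lognormal,
    yield = yield,
    district_sd = district_sd,
    trend_per_year = trend_per_year,
    noise_sd = noise_sd,
    missing_rate = missing_rate,
    duplicate_rate = duplicate_rate,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

rnorm_trunc3 <- function(n, mean, sd) {
  # normal truncated to mean +/- 3 sd by resampling the tails
  x <- stats::rnorm(n, mean, sd)
  bad <- abs(x - mean) > 3 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- abs(x - mean) > 3 * sd
  }
  x
}

#' Generate a synthetic crop dataset with stored ground truth
#'
#' For each crop and each of `n_per_crop` records: a district is drawn
#' uniformly, a harvest year uniformly from the year range, each weather
#' variable from a normal truncated at +/- 3 sd around its (crop,
#' variable) climatology, and cultivation area from a per-crop lognormal.
#' Log yield is a linear function of the weather z-scores (standardized by
#' the climatology) with a quadratic penalty on the maximum-temperature
#' z-score, plus a district effect, a linear year trend and Gaussian
#' noise; production is `area * exp(log yield)` tons, so it is always
#' positive and proportional to area. Missingness and duplicates are then
#' injected at the configured rates. The returned ground truth stores the
#' realized district effects, coefficients and each record's noiseless
#' production, enabling recovery tests.
#'
#' @param config A [synthetic_config()].
#' @return List with `dataset` (a `crop_dataset`) and `truth` (list:
#'   `district_effects`, `beta`, `beta_quad_tmax`, `beta0`,
#'   `trend_per_year`, `noise_sd`, `noiseless_production`, `config`).
#' @export
generate_crop_data <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    kinds <- crop_kinds()$crop
    districts <- sprintf("district_%02d", seq_len(config$n_districts))
    u <- stats::rnorm(config$n_districts, 0, config$district_sd)
    names(u) <- districts
    yc <- config$yield
    wp <- config$weather_profile

    year_seq <- seq(config$years[1], config$years[2])
    key_grid <- expand.grid(district = districts, year = year_seq,
                            stringsAsFactors = FALSE)
    per_crop <- lapply(kinds, function(crop) {
      n <- config$n_per_crop
      key <- key_grid[sample.int(nrow(key_grid), n), , drop = FALSE]
      d <- key$district
      t <- key$year
      w <- matrix(NA_real_, n, length(weather_columns()),
                  dimnames = list(NULL, weather_columns()))
      z <- w
      for (v in weather_columns()) {
        p <- wp[wp$crop == crop & wp$variable == v, ]
        w[, v] <- rnorm_trunc3(n, p$mean, p$sd)
        z[, v] <- if (p$sd > 0) (w[, v] - p$mean) / p$sd else 0
      }
      al <- config$area_lognormal
      al <- al[al$crop == crop, ]
      area <- stats::rlnorm(n, al$meanlog, al$sdlog)
      log_yield0 <- yc$beta0[[crop]] +
        drop(z %*% yc$beta[weather_columns()]) -
        yc$beta_quad_tmax * z[, "temp_max"]^2 +
        u[d] +
        config$trend_per_year * (t - config$years[1])
      eps <- stats::rnorm(n, 0, config$noise_sd)
      data.frame(
        district = d, year = t, crop = crop, as.data.frame(w),
        area = area,
        production = area * exp(log_yield0 + eps),
        noiseless = area * exp(log_yield0),
        stringsAsFactors = FALSE
      )
    })
    df <- do.call(rbind, per_crop)
    noiseless <- df$noiseless
    df$noiseless <- NULL
    ds <- as_crop_dataset(df)
    if (config$missing_rate > 0) {
      ds <- inject_missing(ds, config$missing_rate,
                           seed = config$seed + 1L)
    }
    if (config$duplicate_rate > 0) {
      ds <- inject_duplicates(ds, config$duplicate_rate,
                              seed = config$seed + 2L)
    }
    list(
      dataset = ds,
      truth = list(
        district_effects = u,
        beta = yc$beta,
        beta_quad_tmax = yc$beta_quad_tmax,
        beta0 = yc$beta0,
        trend_per_year = config$trend_per_year,
        noise_sd = config$noise_sd,
        noiseless_production = noiseless,
        config = config
      )
    )
  })
}

#' Corrupt a dataset with missing cells or duplicate rows
#'
#' `inject_missing()` sets each predictor cell independently missing with
#' probability `rate`; `inject_duplicates()` appends `ceiling(rate * n)`
#' uniformly chosen rows as exact copies. Both are seeded and exist to
#' exercise the cleaning pipeline.
#'
#' @param ds A `crop_dataset`.
#' @param rate Probability / fraction in \[0, 1\].
#' @param seed Integer seed.
#' @return The corrupted `crop_dataset`.
#' @export
inject_missing <- function(ds, rate, seed = 1L) {
  stopifnot(inherits(ds, "crop_dataset"), rate >= 0, rate <= 1)
  if (rate == 0 || nrow(ds) == 0L) return(ds)
  withr::with_seed(as.integer(seed), {
    for (cl in predictor_columns()) {
      hit <- stats::runif(nrow(ds)) < rate
      ds[[cl]][hit] <- NA_real_
    }
  })
  ds
}

#' @rdname inject_missing
#' @export
inject_duplicates <- function(ds, rate, seed = 1L) {
  stopifnot(inherits(ds, "crop_dataset"), rate >= 0, rate <= 1)
  n <- nrow(ds)
  if (rate == 0 || n == 0L) return(ds)
  k <- ceiling(rate * n)
  idx <- withr::with_seed(as.integer(seed), sample.int(n, k, replace = TRUE))
  out <- rbind(as.data.frame(ds), as.data.frame(ds)[idx, , drop = FALSE])
  as_crop_dataset(out,
                  normalization = attr(ds, "normalization"),
                  norm_params = attr(ds, "norm_params"))
}
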