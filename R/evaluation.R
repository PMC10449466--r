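check_metric_input <- function(y, yhat) {
  if (length(y) == 0L) stop("empty-input error: no observations",
                            call. = FALSE)
  if (length(y) != length(yhat)) {
    stop("shape error: y and yhat lengths differ (", length(y), " vs ",
         length(yhat), ")", call. = FALSE)
  }
  if (!all(is.finite(y)) || !all(is.finite(yhat))) {
    stop("non-finite values in y or yhat", call. = FALSE)
  }
  invisible(TRUE)
}

#' Regression error metrics
#'
#' The four evaluation metrics used throughout: mean absolute error
#' \eqn{\frac{1}{n}\sum |y - \hat y|}, mean squared error
#' \eqn{\frac{1}{n}\sum (y - \hat y)^2}, its square root (RMSE), and the
#' coefficient of determination
#' \eqn{R^2 = 1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2}.
#'
#' @param y Observed values (finite, non-empty).
#' @param yhat Predicted values, same length as `y`.
#' @return A single numeric value.
#' @export
#' @examples
#' mae(c(3, -0.5, 2, 7), c(2.5, 0, 2, 8))   # 0.5
#' mse(c(3, -0.5, 2, 7), c(2.5, 0, 2, 8))   # 0.375
mae <- function(y, yhat) {
  check_metric_input(y, yhat)
  mean(abs(y - yhat))
}

#' @rdname mae
#' @export
mse <- function(y, yhat) {
  check_metric_input(y, yhat)
  mean((y - yhat)^2)
}

#' @rdname mae
#' @export
rmse <- function(y, yhat) sqrt(mse(y, yhat))

#' @rdname mae
#' @export
r_squared <- function(y, yhat) {
  check_metric_input(y, yhat)
  if (length(y) < 2L) stop("r_squared requires at least 2 observations",
                           call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    stop("r_squared is undefined for a constant y", call. = FALSE)
  }
  1 - sum((y - yhat)^2) / ss_tot
}

#' Split a dataset into training and testing partitions
#'
#' Uniform random seeded partition. The training set gets
#' `ceiling(train_fraction * n)` rows; the two parts are disjoint and
#' exhaustive, with original row order preserved inside each part.
#'
#' @param ds A `crop_dataset` or plain data.frame.
#' @param train_fraction Fraction of rows assigned to training, in (0, 1).
#' @param seed Integer seed; identical seeds give identical partitions.
#' @return List with `train` and `test` subsets (same class as `ds`) and
#'   an attribute-free `train_idx` integer vector.
#' @export
split_dataset <- function(ds, train_fraction, seed = 42L) {
  n <- nrow(ds)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  n_train <- ceiling(train_fraction * n)
  if (n_train < 1L || n - n_train < 1L) {
    stop("size error: split leaves an empty partition (n = ", n, ")",
         call. = FALSE)
  }
  idx <- sort(withr::with_seed(as.integer(seed), sample.int(n, n_train)))
  list(train = ds[idx, , drop = FALSE],
       test = ds[-idx, , drop = FALSE],
       train_idx = idx)
}

#' Extract the model matrix and target from a crop dataset
#'
#' @param ds A `crop_dataset`.
#' @return List with `X` (numeric matrix of the eight predictors) and `y`
#'   (production target).
#' @export
model_matrix <- function(ds) {
  list(X = as.matrix(as.data.frame(ds)[, predictor_columns()]),
       y = ds$production)
}

fit_any <- function(spec, X, y) {
  if (inherits(spec, "blend_config")) fit_krr(X, y, spec)
  else fit_regressor(spec, X, y)
}

#' Run the multi-phase repeated train/test evaluation protocol
#'
#' For each phase (a train fraction) and each of its trials: draw a fresh
#' seeded train/test split, fit every model on the training rows, and
#' score its test predictions with all four metrics. Trials differ only in
#' the split seed (`seed + trial - 1`); model seeds stay fixed at their
#' spec values so that split variance is isolated. The default phases are
#' the 80:20, 50:50 and 30:70 train:test ratios with 10 trials each.
#'
#' @param ds A preprocessed `crop_dataset` (no missing values).
#' @param specs Named list of [regressor_spec()] and/or [blend_config()]
#'   objects; names label the models in the report.
#' @param phases data.frame with columns `train_fraction` and `n_trials`.
#' @param seed Base seed for the split sequence.
#' @return An object of class `metrics_report`: `$trials` (one row per
#'   model, phase, trial with mae/mse/rmse/r2), `$by_phase` (per-model,
#'   per-phase means) and `$pooled` (per-model means over all trials).
#' @export
run_experiment <- function(ds, specs,
                           phases = data.frame(
                             train_fraction = c(0.8, 0.5, 0.3),
                             n_trials = c(10L, 10L, 10L)),
                           seed = 42L) {
  stopifnot(is.list(specs), length(specs) > 0L,
            !is.null(names(specs)), all(nzchar(names(specs))))
  mm <- model_matrix(ds)
  rows <- list()
  for (p in seq_len(nrow(phases))) {
    f <- phases$train_fraction[p]
    for (trial in seq_len(phases$n_trials[p])) {
      sp <- split_dataset(as.data.frame(ds), f, seed = seed + trial - 1L)
      X_tr <- mm$X[sp$train_idx, , drop = FALSE]
      y_tr <- mm$y[sp$train_idx]
      X_te <- mm$X[-sp$train_idx, , drop = FALSE]
      y_te <- mm$y[-sp$train_idx]
      for (nm in names(specs)) {
        model <- tryCatch(fit_any(specs[[nm]], X_tr, y_tr),
                          error = function(e) {
                            stop("model '", nm, "' failed in phase ", f,
                                 " trial ", trial, ": ",
                                 conditionMessage(e), call. = FALSE)
                          })
        pred <- stats::predict(model, X_te)
        rows[[length(rows) + 1L]] <- data.frame(
          model = nm, train_fraction = f, trial = trial,
          mae = mae(y_te, pred), mse = mse(y_te, pred),
          rmse = rmse(y_te, pred), r2 = r_squared(y_te, pred),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  trials <- do.call(rbind, rows)
  agg <- function(df, by) {
    stats::aggregate(df[, c("mae", "mse", "rmse", "r2")], by = by, FUN = mean)
  }
  by_phase <- agg(trials, list(model = trials$model,
                               train_fraction = trials$train_fraction))
  pooled <- agg(trials, list(model = trials$model))
  structure(list(trials = trials, by_phase = by_phase, pooled = pooled),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> pooled over",
      length(unique(paste(x$trials$train_fraction, x$trials$trial))),
      "trial(s)\n")
  print(x$pooled, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Collect aligned test-error series for forecast comparison
#'
#' Fits every model on one seeded train/test split and returns each
#' model's test-set error series (observed minus predicted), aligned by
#' test row — the input the Diebold--Mariano comparison needs.
#'
#' @inheritParams run_experiment
#' @param train_fraction Training fraction for the single split.
#' @return data.frame with one column of errors per model.
#' @export
collect_test_errors <- function(ds, specs, train_fraction = 0.8,
                                seed = 42L) {
  mm <- model_matrix(ds)
  sp <- split_dataset(as.data.frame(ds), train_fraction, seed = seed)
  X_tr <- mm$X[sp$train_idx, , drop = FALSE]
  y_tr <- mm$y[sp$train_idx]
  X_te <- mm$X[-sp$train_idx, , drop = FALSE]
  y_te <- mm$y[-sp$train_idx]
  out <- lapply(specs, function(s) {
    y_te - stats::predict(fit_any(s, X_tr, y_tr), X_te)
  })
  as.data.frame(out)
}
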