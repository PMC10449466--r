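#' Specify a regressor
#'
#' Builds a validated specification for one of the six supported regression
#' families. Hyperparameters not supplied take the family default.
#'
#' Families and their hyperparameters:
#' \describe{
#'   \item{`knn`}{k-nearest neighbours; `k` (>= 1, default 5).}
#'   \item{`rf`}{random forest; `trees` (>= 1, default 20).}
#'   \item{`ridge`}{ridge regression; `alpha` (> 0, default 0.01), the L2
#'     penalty on the coefficients (intercept unpenalized).}
#'   \item{`svr`}{epsilon support vector regression, linear kernel;
#'     `C` (> 0, default 100).}
#'   \item{`nb`}{naive-Bayes regression via target discretization;
#'     `bins` (>= 2, default 20), `binning` ("quantile" or "equal_width").}
#'   \item{`gbdt`}{gradient-boosted regression trees;
#'     `learning_rate` (in (0, 1], default 0.05), `trees` (default 100),
#'     `max_depth` (default 6).}
#' }
#'
#' @param family One of `"knn"`, `"rf"`, `"ridge"`, `"svr"`, `"nb"`,
#'   `"gbdt"`.
#' @param ... Family hyperparameters (see Details).
#' @param seed Integer seed for stochastic families (`rf`, `gbdt`);
#'   ignored by deterministic ones.
#' @return An object of class `regressor_spec`.
#' @export
#' @examples
#' regressor_spec("ridge", alpha = 0.01)
#' regressor_spec("rf", trees = 20, seed = 42)
regressor_spec <- function(family = c("knn", "rf", "ridge", "svr", "nb", "gbdt"),
                           ..., seed = NULL) {
  family <- match.arg(family)
  defaults <- switch(family,
    knn   = list(k = 5L),
    rf    = list(trees = 20L),
    ridge = list(alpha = 0.01),
    svr   = list(C = 100),
    nb    = list(bins = 20L, binning = "quantile"),
    gbdt  = list(learning_rate = 0.05, trees = 100L, max_depth = 6L)
  )
  hp <- utils::modifyList(defaults, list(...))
  unknown <- setdiff(names(hp), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown hyperparameter(s) for family '", family, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ok <- switch(family,
    knn   = hp$k >= 1,
    rf    = hp$trees >= 1,
    ridge = hp$alpha > 0,
    svr   = hp$C > 0,
    nb    = hp$bins >= 2 && hp$binning %in% c("quantile", "equal_width"),
    gbdt  = hp$learning_rate > 0 && hp$learning_rate <= 1 && hp$trees >= 1
  )
  if (!isTRUE(ok)) {
    stop("invalid hyperparameters for family '", family, "'", call. = FALSE)
  }
  structure(list(family = family, hyperparameters = hp,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "regressor_spec")
}

#' @export
print.regressor_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparameters), unlist(x$hyperparameters),
              sep = "=", collapse = ", ")
  cat(sprintf("<regressor_spec> %s (%s)%s\n", x$family, hp,
              if (is.null(x$seed)) "" else paste0(" seed=", x$seed)))
  invisible(x)
}

#' Default regressor specifications for the benchmark suite
#'
#' The hyperparameter settings used throughout the toolkit's experiments:
#' SVR with a linear kernel and C = 100; random forest with 20 trees and
#' seed 42; ridge with alpha = 0.01; gradient-boosted trees with learning
#' rate 0.05; naive-Bayes regression with 20 quantile bins; and KNN with
#' k = 5.
#'
#' @return Named list of `regressor_spec` objects
#'   (`svr`, `nb`, `rf`, `ridge`, `gbdt`, `knn`).
#' @export
default_regressor_specs <- function() {
  list(
    svr   = regressor_spec("svr", C = 100),
    nb    = regressor_spec("nb", bins = 20L, binning = "quantile"),
    rf    = regressor_spec("rf", trees = 20L, seed = 42L),
    ridge = regressor_spec("ridge", alpha = 0.01),
    gbdt  = regressor_spec("gbdt", learning_rate = 0.05, seed = 42L),
    knn   = regressor_spec("knn", k = 5L)
  )
}

as_feature_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

check_xy <- function(X, y) {
  if (nrow(X) != length(y)) {
    stop("shape error: X has ", nrow(X), " rows but y has length ",
         length(y), call. = FALSE)
  }
  if (nrow(X) < 1L) stop("fit requires at least one row", call. = FALSE)
  if (anyNA(X) || anyNA(y)) {
    stop("missing values in X or y; impute before fitting", call. = FALSE)
  }
  invisible(TRUE)
}

with_spec_seed <- function(spec, expr) {
  if (is.null(spec$seed)) expr else withr::with_seed(spec$seed, expr)
}

#' Fit a regressor to a feature matrix and target
#'
#' Dispatches to the family's backend: `caret::knnreg` (knn),
#' `randomForest::randomForest` (rf), a closed-form penalized
#' least-squares solve (ridge), `e1071::svm` with a linear kernel and no
#' internal rescaling (svr), `e1071::naiveBayes` on the discretized target
#' (nb), or `xgboost` (gbdt). Fits are deterministic given
#' `(spec, X, y, seed)`; stochastic families are fitted under the spec's
#' seed without disturbing the caller's RNG state.
#'
#' @param spec A [regressor_spec()].
#' @param X Feature matrix or data.frame (rows = observations).
#' @param y Numeric target vector, one value per row of `X`.
#' @return An object of class `fitted_regressor` with elements `spec`,
#'   `fit` (backend-specific state) and `n_features`.
#' @export
fit_regressor <- function(spec, X, y) {
  stopifnot(inherits(spec, "regressor_spec"))
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  check_xy(X, y)
  hp <- spec$hyperparameters
  fit <- switch(spec$family,
    knn = caret::knnreg(X, y, k = as.integer(hp$k)),
    rf = with_spec_seed(spec,
      randomForest::randomForest(x = X, y = y,
                                 ntree = as.integer(hp$trees))),
    ridge = ridge_fit(X, y, hp$alpha),
    svr = e1071::svm(x = X, y = y, type = "eps-regression",
                     kernel = "linear", cost = hp$C, scale = FALSE),
    nb = nb_regress_fit_impl(X, y, n_bins = as.integer(hp$bins),
                             binning = hp$binning),
    gbdt = xgboost::xgboost(x = X, y = y,
                            objective = "reg:squarederror",
                            nrounds = as.integer(hp$trees),
                            learning_rate = hp$learning_rate,
                            max_depth = as.integer(hp$max_depth),
                            nthreads = 1L,
                            seed = if (is.null(spec$seed)) 0L else spec$seed,
                            verbosity = 0L)
  )
  structure(list(spec = spec, fit = fit, n_features = ncol(X),
                 feature_names = colnames(X)),
            class = "fitted_regressor")
}

# Ridge with unpenalized intercept: coefficients solve
# (Xc'Xc + alpha I) w = Xc'yc on centred data, matching the textbook
# objective ||y - b - Xw||^2 + alpha ||w||^2.
ridge_fit <- function(X, y, alpha) {
  x_means <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_means)
  w <- solve(crossprod(Xc) + diag(alpha, ncol(X)),
             crossprod(Xc, y - y_mean))
  list(coefficients = drop(w),
       intercept = y_mean - drop(x_means %*% w))
}

#' Naive-Bayes regression by target discretization
#'
#' Adapts the Gaussian naive-Bayes classifier to a continuous target: `y`
#' is discretized into `n_bins` bins (quantile or equal-width breaks), a
#' Gaussian naive-Bayes classifier with bin-frequency priors is fitted on
#' the binned labels, and the prediction is the posterior-weighted mean of
#' the per-bin target means, \eqn{\sum_b P(b \mid x)\,\bar{y}_b}.
#'
#' @param X Feature matrix.
#' @param y Numeric target with at least `n_bins` distinct values when
#'   `binning = "quantile"`.
#' @param n_bins Number of target bins (>= 2).
#' @param binning `"quantile"` or `"equal_width"`.
#' @return A `fitted_regressor` of family `nb`.
#' @export
nb_regress_fit <- function(X, y, n_bins = 20L,
                           binning = c("quantile", "equal_width")) {
  binning <- match.arg(binning)
  fit_regressor(regressor_spec("nb", bins = n_bins, binning = binning), X, y)
}

nb_regress_fit_impl <- function(X, y, n_bins, binning) {
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  breaks <- if (binning == "quantile") {
    if (length(unique(y)) < n_bins) {
      stop("binning error: y has fewer than ", n_bins, " distinct values",
           call. = FALSE)
    }
    unique(stats::quantile(y, probs = seq(0, 1, length.out = n_bins + 1L),
                           names = FALSE))
  } else {
    if (min(y) == max(y)) {
      stop("binning error: y is constant", call. = FALSE)
    }
    seq(min(y), max(y), length.out = n_bins + 1L)
  }
  if (length(breaks) < 3L) {
    stop("binning error: could not form >= 2 distinct bins", call. = FALSE)
  }
  labels <- cut(y, breaks = breaks, include.lowest = TRUE)
  labels <- droplevels(labels)
  bin_means <- tapply(y, labels, mean)
  nb <- e1071::naiveBayes(x = as.data.frame(X), y = labels)
  # zero within-bin spread makes the Gaussian density degenerate; floor the
  # per-bin sd at a small fraction of the feature's overall spread
  for (v in names(nb$tables)) {
    tab <- nb$tables[[v]]
    floor_sd <- max(stats::sd(X[, v]), 1e-9) * 1e-6
    tab[, 2L][tab[, 2L] < floor_sd | is.na(tab[, 2L])] <- floor_sd
    nb$tables[[v]] <- tab
  }
  list(nb = nb, bin_means = bin_means, levels = levels(labels))
}

#' Predict from a fitted regressor
#'
#' @param object A `fitted_regressor`.
#' @param newdata Feature matrix with the same number of columns as used
#'   at fit time; zero rows yield a zero-length result.
#' @param ... Ignored.
#' @return Numeric vector of finite predictions, one per row.
#' @export
predict.fitted_regressor <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata)
  if (ncol(X) != object$n_features) {
    stop("shape error: model expects ", object$n_features,
         " feature column(s), got ", ncol(X), call. = FALSE)
  }
  if (nrow(X) == 0L) return(numeric(0))
  colnames(X) <- object$feature_names
  switch(object$spec$family,
    knn = as.numeric(stats::predict(object$fit, X)),
    rf = as.numeric(stats::predict(object$fit, X)),
    ridge = drop(X %*% object$fit$coefficients) + object$fit$intercept,
    svr = as.numeric(stats::predict(object$fit, X)),
    nb = {
      post <- stats::predict(object$fit$nb, as.data.frame(X), type = "raw")
      as.numeric(post %*% object$fit$bin_means[colnames(post)])
    },
    gbdt = as.numeric(stats::predict(object$fit, X))
  )
}

#' @export
print.fitted_regressor <- function(x, ...) {
  cat(sprintf("<fitted_regressor> family=%s, %d feature(s)\n",
              x$spec$family, x$n_features))
  invisible(x)
}
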