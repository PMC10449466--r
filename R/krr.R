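#' Configuration for the blending ensemble
#'
#' The blending ensemble (KRR: KNN + RF + ridge) fits its three base
#' learners on part of the training data and a meta-learner on their
#' predictions over a held-out validation slice of the training data.
#' Defaults follow the method's settings: KNN with k = 5, random forest
#' with 10 trees and seed 42, ridge with alpha = 0.01, a holdout of 15%
#' of the training rows (the top of the method's 10--15% band, for a more
#' stable meta-fit at small n), and a simplex-constrained least-squares
#' meta-learner.
#'
#' @param holdout_fraction Fraction of training rows held out for the
#'   meta-learner, in \[0.05, 0.5\].
#' @param base_specs Named list of three [regressor_spec()]s, in base
#'   order `knn`, `rf`, `ridge`.
#' @param meta `"simplex"` (non-negative weights summing to one, no
#'   intercept) or `"ols"` (unconstrained least squares with intercept).
#' @param seed Integer seed for the holdout split.
#' @return An object of class `blend_config`.
#' @export
blend_config <- function(holdout_fraction = 0.15,
                         base_specs = list(
                           knn   = regressor_spec("knn", k = 5L),
                           rf    = regressor_spec("rf", trees = 10L, seed = 42L),
                           ridge = regressor_spec("ridge", alpha = 0.01)
                         ),
                         meta = c("simplex", "ols"),
                         seed = 42L) {
  meta <- match.arg(meta)
  if (holdout_fraction < 0.05 || holdout_fraction > 0.5) {
    stop("holdout_fraction must be in [0.05, 0.5]", call. = FALSE)
  }
  if (length(base_specs) != 3L ||
      !all(vapply(base_specs, inherits, logical(1), "regressor_spec"))) {
    stop("base_specs must be a list of three regressor_spec objects",
         call. = FALSE)
  }
  structure(list(holdout_fraction = holdout_fraction,
                 base_specs = base_specs, meta = meta,
                 seed = as.integer(seed)),
            class = "blend_config")
}

#' Least squares over the probability simplex
#'
#' Solves \eqn{\min_w \|Pw - y\|^2} subject to \eqn{w \ge 0} and
#' \eqn{\sum_i w_i = 1}. With a small number of columns the exact optimum
#' is found by enumerating the faces of the simplex: for every non-empty
#' subset of columns the equality-constrained least-squares problem is
#' solved via its KKT system, infeasible solutions are discarded, and the
#' feasible candidate with the lowest objective wins. Ties are broken
#' toward the candidate involving the lowest column indices (so with
#' identical columns, the first vertex wins).
#'
#' @param P Numeric matrix of predictions (rows = observations, columns =
#'   models); at least as many rows as columns.
#' @param y Numeric target vector.
#' @return Numeric weight vector of length `ncol(P)`, non-negative and
#'   summing to 1.
#' @export
solve_simplex_ls <- function(P, y) {
  P <- as.matrix(P)
  y <- as.numeric(y)
  k <- ncol(P)
  if (nrow(P) != length(y)) stop("shape error: nrow(P) != length(y)",
                                 call. = FALSE)
  if (nrow(P) < k) stop("need at least ", k, " rows", call. = FALSE)

  subsets <- unlist(lapply(seq_len(k), function(m) {
    utils::combn(k, m, simplify = FALSE)
  }), recursive = FALSE)

  best_w <- NULL
  best_obj <- Inf
  for (s in subsets) {
    m <- length(s)
    Ps <- P[, s, drop = FALSE]
    # KKT system of min ||Ps w - y||^2 s.t. sum(w) = 1
    kkt <- rbind(cbind(2 * crossprod(Ps), rep(1, m)),
                 c(rep(1, m), 0))
    sol <- tryCatch(solve(kkt, c(2 * crossprod(Ps, y), 1)),
                    error = function(e) NULL)
    if (is.null(sol)) next
    w_s <- sol[seq_len(m)]
    if (any(w_s < -1e-9)) next
    w <- numeric(k)
    w[s] <- pmax(w_s, 0)
    w <- w / sum(w)
    obj <- sum((P %*% w - y)^2)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best_w <- w
    }
  }
  if (is.null(best_w)) {
    # every face was numerically singular (e.g. all-zero predictions)
    best_w <- rep(1 / k, k)
  }
  best_w
}

#' Fit the blending ensemble
#'
#' Splits the training rows uniformly at random (seeded) into a base-train
#' set and a blend holdout of `ceiling(holdout_fraction * n)` rows; fits
#' the KNN, RF and ridge base learners on base-train only; predicts the
#' holdout with each; and fits the meta-learner mapping the three base
#' holdout predictions to the holdout targets. With `meta = "simplex"` the
#' meta-learner is least squares constrained to the probability simplex
#' (no intercept), which guarantees the blend's holdout MSE never exceeds
#' the best single base's; with `meta = "ols"` it is unconstrained least
#' squares with an intercept. Base learners are not refitted on the full
#' training data: the holdout stays unseen by them, which is what
#' distinguishes blending from stacking.
#'
#' @param X Feature matrix (>= 20 rows, no missing values).
#' @param y Numeric target vector.
#' @param config A [blend_config()].
#' @return An object of class `krr_model`: base models, meta weights (and
#'   intercept under `"ols"`), plus holdout diagnostics
#'   `holdout_mse_by_base` and `holdout_mse_blend`.
#' @export
fit_krr <- function(X, y, config = blend_config()) {
  stopifnot(inherits(config, "blend_config"))
  X <- as_feature_matrix(X)
  y <- as.numeric(y)
  check_xy(X, y)
  n <- nrow(X)
  if (n < 20L) stop("size error: blending requires >= 20 rows, got ", n,
                    call. = FALSE)
  m <- ceiling(config$holdout_fraction * n)
  if (m < 3L || n - m < 3L) {
    stop("size error: holdout split leaves fewer than 3 rows on one side",
         call. = FALSE)
  }
  holdout_idx <- withr::with_seed(config$seed, sample.int(n, m))
  base_idx <- setdiff(seq_len(n), holdout_idx)

  base_models <- lapply(config$base_specs, function(s) {
    fit_regressor(s, X[base_idx, , drop = FALSE], y[base_idx])
  })
  y_h <- y[holdout_idx]
  P <- vapply(base_models, stats::predict,
              numeric(length(holdout_idx)),
              newdata = X[holdout_idx, , drop = FALSE])

  intercept <- 0
  if (stats::var(y_h) == 0) {
    warning("degenerate holdout: constant targets; using uniform weights",
            call. = FALSE)
    weights <- rep(1 / 3, 3L)
  } else if (config$meta == "simplex") {
    weights <- solve_simplex_ls(P, y_h)
  } else {
    fit <- stats::lm.fit(cbind(1, P), y_h)
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0
    intercept <- coefs[1L]
    weights <- coefs[-1L]
  }
  names(weights) <- names(base_models)
  blend_h <- drop(P %*% weights) + intercept
  structure(list(
    config = config,
    base_models = base_models,
    meta_weights = weights,
    meta_intercept = intercept,
    holdout_mse_by_base = apply(P, 2L, function(p) mean((y_h - p)^2)),
    holdout_mse_blend = mean((y_h - blend_h)^2),
    n_features = ncol(X)
  ), class = "krr_model")
}

#' Predict from a fitted blending ensemble
#'
#' @param object A `krr_model` from [fit_krr()].
#' @param newdata Feature matrix with the training column count.
#' @param ... Ignored.
#' @return Numeric predictions: the meta-weighted combination of the base
#'   learners' predictions (plus the intercept under the `"ols"` meta).
#' @export
predict.krr_model <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata)
  if (ncol(X) != object$n_features) {
    stop("shape error: model expects ", object$n_features,
         " feature column(s), got ", ncol(X), call. = FALSE)
  }
  if (nrow(X) == 0L) return(numeric(0))
  P <- vapply(object$base_models, stats::predict, numeric(nrow(X)),
              newdata = X)
  if (nrow(X) == 1L) P <- matrix(P, nrow = 1L)
  drop(P %*% object$meta_weights) + object$meta_intercept
}

#' @export
print.krr_model <- function(x, ...) {
  cat("<krr_model> blending ensemble (knn + rf + ridge)\n")
  cat("  meta:", x$config$meta,
      "| weights:", paste(sprintf("%s=%.3f", names(x$meta_weights),
                                  x$meta_weights), collapse = " "),
      if (x$config$meta == "ols") sprintf("| intercept=%.3f",
                                          x$meta_intercept) else "", "\n")
  cat(sprintf("  holdout MSE: blend=%.4g, bases=%s\n", x$holdout_mse_blend,
              paste(sprintf("%.4g", x$holdout_mse_by_base),
                    collapse = "/")))
  invisible(x)
}
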