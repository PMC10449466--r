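#' Significance label for a one-sided p-value
#'
#' Star convention used in the comparison tables: `"*"` for 1%
#' significance (p < 0.01), `"**"` for 5% (0.01 <= p < 0.05), `"***"` for
#' 10% (0.05 <= p < 0.10), and `""` otherwise.
#'
#' @param p One-sided p-value in \[0, 1\].
#' @return One of `"*"`, `"**"`, `"***"`, `""`.
#' @export
significance_label <- function(p) {
  stopifnot(is.numeric(p), p >= 0, p <= 1)
  if (p < 0.01) "*"
  else if (p < 0.05) "**"
  else if (p < 0.10) "***"
  else ""
}

#' Diebold--Mariano test of equal forecast accuracy
#'
#' Compares two aligned forecast-error series via the loss differential
#' \eqn{d_t = L(e_{A,t}) - L(e_{B,t})}. The statistic is
#' \eqn{DM = \bar d / \sqrt{\hat\sigma^2 / T}} where \eqn{\hat\sigma^2 =
#' \gamma_0 + 2\sum_{k=1}^{h-1}\gamma_k} is the truncated long-run
#' variance built from 1/T-normalized autocovariances of \eqn{d} (floored
#' at \eqn{\gamma_0 \times 10^{-12}}). The one-sided p-value
#' \eqn{1 - \Phi(DM)} tests the alternative that model B is the more
#' accurate forecaster, so rejection favours B. With
#' `small_sample = TRUE` the Harvey--Leybourne--Newbold correction is
#' applied: the statistic is scaled by
#' \eqn{\sqrt{(T + 1 - 2h + h(h-1)/T)/T}} and referred to a Student-t
#' distribution with T - 1 degrees of freedom.
#'
#' @param e_a,e_b Forecast-error series of equal length T >= 4.
#' @param loss `"squared"` or `"absolute"`.
#' @param h Forecast horizon (>= 1); at `h = 1` the long-run variance
#'   reduces to \eqn{\gamma_0}.
#' @param small_sample Apply the Harvey--Leybourne--Newbold correction.
#' @return An object of class `dm_result`: `statistic`, `p_one_sided`,
#'   `p_two_sided`, `n`, `loss`, `horizon`, and the significance `label`.
#' @export
#' @examples
#' dm_test(c(2, 0, 2, 0), c(0, 0, 0, 0))  # DM = 2, p ~ 0.0228
dm_test <- function(e_a, e_b, loss = c("squared", "absolute"), h = 1L,
                    small_sample = FALSE) {
  loss <- match.arg(loss)
  e_a <- as.numeric(e_a)
  e_b <- as.numeric(e_b)
  n <- length(e_a)
  if (n != length(e_b)) stop("shape error: series lengths differ",
                             call. = FALSE)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  if (!all(is.finite(e_a)) || !all(is.finite(e_b))) {
    stop("non-finite values in error series", call. = FALSE)
  }
  h <- as.integer(h)
  if (h < 1L || h > n - 1L) stop("horizon h must be in [1, T - 1]",
                                 call. = FALSE)
  L <- if (loss == "squared") function(e) e^2 else abs
  d <- L(e_a) - L(e_b)
  dbar <- mean(d)
  dc <- d - dbar
  gamma <- function(k) sum(dc[seq_len(n - k)] * dc[seq_len(n - k) + k]) / n
  g0 <- gamma(0L)
  if (g0 < 1e-12 * max(1, dbar^2)) {
    stop("degenerate-series error: the loss differential has (near-)zero ",
         "variance, so the DM statistic is undefined", call. = FALSE)
  }
  sigma2 <- g0
  if (h > 1L) {
    sigma2 <- sigma2 + 2 * sum(vapply(seq_len(h - 1L), gamma, numeric(1)))
  }
  sigma2 <- max(sigma2, g0 * 1e-12)
  stat <- dbar / sqrt(sigma2 / n)
  if (small_sample) {
    stat <- stat * sqrt((n + 1 - 2 * h + h * (h - 1) / n) / n)
    p_one <- 1 - stats::pt(stat, df = n - 1)
  } else {
    p_one <- 1 - stats::pnorm(stat)
  }
  structure(list(
    statistic = stat,
    p_one_sided = p_one,
    p_two_sided = 2 * min(p_one, 1 - p_one),
    n = n,
    loss = loss,
    horizon = h,
    small_sample = small_sample,
    label = significance_label(p_one)
  ), class = "dm_result")
}

#' @export
print.dm_result <- function(x, ...) {
  cat(sprintf("<dm_result> DM = %.4f%s (T = %d, loss = %s, h = %d)\n",
              x$statistic, x$label, x$n, x$loss, x$horizon))
  cat(sprintf("  one-sided p = %.4g (H1: model B more accurate), ",
              x$p_one_sided))
  cat(sprintf("two-sided p = %.4g\n", x$p_two_sided))
  invisible(x)
}

#' Compare every model's forecast errors against a reference model
#'
#' Runs [dm_test()] with A = each non-reference model and B = the
#' reference, so a significant positive statistic means the reference
#' forecasts more accurately than that model.
#'
#' @param errors data.frame or named list of aligned error series, one per
#'   model.
#' @param reference Name of the reference model column (default `"krr"`).
#' @param loss,h,small_sample Passed to [dm_test()].
#' @return data.frame with one row per non-reference model: `model`,
#'   `dm`, `p_one_sided`, `p_two_sided`, `label`.
#' @export
dm_compare <- function(errors, reference = "krr",
                       loss = c("squared", "absolute"), h = 1L,
                       small_sample = FALSE) {
  errors <- as.data.frame(errors)
  if (!reference %in% names(errors)) {
    stop("key error: reference model '", reference,
         "' not found in errors", call. = FALSE)
  }
  others <- setdiff(names(errors), reference)
  rows <- lapply(others, function(nm) {
    res <- dm_test(errors[[nm]], errors[[reference]], loss = loss, h = h,
                   small_sample = small_sample)
    data.frame(model = nm, dm = res$statistic,
               p_one_sided = res$p_one_sided,
               p_two_sided = res$p_two_sided,
               label = res$label, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
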