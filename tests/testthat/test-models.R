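test_that("default specs carry the documented hyperparameters", {
  specs <- default_regressor_specs()
  expect_setequal(names(specs), c("svr", "nb", "rf", "ridge", "gbdt", "knn"))
  expect_equal(specs$ridge$hyperparameters$alpha, 0.01)
  expect_equal(specs$rf$hyperparameters$trees, 20L)
  expect_equal(specs$rf$seed, 42L)
  expect_equal(specs$svr$hyperparameters$C, 100)
  expect_equal(specs$gbdt$hyperparameters$learning_rate, 0.05)
  expect_equal(specs$nb$hyperparameters$bins, 20L)
  expect_equal(specs$knn$hyperparameters$k, 5L)
})

test_that("spec validation rejects out-of-range hyperparameters", {
  expect_error(regressor_spec("knn", k = 0), "invalid")
  expect_error(regressor_spec("ridge", alpha = 0), "invalid")
  expect_error(regressor_spec("gbdt", learning_rate = 1.5), "invalid")
  expect_error(regressor_spec("rf", bogus = 3), "unknown hyperparameter")
})

test_that("ridge recovers exact linear structure at tiny alpha", {
  X <- matrix(1:10, ncol = 1)
  y <- 2 * (1:10)
  fit <- fit_regressor(regressor_spec("ridge", alpha = 1e-8), X, y)
  expect_equal(unname(fit$fit$coefficients), 2, tolerance = 1e-5)
  expect_equal(unname(predict(fit, matrix(20))), 40, tolerance = 1e-4)

  # constant target: intercept-only limit
  fitc <- fit_regressor(regressor_spec("ridge", alpha = 0.01),
                        matrix(rnorm(20), ncol = 2), rep(7, 10))
  expect_equal(unname(predict(fitc, matrix(rnorm(6), ncol = 2))),
               rep(7, 3), tolerance = 1e-8)
})

test_that("ridge converges to least squares as alpha shrinks, and shrinks as it grows", {
  dat <- make_linear_xy(n = 80, p = 3)
  ls_coef <- unname(stats::lm.fit(cbind(1, dat$X), dat$y)$coefficients[-1])
  tiny <- fit_regressor(regressor_spec("ridge", alpha = 1e-10),
                        dat$X, dat$y)
  expect_lt(sqrt(sum((unname(tiny$fit$coefficients) - ls_coef)^2)), 1e-5)

  alphas <- c(0.01, 0.1, 1, 10, 100)
  norms <- vapply(alphas, function(a) {
    f <- fit_regressor(regressor_spec("ridge", alpha = a), dat$X, dat$y)
    sqrt(sum(f$fit$coefficients^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("knn memorizes at k = 1, averages neighbours, and flattens at k = n", {
  X <- matrix(c(0, 1, 2, 3), ncol = 1)
  y <- c(10, 20, 30, 40)
  k1 <- fit_regressor(regressor_spec("knn", k = 1), X, y)
  expect_equal(predict(k1, X), y)

  # query equidistant from targets 0 and 10
  k2 <- fit_regressor(regressor_spec("knn", k = 2),
                      matrix(c(-1, 1), ncol = 1), c(0, 10))
  expect_equal(unname(predict(k2, matrix(0))), 5)

  kn <- fit_regressor(regressor_spec("knn", k = 4), X, y)
  expect_equal(unname(predict(kn, matrix(c(-5, 1.2, 99)))),
               rep(mean(y), 3))
})

test_that("stochastic families are reproducible under a fixed seed", {
  dat <- make_linear_xy(n = 60)
  for (fam in c("rf", "gbdt")) {
    f1 <- fit_regressor(regressor_spec(fam, seed = 42L), dat$X, dat$y)
    f2 <- fit_regressor(regressor_spec(fam, seed = 42L), dat$X, dat$y)
    expect_identical(predict(f1, dat$X), predict(f2, dat$X), info = fam)
  }
})

test_that("fit and predict enforce the shape contract", {
  dat <- make_linear_xy(n = 30)
  expect_error(fit_regressor(regressor_spec("ridge"), dat$X, dat$y[-1]),
               "shape error")
  Xna <- dat$X
  Xna[1, 1] <- NA
  expect_error(fit_regressor(regressor_spec("ridge"), Xna, dat$y),
               "missing values")
  fit <- fit_regressor(regressor_spec("ridge"), dat$X, dat$y)
  expect_error(predict(fit, dat$X[, 1:2]), "shape error")
  expect_identical(predict(fit, dat$X[0, , drop = FALSE]), numeric(0))
})

test_that("naive-Bayes regression collapses to the right bin on separated clusters", {
  withr::local_seed(5)
  x <- c(rnorm(50, -3, 0.5), rnorm(50, 3, 0.5))
  y <- c(rnorm(50, 0, 0.1), rnorm(50, 10, 0.1))
  fit <- nb_regress_fit(matrix(x, ncol = 1), y, n_bins = 2L)
  expect_lt(abs(predict(fit, matrix(-5)) - 0), 0.5)
  expect_lt(abs(predict(fit, matrix(5)) - 10), 0.5)
})

test_that("naive-Bayes regression reverts to the prior mean under pure noise", {
  withr::local_seed(8)
  n <- 400
  x <- rnorm(n)
  y <- runif(n)
  fit <- nb_regress_fit(matrix(x, ncol = 1), y, n_bins = 4L)
  pred <- predict(fit, matrix(rnorm(50), ncol = 1))
  se <- sd(y) / sqrt(n)
  expect_true(all(abs(pred - mean(y)) < max(2 * se, 0.1)))
  # a constant target cannot be binned
  expect_error(nb_regress_fit(matrix(x, ncol = 1), rep(1, n), n_bins = 2L),
               "binning error")
})

test_that("fitted models round-trip through serialization bit-exactly", {
  dat <- make_linear_xy(n = 50)
  path <- withr::local_tempfile(fileext = ".rds")
  for (fam in c("ridge", "rf", "knn", "gbdt")) {
    fit <- fit_regressor(regressor_spec(fam, seed = 42L), dat$X, dat$y)
    before <- predict(fit, dat$X)
    saveRDS(fit, path)
    expect_identical(predict(readRDS(path), dat$X), before, info = fam)
  }
})
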