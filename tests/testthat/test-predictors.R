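fake_windows <- function(mat, scr = 1, ratio = 1.2, age = "60-69",
                         sex = "male", label = 0L) {
  colnames(mat) <- paste0("uo_h", 1:12)
  tibble::as_tibble(cbind(
    tibble::tibble(patient_id = sprintf("P%04d", seq_len(nrow(mat))),
                   window_end_hour = 12L),
    tibble::as_tibble(mat),
    tibble::tibble(age_group = age, sex = sex, scr = scr,
                   scr_ratio = ratio, label = label)))
}

test_that("window features match hand computations", {
  w <- fake_windows(matrix(1.0, 1, 12))
  f <- extract_features(w)
  expect_equal(f$uo_min, 1); expect_equal(f$uo_max, 1)
  expect_equal(f$uo_mean, 1); expect_equal(f$uo_slope, 0)
  expect_equal(f$hours_below_05, 0)
  expect_equal(f$sex_male, 1); expect_equal(f$age_ordinal, 4)

  # exact line 1.25 -> 0.15 in steps of -0.1: least-squares slope is the step
  lin <- matrix(1.25 - 0.1 * (0:11), 1, 12)
  fl <- extract_features(fake_windows(lin))
  expect_equal(fl$uo_slope, -0.1, tolerance = 1e-12)
  expect_equal(fl$uo_last, 0.15)
  expect_equal(fl$hours_below_05, 4)      # 0.45, 0.35, 0.25, 0.15

  fz <- extract_features(fake_windows(matrix(0, 1, 12)))
  expect_equal(fz$hours_below_03, 12)
  expect_error(extract_features(fake_windows(matrix(c(NA, rep(1, 11)), 1, 12))),
               "fully observed")
})

test_that("logistic fit recovers simulated coefficients and the null", {
  set.seed(101)
  n <- 20000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 2 * x))
  fit <- fit_logistic_model(tibble::tibble(x = x), y)
  beta_raw <- fit$coefficients[["x"]] / fit$norm$scale[["x"]]
  expect_lt(abs(beta_raw - 2) / 2, 0.05)

  # labels independent of the feature: slope ~ 0, intercept ~ logit(prevalence)
  y0 <- rbinom(n, 1, 0.1)
  fit0 <- fit_logistic_model(tibble::tibble(x = x), y0)
  expect_lt(abs(fit0$coefficients[["x"]]), 0.05)
  expect_equal(unname(fit0$coefficients[1]), qlogis(mean(y0)),
               tolerance = 0.05)

  # duplicating every row leaves the ML fit unchanged (up to the sample-sd
  # standardisation constant, which differs at order 1/n)
  xx <- tibble::tibble(x = c(x[1:2000], x[1:2000]))
  yy <- c(y[1:2000], y[1:2000])
  f1 <- fit_logistic_model(tibble::tibble(x = x[1:2000]), y[1:2000])
  f2 <- fit_logistic_model(xx, yy)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-3)
  expect_equal(f1$coefficients[["x"]] / f1$norm$scale[["x"]],
               f2$coefficients[["x"]] / f2$norm$scale[["x"]],
               tolerance = 1e-6)

  expect_error(fit_logistic_model(tibble::tibble(x = x), rep(1, n)),
               "both classes")
})

test_that("logistic predictions are sigmoids of the standardised score", {
  set.seed(5)
  x <- rnorm(500); y <- rbinom(500, 1, plogis(x))
  fit <- fit_logistic_model(tibble::tibble(x = x), y)
  # at the training feature mean the score is the intercept
  expect_equal(predict(fit, tibble::tibble(x = mean(x))),
               plogis(unname(fit$coefficients[1])))
  p <- predict(fit, tibble::tibble(x = x))
  expect_true(all(p > 0 & p < 1))
  expect_error(predict(fit, tibble::tibble(z = 1)))
})

test_that("perfect separation triggers the penalised refit with a warning", {
  x <- c(rep(0, 20), rep(1, 20))
  y <- c(rep(0, 20), rep(1, 20))
  expect_warning(fit <- fit_logistic_model(tibble::tibble(x = x), y),
                 "separation")
  expect_true(all(is.finite(fit$coefficients)))
  p <- predict(fit, tibble::tibble(x = c(0, 1)))
  expect_lt(p[1], 0.05); expect_gt(p[2], 0.95)
})

test_that("conv net training is seeded, bounded and batch-invariant", {
  set.seed(9)
  n <- 400
  neg <- matrix(rnorm(n * 12, 1.2, 0.25), n, 12)
  pos <- cbind(matrix(rnorm(n * 6, 1.0, 0.25), n, 6),
               matrix(abs(rnorm(n * 6, 0.15, 0.05)), n, 6))
  X <- rbind(neg, pos)
  y <- rep(c(0, 1), each = n)
  pid <- rep(sprintf("P%03d", 1:80), length.out = 2 * n)
  spec <- convnet_spec(epochs = 80, patience = 20, seed = 7)
  m1 <- fit_convnet(X, y, pid, spec)
  m2 <- fit_convnet(X, y, pid, spec)
  expect_identical(predict(m1, X), predict(m2, X))
  p <- predict(m1, X)
  expect_true(all(p > 0 & p < 1))
  # batch prediction equals per-window prediction
  expect_equal(p[3], unname(predict(m1, X[3, ])))
  expect_error(predict(m1, X[, 1:10]), "window length")
  # separable signal is learned
  expect_gt(mean(p[y == 1]), mean(p[y == 0]))
  expect_gt(roc_curve(p, y)$auc, 0.9)
})

test_that("conv net refuses starved fits and collapses on shuffled labels", {
  set.seed(13)
  X <- matrix(rnorm(600, 1, 0.3), 50, 12)
  expect_error(fit_convnet(X, rep(c(0, 1), c(45, 5)), sprintf("P%02d", 1:50)),
               "positive windows")
  n <- 300
  neg <- matrix(rnorm(n * 12, 1.2, 0.25), n, 12)
  pos <- cbind(matrix(rnorm(n * 6, 1.0, 0.25), n, 6),
               matrix(abs(rnorm(n * 6, 0.15, 0.05)), n, 6))
  X2 <- rbind(neg, pos)
  y_shuf <- sample(rep(c(0, 1), each = n))
  pid <- rep(sprintf("P%03d", 1:60), length.out = 2 * n)
  m <- fit_convnet(X2, y_shuf, pid,
                   convnet_spec(epochs = 60, patience = 15, seed = 3,
                                min_positive = 50))
  auc <- roc_curve(predict(m, X2), y_shuf)$auc
  expect_gt(auc, 0.35); expect_lt(auc, 0.65)
})

test_that("models round-trip through the portable JSON format", {
  set.seed(21)
  x <- rnorm(300); y <- rbinom(300, 1, plogis(x))
  fit <- fit_logistic_model(tibble::tibble(x = x), y)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(fit, f)
  back <- read_model(f)
  expect_equal(predict(back, tibble::tibble(x = x)),
               predict(fit, tibble::tibble(x = x)))

  X <- matrix(rnorm(1200, 1, 0.3), 100, 12)
  yy <- rep(c(0, 1), each = 50)
  m <- fit_convnet(X, yy, sprintf("P%03d", rep(1:20, each = 5)),
                   convnet_spec(epochs = 10, patience = 5, min_positive = 10,
                                seed = 2))
  f2 <- withr::local_tempfile(fileext = ".json")
  write_model(m, f2)
  back2 <- read_model(f2)
  expect_equal(predict(back2, X), predict(m, X))
})
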