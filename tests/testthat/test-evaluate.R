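test_that("ROC curves sweep all thresholds with both endpoints", {
  r <- roc_curve(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)                 # exhaustive 4-pair count
  expect_equal(r$auc, oracle_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)))
  expect_true(any(r$points$sensitivity == 1 & r$points$specificity == 0))
  expect_true(any(r$points$sensitivity == 0 & r$points$specificity == 1))
  # monotone in the threshold
  expect_true(all(diff(r$points$sensitivity) <= 0))
  expect_true(all(diff(r$points$specificity) >= 0))

  expect_equal(roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_curve(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_curve(1:4, rep(1, 4)), "both classes")
  expect_error(roc_curve(c(1, NA), c(0, 1)), "finite")
})

test_that("trapezoidal AUC equals pair counting on random instances", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(20:150, 1)
    s <- round(runif(n), sample(1:2, 1))    # coarse rounding forces ties
    y <- rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    expect_equal(roc_curve(s, y)$auc, oracle_auc(s, y), tolerance = 1e-12)
  }
})

test_that("Hanley-McNeil standard error matches the closed form", {
  # A = 0.5: Q1 = Q2 = 1/3, se^2 = (1/4 + (n-1)/6) / n^2 x ... by hand
  n <- 50
  expect_equal(auc_standard_error(0.5, n, n),
               sqrt((0.25 + 2 * (n - 1) * (1 / 3 - 0.25)) / n^2))
  expect_equal(auc_standard_error(1, 10, 20), 0)
  # shrinks with sample size at fixed A
  ses <- sapply(c(10, 50, 200, 1000), function(n)
    auc_standard_error(0.9, n, 5 * n))
  expect_true(all(diff(ses) < 0))
  expect_error(auc_standard_error(1.2, 5, 5), "0, 1")
})

test_that("likelihood ratios reproduce the published working points", {
  lr <- likelihood_ratios(0.80, 0.89)
  expect_equal(round_half_up(lr$lr_pos), 7.27)    # deep model, European cohort
  expect_equal(round_half_up(lr$lr_neg), 0.22)
  lr2 <- likelihood_ratios(0.80, 0.81)
  expect_equal(round_half_up(lr2$lr_pos), 4.21)   # logistic, European cohort
  expect_equal(round_half_up(lr2$lr_neg), 0.25)
  expect_equal(likelihood_ratios(1, 0.5)$lr_neg, 0)
  expect_equal(likelihood_ratios(0.8, 1)$lr_pos, Inf)
  expect_equal(likelihood_ratios(0.8, 0)$lr_neg, Inf)
  expect_error(likelihood_ratios(1.2, 0.5), "0, 1")
})

test_that("operating points equal brute-force scans of the curve", {
  set.seed(17)
  s <- runif(400); y <- rbinom(400, 1, plogis(4 * (s - 0.5)))
  r <- roc_curve(s, y)
  op <- operating_point_fixed_sensitivity(r, 0.80)
  # brute force over every threshold row
  ok <- r$points$sensitivity >= 0.80
  expect_equal(op$specificity, max(r$points$specificity[ok]))
  expect_gte(op$sensitivity, 0.80)
  kp <- knee_point(r)
  d <- sqrt((1 - r$points$sensitivity)^2 + (1 - r$points$specificity)^2)
  expect_equal(sqrt((1 - kp$sensitivity)^2 + (1 - kp$specificity)^2), min(d))
  # LR+ > 1 iff the point is above the chance diagonal
  expect_gt(kp$lr_pos, 1)
  # perfect classifier: spec 1 at 80% sensitivity, knee at the ideal corner
  rp <- roc_curve(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(operating_point_fixed_sensitivity(rp)$specificity, 1)
  kpp <- knee_point(rp)
  expect_equal(c(kpp$sensitivity, kpp$specificity), c(1, 1))
  expect_error(operating_point_fixed_sensitivity(r, 1.5), "attains")
})

test_that("youden knee selection maximises sensitivity + specificity", {
  set.seed(3)
  s <- runif(200); y <- rbinom(200, 1, plogis(3 * (s - 0.4)))
  r <- roc_curve(s, y)
  ky <- knee_point(r, method = "youden")
  j <- r$points$sensitivity + r$points$specificity - 1
  expect_equal(ky$sensitivity + ky$specificity - 1, max(j))
})

test_that("patient-level aggregation uses alert semantics", {
  ps <- patient_level_scores(c(0.1, 0.7, 0.3), rep("A", 3))
  expect_equal(ps$score, 0.7)
  expect_equal(patient_level_scores(0.4, "B")$score, 0.4)
  pm <- patient_level_scores(c(0.1, 0.7), rep("A", 2), agg = "mean")
  expect_equal(pm$score, 0.4)
  # aggregated AUC equals the pair-counting oracle on aggregated scores
  set.seed(11)
  pid <- rep(sprintf("P%02d", 1:30), each = 4)
  ev <- setNames(rbinom(30, 1, 0.3), sprintf("P%02d", 1:30))
  sc <- runif(120) + 0.4 * ev[pid]
  agg <- patient_level_scores(sc, pid)
  lab <- as.numeric(ev[agg$patient_id])
  expect_equal(roc_curve(agg$score, lab)$auc, oracle_auc(agg$score, lab))
})

test_that("ROC and AUC agree with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(99)
  s <- round(runif(300), 2)
  y <- rbinom(300, 1, plogis(5 * (s - 0.5)))
  r <- roc_curve(s, y)
  ref <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})
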