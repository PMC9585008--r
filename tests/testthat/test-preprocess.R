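test_that("Devine IBW handles base cases, midpoints and the 40 kg floor", {
  expect_equal(compute_ibw("male", c(152.4, 152.4)), 50)
  expect_equal(compute_ibw("female", c(152.4, 152.4)), 45.5)
  expect_equal(compute_ibw("male", c(170, 180)), 50 + 0.9059 * 22.6,
               tolerance = 1e-10)                  # midpoint 175 -> 70.47 kg
  expect_equal(compute_ibw("female", 140), 40)     # floored
  expect_equal(compute_ibw("male", 175), compute_ibw("male", c(170, 180)))
  expect_error(compute_ibw("m", 170), "sex")
  expect_error(compute_ibw("male", 119), "120")
  expect_equal(unname(parse_height_range("170-179")[1, ]), c(170, 179))
  expect_error(parse_height_range("tall"), "unparseable")
})

test_that("urine resampling splits short gaps and conserves volume", {
  # 300 ml at hour 3, nothing before: 3 bins at 100 ml/h
  expect_equal(resample_urine_hourly(3, 300, 6), c(100, 100, 100, NA, NA, NA))
  # already-hourly stream is the identity
  expect_equal(resample_urine_hourly(1:5, rep(80, 5), 5), rep(80, 5))
  # randomised conservation: all gaps < 9 h, total volume conserved
  set.seed(42)
  for (i in 1:20) {
    gaps <- runif(15, 0.3, 6)
    t <- cumsum(gaps)
    v <- round(runif(15, 0, 400), 1)
    stay <- ceiling(max(t))
    keep <- ceiling(t) <= stay
    out <- resample_urine_hourly(t, v, stay)
    expect_equal(sum(out, na.rm = TRUE), sum(v[keep]), tolerance = 1e-9)
  }
})

test_that("gaps of 9 h or more stay missing except the record's own bin", {
  # 500 ml after a 10-h silent gap: 9 missing bins, own bin gets it all
  out <- resample_urine_hourly(10, 500, 12)
  expect_equal(out, c(rep(NA, 9), 500, NA, NA))
  # strict boundary: a 9-bin gap is NOT split ...
  out9 <- resample_urine_hourly(9, 450, 10)
  expect_equal(out9, c(rep(NA, 8), 450, NA))
  # ... an 8-bin gap is
  out8 <- resample_urine_hourly(8, 400, 10)
  expect_equal(out8, c(rep(50, 8), NA, NA))
  expect_error(resample_urine_hourly(-1, 10, 5), "outside")
  expect_error(resample_urine_hourly(7, 10, 5), "outside")
})

test_that("creatinine carry-forward respects the 95-hour cap", {
  # single value, long stay: filled through hour bin 96, missing beyond
  out <- fill_creatinine(0.5, 1.2, 200)
  expect_equal(out[1:96], rep(1.2, 96))
  expect_true(all(is.na(out[97:200])))
  # a later value takes over at its own bin
  out2 <- fill_creatinine(c(0.5, 50), c(1.0, 2.0), 60)
  expect_equal(out2[1:49], rep(1.0, 49))
  expect_equal(out2[50:60], rep(2.0, 11))
  # last value wins within one bin
  out3 <- fill_creatinine(c(10.2, 10.8), c(1.0, 1.6), 12)
  expect_equal(out3[11], 1.6)
  # bins before the first measurement stay missing
  expect_true(all(is.na(fill_creatinine(5.5, 1.1, 10)[1:5])))
  # empty records: all missing
  expect_true(all(is.na(fill_creatinine(numeric(), numeric(), 24))))
  expect_error(fill_creatinine(1, -0.5, 24), "positive")
})

test_that("carry-forward never inverts order", {
  set.seed(7)
  for (i in 1:10) {
    t <- sort(runif(8, 0, 120))
    v <- round(runif(8, 0.5, 3), 2)
    out <- fill_creatinine(t, v, 120)
    bins <- pmax(ceiling(t - 1e-9), 1)
    for (h in which(!is.na(out))) {
      j <- max(which(bins <= h))
      expect_lte(h - bins[j], 95)
      expect_equal(out[h], v[j])
    }
  }
})

test_that("trajectories normalise by IBW and propagate missingness", {
  tr <- build_trajectory("A", c(70, NA, 140), c(1, 1, NA), 70)
  expect_equal(tr$uo_norm, c(1, NA, 2))
  expect_true(is.na(tr$scr_mg_dl[3]))
  expect_error(build_trajectory("A", 1:3, 1:2, 70), "length")
  # scaling identity on a random trajectory
  set.seed(1)
  uo <- runif(30, 0, 300); uo[sample(30, 5)] <- NA
  tr2 <- build_trajectory("B", uo, rep(1, 30), 62.5)
  expect_equal(max(tr2$uo_norm, na.rm = TRUE) * tr2$ibw_kg,
               max(tr2$uo_ml_per_h, na.rm = TRUE))
})

test_that("cohort-level preprocessing reproduces per-patient rules", {
  co <- generate_cohort(generator_config(n_patients = 25, prevalence = 0.2,
                                         seed = 31))
  trs <- build_trajectories(co)
  expect_named(trs, co$demographics$patient_id)
  pid <- co$demographics$patient_id[1]
  demo <- co$demographics[1, ]
  stay <- as.numeric(difftime(demo$discharge_time, demo$admit_time,
                              units = "hours"))
  expect_equal(trs[[pid]]$n_hours, floor(stay))
  uo <- co$uo_records[co$uo_records$patient_id == pid, ]
  t_h <- as.numeric(difftime(uo$timestamp, demo$admit_time, units = "hours"))
  expect_equal(trs[[pid]]$uo_ml_per_h,
               resample_urine_hourly(t_h, uo$volume_ml, stay))
})
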