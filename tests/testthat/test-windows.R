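test_that("exclusion log partitions a constructed cohort by reason", {
  trs <- list()
  for (i in 1:7) trs[[sprintf("OK%02d", i)]] <- constant_trajectory(
    sprintf("OK%02d", i), hours = 72)
  trs[["SHORT"]] <- constant_trajectory("SHORT", hours = 20)
  uo_gappy <- rep(70, 60); uo_gappy[1:30] <- NA
  trs[["GAPPY"]] <- build_trajectory("GAPPY", uo_gappy, rep(1, 60), 70)
  trs[["NOSCR"]] <- constant_trajectory("NOSCR", hours = 72)
  lab <- small_labels(trs,
                      labelable = c(rep(TRUE, 9), FALSE))
  res <- apply_exclusions(trs, lab)
  expect_equal(sort(res$included), sort(sprintf("OK%02d", 1:7)))
  expect_equal(nrow(res$log), 10)
  expect_equal(sum(res$log$decision == "included") +
                 sum(res$log$decision == "excluded"), 10)
  expect_equal(res$log$reason[res$log$patient_id == "SHORT"], "stay_too_short")
  expect_equal(res$log$reason[res$log$patient_id == "GAPPY"], "missing_uo")
  expect_equal(res$log$reason[res$log$patient_id == "NOSCR"], "missing_scr")
})

test_that("early-onset and admission-AKI cases are excluded", {
  trs <- list(EARLY = constant_trajectory("EARLY", hours = 72),
              ADMIT = constant_trajectory("ADMIT", hours = 72))
  lab <- small_labels(trs, has_event = c(TRUE, TRUE),
                      onset = c(15L, 10L))
  res <- apply_exclusions(trs, lab)
  # onset 15: 15 - 6 = 9 usable hours < 12 -> unlabelable
  expect_equal(res$log$reason[res$log$patient_id == "EARLY"],
               "event_unlabelable")
  # onset 10 <= 12 h: community-acquired proxy
  expect_equal(res$log$reason[res$log$patient_id == "ADMIT"],
               "aki_at_admission")
})

test_that("case trajectories are truncated 6 h before onset", {
  tr <- constant_trajectory(hours = 60)
  ep <- structure(list(patient_id = "T01", onset_hour = 40L, max_stage = 2L,
                       uo_criterion_met = TRUE, scr_criterion_met = TRUE),
                  class = "aki_episode")
  cut <- truncate_before_onset(tr, ep)
  expect_equal(cut$n_hours, 34)
  # controls pass through whole
  expect_equal(truncate_before_onset(tr, NULL)$n_hours, 60)
  ep$onset_hour <- 5L
  expect_error(truncate_before_onset(tr, ep), "onset too early")
})

test_that("window counts, labels and lead times follow the geometry", {
  # 24-h fully observed control: 24 - 12 + 1 = 13 windows, all negative
  w <- make_windows(constant_trajectory(hours = 24), NULL, baseline = 1,
                    age_group = "60-69", sex = "male")
  expect_equal(nrow(w), 13)
  expect_equal(w$window_end_hour, 12:24)
  expect_true(all(w$label == 0))

  # case with onset 40, truncated to 34 h: positives end within 24 h of onset
  ep <- structure(list(patient_id = "T01", onset_hour = 40L, max_stage = 2L,
                       uo_criterion_met = TRUE, scr_criterion_met = TRUE),
                  class = "aki_episode")
  tr <- truncate_before_onset(constant_trajectory(hours = 60), ep)
  wc <- make_windows(tr, ep, baseline = 1, age_group = "60-69", sex = "male")
  expect_equal(max(wc$window_end_hour), 34)
  expect_equal(wc$window_end_hour[wc$label == 1], 16:34)
  # lead-time guarantee: no positive window ends after onset - 6
  expect_true(all(wc$window_end_hour[wc$label == 1] <= 40 - 6))

  # a missing urine bin blocks every window that spans it
  uo <- rep(70, 24); uo[6] <- NA
  wm <- make_windows(build_trajectory("T02", uo, rep(1, 24), 70), NULL,
                     baseline = 1, age_group = "60-69", sex = "female")
  expect_equal(wm$window_end_hour, 18:24)

  # missing creatinine at the window end drops that window
  scr <- rep(1, 24); scr[15] <- NA
  ws <- make_windows(build_trajectory("T03", rep(70, 24), scr, 70), NULL,
                     baseline = 1, age_group = "60-69", sex = "female")
  expect_false(15 %in% ws$window_end_hour)

  # too-short trajectory: zero windows, well-formed empty tibble
  w0 <- make_windows(constant_trajectory(hours = 8), NULL, baseline = 1)
  expect_equal(nrow(w0), 0)
  expect_true(all(c("uo_h1", "uo_h12", "label") %in% names(w0)))
})

test_that("window uo columns carry the oldest-to-newest hourly values", {
  uo <- seq(10, 240, by = 10)                      # distinct hourly values
  tr <- build_trajectory("T04", uo, rep(1, 24), 1)
  w <- make_windows(tr, NULL, baseline = 1, age_group = "18-39", sex = "male")
  expect_equal(unlist(w[1, paste0("uo_h", 1:12)], use.names = FALSE),
               uo[1:12])
  expect_equal(w$uo_h12, uo[12:24])                # newest value = window end
  expect_equal(w$scr_ratio, rep(1, 13))
})

test_that("patient-level splits are disjoint, stratified and seeded", {
  ids <- sprintf("P%03d", 1:200)
  ev <- rep(c(TRUE, FALSE), c(20, 180))
  s1 <- split_patients(ids, ev, test_frac = 0.3, seed = 5)
  s2 <- split_patients(ids, ev, test_frac = 0.3, seed = 5)
  expect_identical(s1, s2)
  expect_length(intersect(s1$train, s1$test), 0)
  expect_setequal(c(s1$train, s1$test), ids)
  expect_equal(sum(ev[match(s1$test, ids)]), 6)    # 30% of 20 event patients
})

test_that("cohort window sets respect truncation and labels end-to-end", {
  co <- generate_cohort(generator_config(n_patients = 120, prevalence = 0.15,
                                         seed = 8))
  cfg <- pipeline_config(n_patients_a = 1, n_patients_b = 1, seed = 1)
  prep <- prepare_cohort(co, cfg)
  w <- prep$windows
  expect_true(all(!is.na(w$scr_ratio)))
  lab <- prep$labelled$labels
  on <- setNames(lab$onset_hour, lab$patient_id)
  pos <- w[w$label == 1, ]
  expect_gt(nrow(pos), 0)
  expect_true(all(pos$window_end_hour <= on[pos$patient_id] - 6))
  expect_true(all(pos$window_end_hour >= on[pos$patient_id] - 24))
  # exclusion log partition at cohort scale
  expect_equal(nrow(prep$exclusions$log), 120)
  expect_equal(length(prep$exclusions$included) +
                 sum(prep$exclusions$log$decision == "excluded"), 120)
})
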