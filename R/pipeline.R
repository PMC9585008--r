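#' End-to-end pipeline configuration
#'
#' Bundles every tunable of the study design: generator configurations for
#' a training-like cohort A (sparser "eICU-like" charting, 3% prevalence)
#' and an external-validation-like cohort B (denser "Amsterdam-like"
#' charting, 4.2% prevalence), the preprocessing caps (9 h urine split
#' rule, 95 h creatinine carry-forward), the KDIGO composite settings, the
#' window geometry (12 h windows, 24 h horizon, 6 h truncation lead), model
#' settings and a single global seed fanned out to per-stage seeds by
#' [derive_seeds()].
#'
#' @param n_patients_a,n_patients_b cohort sizes.
#' @param seed global integer seed.
#' @param cohort_a,cohort_b optional [generator_config()] overrides (their
#'   seeds are replaced by derived per-stage seeds).
#' @param split_max_h,max_carry_h preprocessing caps (h).
#' @param co_window_h,scr_stage_floor composite-endpoint settings.
#' @param min_stay_h,max_missing_uo_frac,admission_aki_window_h exclusion
#'   thresholds.
#' @param window_h,horizon_h,truncation_lead_h window geometry (h).
#' @param test_frac held-out fraction of cohort A patients.
#' @param convnet a [convnet_spec()].
#' @param aggregation patient-level score aggregation, `"max"` or `"mean"`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_patients_a = 2000, n_patients_b = 2000,
                            seed = 1L,
                            cohort_a = NULL, cohort_b = NULL,
                            split_max_h = 9, max_carry_h = 95,
                            co_window_h = 12, scr_stage_floor = 1,
                            min_stay_h = 24, max_missing_uo_frac = 0.30,
                            admission_aki_window_h = 12,
                            window_h = 12, horizon_h = 24,
                            truncation_lead_h = 6,
                            test_frac = 0.3,
                            convnet = convnet_spec(),
                            aggregation = "max") {
  seeds <- derive_seeds(seed, c("gen_a", "gen_b", "split", "convnet"))
  if (is.null(cohort_a)) {
    cohort_a <- generator_config(n_patients = n_patients_a, prevalence = 0.03,
                                 uo_interval_median_h = 2.4,
                                 scr_interval_median_h = 23.2,
                                 seed = seeds[["gen_a"]])
  } else {
    cohort_a$seed <- seeds[["gen_a"]]
  }
  if (is.null(cohort_b)) {
    cohort_b <- generator_config(n_patients = n_patients_b, prevalence = 0.042,
                                 uo_interval_median_h = 1.3,
                                 scr_interval_median_h = 16.2,
                                 seed = seeds[["gen_b"]])
  } else {
    cohort_b$seed <- seeds[["gen_b"]]
  }
  convnet$seed <- seeds[["convnet"]]
  hours <- c(split_max_h = split_max_h, max_carry_h = max_carry_h,
             co_window_h = co_window_h, min_stay_h = min_stay_h,
             window_h = window_h, horizon_h = horizon_h,
             truncation_lead_h = truncation_lead_h)
  abort_if(any(hours <= 0) || any(hours != round(hours)),
           "all hour parameters must be positive integers")
  abort_if(!aggregation %in% c("max", "mean"),
           "`aggregation` must be 'max' or 'mean'")
  structure(list(cohort_a = cohort_a, cohort_b = cohort_b,
                 split_max_h = split_max_h, max_carry_h = max_carry_h,
                 co_window_h = co_window_h, scr_stage_floor = scr_stage_floor,
                 min_stay_h = min_stay_h,
                 max_missing_uo_frac = max_missing_uo_frac,
                 admission_aki_window_h = admission_aki_window_h,
                 window_h = window_h, horizon_h = horizon_h,
                 truncation_lead_h = truncation_lead_h,
                 test_frac = test_frac, convnet = convnet,
                 aggregation = aggregation,
                 seed = as.integer(seed), seeds = seeds),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `path` invisibly, or the reconstructed `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  snap <- unclass(config)
  snap$cohort_a <- unclass(snap$cohort_a)
  snap$cohort_b <- unclass(snap$cohort_b)
  snap$convnet <- unclass(snap$convnet)
  snap$seeds <- as.list(snap$seeds)
  yaml::write_yaml(snap, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  snap <- yaml::read_yaml(path)
  cfg <- pipeline_config(seed = snap$seed)
  for (nm in setdiff(names(snap), c("cohort_a", "cohort_b", "convnet", "seeds"))) {
    cfg[[nm]] <- snap[[nm]]
  }
  cfg$cohort_a <- do.call(generator_config, snap$cohort_a)
  cfg$cohort_b <- do.call(generator_config, snap$cohort_b)
  cfg$convnet <- do.call(convnet_spec, snap$convnet)
  cfg$seeds <- unlist(snap$seeds)
  cfg
}

#' Preprocess, label, filter and window one cohort
#'
#' Runs the full data side of the pipeline on a raw cohort and logs the
#' patient counts at every filtering step.
#'
#' @param cohort an `icu_cohort`.
#' @param config a [pipeline_config()].
#' @return list with `trajectories`, `labelled`, `exclusions`, `windows`
#'   (tibble), `no_window`, `counts` (named integer vector).
#' @export
prepare_cohort <- function(cohort, config) {
  trajectories <- build_trajectories(cohort,
                                     split_max_h = config$split_max_h,
                                     max_carry_h = config$max_carry_h)
  labelled <- label_cohort(trajectories, cohort,
                           co_window_h = config$co_window_h,
                           scr_stage_floor = config$scr_stage_floor)
  excl <- apply_exclusions(trajectories, labelled$labels,
                           min_stay_h = config$min_stay_h,
                           max_missing_uo_frac = config$max_missing_uo_frac,
                           admission_aki_window_h = config$admission_aki_window_h,
                           truncation_lead_h = config$truncation_lead_h,
                           window_h = config$window_h)
  ws <- build_window_set(trajectories, labelled, cohort, excl$included,
                         window_h = config$window_h,
                         horizon_h = config$horizon_h,
                         truncation_lead_h = config$truncation_lead_h)
  counts <- c(total = nrow(cohort$demographics),
              included = length(excl$included),
              excluded = sum(excl$log$decision == "excluded"),
              events_labelled = sum(labelled$labels$has_event),
              windows = nrow(ws$windows),
              positive_windows = sum(ws$windows$label == 1))
  list(trajectories = trajectories, labelled = labelled, exclusions = excl,
       windows = ws$windows, no_window = ws$no_window, counts = counts)
}

evaluate_scores <- function(scores, windows, aggregation) {
  roc <- roc_curve(scores, windows$label)
  pat <- patient_level_scores(scores, windows$patient_id, agg = aggregation)
  pat_label <- tapply(windows$label, windows$patient_id, max)
  pat_roc <- roc_curve(pat$score, as.numeric(pat_label[pat$patient_id]))
  list(roc = roc, patient_roc = pat_roc,
       fixed = operating_point_fixed_sensitivity(roc, 0.80),
       knee = knee_point(roc))
}

metric_rows <- function(model, dataset, ev) {
  do.call(rbind, lapply(list(ev$fixed, ev$knee), function(op) {
    data.frame(model = model, dataset = dataset,
               working_point = op$selection_rule,
               auroc = ev$roc$auc, auroc_se = ev$roc$auc_se,
               sensitivity = op$sensitivity, specificity = op$specificity,
               patient_auroc = ev$patient_roc$auc,
               n_pos_windows = ev$roc$n_pos, n_neg_windows = ev$roc$n_neg)
  }))
}

#' Run the full study design on synthetic cohorts
#'
#' Generates cohorts A and B, preprocesses and labels both, trains the
#' logistic model and the conv net on the training split of cohort A, and
#' evaluates both models on the held-out A split and on all of cohort B
#' (external validation), at the fixed-80%-sensitivity and knee-point
#' working points.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage progress and Fig.-1-style counts?
#' @return list with `models`, `metrics` (tibble), `report` (rendered
#'   tibble), `predictions` (tibble), `prepared` (per-cohort artefacts)
#'   and `counts`.
#' @export
run_study <- function(config = pipeline_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("generating cohort A (training-like) ...")
  cohort_a <- generate_cohort(config$cohort_a)
  say("generating cohort B (external-validation-like) ...")
  cohort_b <- generate_cohort(config$cohort_b)
  say("preprocessing + labelling ...")
  prep_a <- prepare_cohort(cohort_a, config)
  prep_b <- prepare_cohort(cohort_b, config)
  say("cohort A: %s", paste(names(prep_a$counts), prep_a$counts,
                            sep = "=", collapse = ", "))
  say("cohort B: %s", paste(names(prep_b$counts), prep_b$counts,
                            sep = "=", collapse = ", "))

  lab_a <- prep_a$labelled$labels
  win_a <- prep_a$windows
  pat_event <- setNames(lab_a$has_event, lab_a$patient_id)
  pats <- unique(win_a$patient_id)
  split <- split_patients(pats, as.logical(pat_event[pats]),
                          test_frac = config$test_frac,
                          seed = config$seeds[["split"]])
  train <- win_a[win_a$patient_id %in% split$train, ]
  test_a <- win_a[win_a$patient_id %in% split$test, ]
  abort_if(sum(train$label == 1) == 0 || sum(train$label == 0) == 0,
           "training windows contain a single class; cannot fit models")

  say("fitting logistic model on %d windows ...", nrow(train))
  feats_train <- extract_features(train, window_h = config$window_h)
  logistic <- fit_logistic_model(feats_train, train$label)
  say("training conv net on %d windows ...", nrow(train))
  uo_cols <- paste0("uo_h", seq_len(config$window_h))
  convnet <- fit_convnet(as.matrix(train[, uo_cols]), train$label,
                         train$patient_id, spec = config$convnet)
  say("conv net stopped at epoch %d/%d", convnet$best_epoch,
      convnet$epochs_run)

  eval_sets <- list(`cohortA-test` = test_a, `cohortB-external` = prep_b$windows)
  metrics <- list(); preds <- list()
  for (ds in names(eval_sets)) {
    w <- eval_sets[[ds]]
    p_log <- predict(logistic, extract_features(w, window_h = config$window_h))
    p_cnn <- predict(convnet, as.matrix(w[, uo_cols]))
    metrics[[paste0(ds, "-log")]] <-
      metric_rows("logistic", ds, evaluate_scores(p_log, w, config$aggregation))
    metrics[[paste0(ds, "-cnn")]] <-
      metric_rows("deep_learning", ds, evaluate_scores(p_cnn, w, config$aggregation))
    preds[[ds]] <- tibble::tibble(
      patient_id = rep(w$patient_id, 2),
      window_end_hour = rep(w$window_end_hour, 2),
      score = c(p_log, p_cnn),
      label = rep(w$label, 2),
      model_name = rep(c("logistic", "deep_learning"), each = nrow(w)),
      dataset = ds)
  }
  metrics <- tibble::as_tibble(do.call(rbind, metrics))
  list(models = list(logistic = logistic, convnet = convnet),
       metrics = metrics,
       report = render_report(metrics),
       predictions = dplyr::bind_rows(preds),
       prepared = list(cohort_a = prep_a, cohort_b = prep_b),
       cohorts = list(cohort_a = cohort_a, cohort_b = cohort_b),
       split = split,
       counts = list(cohort_a = prep_a$counts, cohort_b = prep_b$counts))
}

#' Generate and write both study cohorts (command form)
#'
#' Wraps the synthetic-cohort generator: writes the four CSVs per cohort
#' plus a resolved YAML config snapshot into a run directory.
#'
#' @param config a [pipeline_config()].
#' @param directory run directory (created if needed).
#' @param overwrite overwrite existing files?
#' @return the directory, invisibly.
#' @export
cmd_generate <- function(config = pipeline_config(), directory,
                         overwrite = FALSE) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  write_cohort(generate_cohort(config$cohort_a),
               file.path(directory, "cohort_a"), overwrite = overwrite)
  write_cohort(generate_cohort(config$cohort_b),
               file.path(directory, "cohort_b"), overwrite = overwrite)
  write_pipeline_config(config, file.path(directory, "config.yaml"))
  invisible(directory)
}

#' Run the study end-to-end and write all artefacts (command form)
#'
#' Calls [run_study()] and writes the exclusion logs, window files,
#' predictions, `metrics.csv`, the rendered `report.csv` and the config
#' snapshot into the run directory.
#'
#' @param config a [pipeline_config()].
#' @param directory output directory.
#' @param verbose print progress?
#' @return the [run_study()] result, invisibly.
#' @export
cmd_run <- function(config = pipeline_config(), directory, verbose = TRUE) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  res <- run_study(config, verbose = verbose)
  for (ds in c("cohort_a", "cohort_b")) {
    readr::write_csv(res$prepared[[ds]]$exclusions$log,
                     file.path(directory, paste0("exclusions_", ds, ".csv")))
    readr::write_csv(res$prepared[[ds]]$windows,
                     file.path(directory, paste0("windows_", ds, ".csv")))
    readr::write_csv(res$prepared[[ds]]$labelled$labels,
                     file.path(directory, paste0("labels_", ds, ".csv")))
  }
  readr::write_csv(res$predictions, file.path(directory, "predictions.csv"))
  readr::write_csv(res$metrics, file.path(directory, "metrics.csv"))
  readr::write_csv(res$report, file.path(directory, "report.csv"))
  write_pipeline_config(config, file.path(directory, "config.yaml"))
  write_model(res$models$logistic, file.path(directory, "model_logistic.json"))
  write_model(res$models$convnet, file.path(directory, "model_convnet.json"))
  invisible(res)
}

#' Validate the published operating-point tables (command form)
#'
#' Pure arithmetic: recomputes every published LR+/LR- cell from its own
#' row's printed sensitivity and specificity (see
#' [check_reference_tables()]) and prints a match/mismatch summary.
#'
#' @param quiet suppress printing?
#' @return the check tibble, invisibly.
#' @export
cmd_validate_tables <- function(quiet = FALSE) {
  chk <- check_reference_tables()
  if (!quiet) {
    n_bad <- sum(!chk$lr_pos_consistent) + sum(!chk$lr_neg_consistent)
    cat(sprintf("%d published LR cells checked; %d inconsistent\n",
                2L * nrow(chk), n_bad))
    bad <- chk[!chk$lr_pos_consistent | !chk$lr_neg_consistent, ]
    if (nrow(bad)) print(as.data.frame(bad))
  }
  invisible(chk)
}
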