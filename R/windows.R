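exclusion_reasons <- c("missing_uo", "missing_scr", "stay_too_short",
                       "aki_at_admission", "event_unlabelable")

#' Apply inclusion/exclusion criteria
#'
#' Excludes patients with: no urine-output records or more than
#' `max_missing_uo_frac` of hourly urine bins missing (`missing_uo`); no
#' creatinine measurements (`missing_scr`); a stay shorter than
#' `min_stay_h` (`stay_too_short`); the composite stage 2/3 condition
#' already satisfied within the first `admission_aki_window_h` hours, a
#' community-acquired-AKI proxy (`aki_at_admission`); or an episode onset
#' too early to leave at least one full observation window after truncation
#' (`event_unlabelable`). Reasons are assigned in that order of precedence;
#' every patient appears in the log exactly once.
#'
#' @param trajectories named list of `hourly_trajectory` objects.
#' @param labels the `labels` tibble from [label_cohort()].
#' @param min_stay_h minimum stay (h).
#' @param max_missing_uo_frac tolerated fraction of missing urine bins.
#' @param admission_aki_window_h window defining AKI "present on admission".
#' @param truncation_lead_h hours removed before onset ([truncate_before_onset()]).
#' @param window_h observation window length (h).
#' @return list with `included` (patient ids) and `log` (tibble:
#'   patient_id, decision, reason).
#' @export
apply_exclusions <- function(trajectories, labels, min_stay_h = 24,
                             max_missing_uo_frac = 0.30,
                             admission_aki_window_h = 12,
                             truncation_lead_h = 6, window_h = 12) {
  lab <- labels[match(names(trajectories), labels$patient_id), ]
  rows <- vector("list", length(trajectories))
  for (i in seq_along(trajectories)) {
    tr <- trajectories[[i]]
    miss <- mean(is.na(tr$uo_norm))
    reason <- NA_character_
    if (tr$n_hours == 0 || all(is.na(tr$uo_norm)) || miss > max_missing_uo_frac) {
      reason <- "missing_uo"
    } else if (!lab$labelable[i]) {
      reason <- "missing_scr"
    } else if (tr$n_hours < min_stay_h) {
      reason <- "stay_too_short"
    } else if (lab$has_event[i] && lab$onset_hour[i] <= admission_aki_window_h) {
      reason <- "aki_at_admission"
    } else if (lab$has_event[i] &&
               lab$onset_hour[i] - truncation_lead_h < window_h) {
      reason <- "event_unlabelable"
    }
    rows[[i]] <- data.frame(
      patient_id = tr$patient_id,
      decision = if (is.na(reason)) "included" else "excluded",
      reason = reason)
  }
  log <- tibble::as_tibble(dplyr::bind_rows(rows))
  list(included = log$patient_id[log$decision == "included"], log = log)
}

#' Truncate a case trajectory ahead of its episode
#'
#' Case trajectories are cut `lead_h` hours before the detected onset, so
#' that a model trained on the result is forced to predict at least that
#' far ahead; control trajectories pass through unchanged (their full stay,
#' admission to discharge or death, is used).
#'
#' @param trajectory an `hourly_trajectory`.
#' @param episode an `aki_episode` or `NULL` for controls.
#' @param lead_h hours removed before onset.
#' @return a (possibly shortened) `hourly_trajectory`.
#' @export
truncate_before_onset <- function(trajectory, episode, lead_h = 6) {
  if (is.null(episode)) return(trajectory)
  keep <- episode$onset_hour - lead_h
  abort_if(keep < 1, "onset too early to truncate: no usable hours remain")
  build_trajectory(trajectory$patient_id,
                   trajectory$uo_ml_per_h[seq_len(keep)],
                   trajectory$scr_mg_dl[seq_len(keep)],
                   trajectory$ibw_kg)
}

#' Cut sliding observation windows from one trajectory
#'
#' One window per hourly step, wherever `window_h` consecutive observed
#' urine bins (and an available creatinine value at the window end) exist.
#' The label is 1 when the episode onset falls within
#' `(window_end, window_end + horizon_h]`. Case trajectories are expected
#' to be pre-truncated ([truncate_before_onset()]), which guarantees every
#' positive window a lead time of at least the truncation lead.
#'
#' @param trajectory an `hourly_trajectory` (truncated for cases).
#' @param episode the patient's `aki_episode` or `NULL`; the onset refers
#'   to the untruncated time axis.
#' @param baseline a [baseline_creatinine()] (or positive scalar).
#' @param age_group,sex patient covariates carried onto each window.
#' @param window_h window length (h).
#' @param horizon_h prediction horizon (h).
#' @return a tibble with columns `patient_id`, `window_end_hour`,
#'   `uo_h1`..`uo_h<window_h>` (oldest to newest, ml/h/kg), `age_group`,
#'   `sex`, `scr`, `scr_ratio`, `label`; zero rows if no valid window.
#' @export
make_windows <- function(trajectory, episode = NULL, baseline,
                         age_group = NA_character_, sex = NA_character_,
                         window_h = 12, horizon_h = 24) {
  b <- if (inherits(baseline, "baseline_creatinine")) baseline$value_mg_dl
       else baseline
  T <- trajectory$n_hours
  uo <- trajectory$uo_norm
  scr <- trajectory$scr_mg_dl
  empty <- tibble::as_tibble(c(
    list(patient_id = character(), window_end_hour = integer()),
    setNames(rep(list(numeric()), window_h), paste0("uo_h", seq_len(window_h))),
    list(age_group = character(), sex = character(), scr = numeric(),
         scr_ratio = numeric(), label = integer())))
  if (T < window_h) return(empty)
  ends <- window_h:T
  csum <- c(0, cumsum(!is.na(uo)))
  complete <- (csum[ends + 1] - csum[ends - window_h + 1]) == window_h
  complete <- complete & !is.na(scr[ends])
  ends <- ends[complete]
  if (!length(ends)) return(empty)
  onset <- if (is.null(episode)) NA_integer_ else episode$onset_hour
  label <- if (is.na(onset)) rep(0L, length(ends)) else
    as.integer(onset > ends & onset <= ends + horizon_h)
  mat <- vapply(seq_len(window_h) - window_h,
                function(j) uo[ends + j], numeric(length(ends)))
  if (length(ends) == 1) mat <- matrix(mat, nrow = 1)
  colnames(mat) <- paste0("uo_h", seq_len(window_h))
  scr_end <- scr[ends]
  tibble::as_tibble(cbind(
    tibble::tibble(patient_id = trajectory$patient_id,
                   window_end_hour = ends),
    tibble::as_tibble(mat),
    tibble::tibble(age_group = age_group, sex = sex,
                   scr = scr_end, scr_ratio = scr_end / b,
                   label = label)))
}

#' Build the full window set for an included cohort
#'
#' Truncates case trajectories, cuts windows for every included patient and
#' stacks them with covariates. Patients contributing zero valid windows
#' are reported in the `no_window` element.
#'
#' @param trajectories named list of trajectories (untruncated).
#' @param labelled result of [label_cohort()].
#' @param cohort the source `icu_cohort` (for demographics and baselines).
#' @param included character vector of included patient ids
#'   ([apply_exclusions()]).
#' @param window_h,horizon_h,truncation_lead_h window geometry (h).
#' @return list with `windows` (tibble) and `no_window` (patient ids).
#' @export
build_window_set <- function(trajectories, labelled, cohort, included,
                             window_h = 12, horizon_h = 24,
                             truncation_lead_h = 6) {
  demo <- cohort$demographics
  scr_by <- split(cohort$scr_records$value_mg_dl, cohort$scr_records$patient_id)
  out <- vector("list", length(included))
  no_window <- character()
  for (i in seq_along(included)) {
    pid <- included[i]
    tr <- trajectories[[pid]]
    ep <- labelled$episodes[[pid]]
    if (!is.null(ep)) {
      tr <- truncate_before_onset(tr, ep, lead_h = truncation_lead_h)
    }
    d <- demo[demo$patient_id == pid, ]
    w <- make_windows(tr, ep,
                      baseline = baseline_creatinine(scr_by[[pid]], pid),
                      age_group = d$age_group[1], sex = d$sex[1],
                      window_h = window_h, horizon_h = horizon_h)
    if (nrow(w) == 0) no_window <- c(no_window, pid) else out[[i]] <- w
  }
  list(windows = tibble::as_tibble(dplyr::bind_rows(out)),
       no_window = no_window)
}

#' Patient-level stratified train/test split
#'
#' Splits patients (never windows) into train and test sets, stratified by
#' event status, under a fixed seed — no patient contributes windows to
#' both sides.
#'
#' @param patient_ids character vector.
#' @param is_event logical vector aligned with `patient_ids`.
#' @param test_frac fraction of patients held out.
#' @param seed integer seed.
#' @return list with `train` and `test` character vectors.
#' @export
split_patients <- function(patient_ids, is_event, test_frac = 0.3, seed = 1L) {
  stopifnot(length(patient_ids) == length(is_event))
  set.seed(as.integer(seed))
  test <- character()
  for (grp in unique(is_event)) {
    ids <- sort(patient_ids[is_event == grp])
    n_test <- round(length(ids) * test_frac)
    test <- c(test, sample(ids, n_test))
  }
  list(train = setdiff(patient_ids, test), test = test)
}
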