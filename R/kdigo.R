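#' Baseline serum creatinine
#'
#' The baseline is the lowest recorded creatinine value; when a patient has
#' readmissions, the lowest value across all admissions is used.
#'
#' @param values a numeric vector of creatinine measurements (mg/dL), or a
#'   list of numeric vectors (one per admission).
#' @param patient_id optional identifier carried through.
#' @return a list of class `baseline_creatinine` with fields `patient_id`,
#'   `value_mg_dl`, `source`.
#' @export
baseline_creatinine <- function(values, patient_id = NA_character_) {
  stays <- if (is.list(values)) values else list(values)
  stays <- lapply(stays, function(v) v[!is.na(v)])
  n_meas <- sum(lengths(stays))
  abort_if(n_meas == 0, "no creatinine measurements: baseline undefined")
  abort_if(any(unlist(stays) <= 0), "creatinine values must be positive")
  structure(list(patient_id = patient_id,
                 value_mg_dl = min(unlist(stays)),
                 source = if (length(stays) > 1) "across-readmissions minimum"
                          else "this-stay minimum"),
            class = "baseline_creatinine")
}

# length of the maximal run of consecutive TRUEs ending at each position;
# NA counts as FALSE (breaks the run)
run_lengths <- function(p) {
  p <- !is.na(p) & p
  idx <- seq_along(p)
  last_break <- cummax(ifelse(p, 0L, idx))
  ifelse(p, idx - last_break, 0L)
}

#' KDIGO urine-output stage track
#'
#' For each hour, the stage implied by the maximal run of consecutive
#' oliguric hours ending there: stage 3 if the rate has been below
#' 0.3 ml/kg/h for >= 24 consecutive hours or zero (anuria) for >= 12 h;
#' stage 2 if below 0.5 ml/kg/h for more than 12 h; stage 1 if below
#' 0.5 ml/kg/h for 6-12 h; else 0. Missing hours break runs (no oliguria
#' is assumed where none was observed) and are themselves `NA` (unknown).
#'
#' @param uo_norm hourly diuresis in ml/h/kg IBW, `NA` allowed.
#' @return integer vector of stages in `{0,1,2,3}` with `NA` for unknown.
#' @export
stage_by_urine <- function(uo_norm) {
  r05 <- run_lengths(uo_norm < 0.5)
  r03 <- run_lengths(uo_norm < 0.3)
  r00 <- run_lengths(uo_norm == 0)
  s <- integer(length(uo_norm))
  s[r05 >= 6 & r05 <= 12] <- 1L
  s[r05 > 12] <- 2L
  s[r03 >= 24 | r00 >= 12] <- 3L
  s[is.na(uo_norm)] <- NA_integer_
  s
}

#' KDIGO creatinine stage track
#'
#' Stage per hour from the filled creatinine sequence relative to baseline:
#' stage 3 if the ratio to baseline is >= 3.0 or the absolute value is
#' >= 4.0 mg/dL; stage 2 if the ratio is in `[2, 3)`; stage 1 if the ratio
#' is in `[1.5, 2)` or the absolute rise over baseline is >= 0.3 mg/dL;
#' else 0. `NA` where creatinine is missing.
#'
#' @param scr_mg_dl hourly creatinine (mg/dL), `NA` allowed.
#' @param baseline a [baseline_creatinine()] or a positive scalar.
#' @return integer vector of stages with `NA` for unknown.
#' @export
stage_by_creatinine <- function(scr_mg_dl, baseline) {
  b <- if (inherits(baseline, "baseline_creatinine")) baseline$value_mg_dl
       else baseline
  abort_if(!is.numeric(b) || length(b) != 1 || is.na(b) || b <= 0,
           "baseline must be a positive scalar")
  ratio <- scr_mg_dl / b
  s <- integer(length(scr_mg_dl))
  s[(ratio >= 1.5 & ratio < 2) | (scr_mg_dl - b >= 0.3)] <- 1L
  s[ratio >= 2 & ratio < 3] <- 2L
  s[ratio >= 3 | scr_mg_dl >= 4.0] <- 3L
  s[is.na(scr_mg_dl)] <- NA_integer_
  s
}

#' Detect a hospital-acquired oliguric AKI stage 2/3 episode
#'
#' The composite endpoint requires a simultaneous reduction in urine output
#' and an increase in serum creatinine: the episode onset is the first hour
#' `h` with urine-output stage >= 2 such that the creatinine stage reaches
#' at least `scr_stage_floor` somewhere within `h +/- co_window_h` hours.
#' How strict "simultaneous" should be is not nailed down by the KDIGO
#' consensus itself, so both the stage floor (default 1, i.e. any
#' creatinine increase) and the co-occurrence window (default +/- 12 h) are
#' exposed as parameters.
#'
#' @param uo_stage urine-output stage track ([stage_by_urine()]).
#' @param scr_stage creatinine stage track ([stage_by_creatinine()]).
#' @param co_window_h co-occurrence half-window in hours.
#' @param scr_stage_floor minimal creatinine stage counting as an increase.
#' @param patient_id optional identifier carried through.
#' @return an `aki_episode` (fields `patient_id`, `onset_hour`, `max_stage`,
#'   `uo_criterion_met`, `scr_criterion_met`) or `NULL` if no episode.
#' @export
detect_oliguric_aki <- function(uo_stage, scr_stage, co_window_h = 12,
                                scr_stage_floor = 1,
                                patient_id = NA_character_) {
  abort_if(length(uo_stage) != length(scr_stage),
           "stage tracks must be aligned")
  T <- length(uo_stage)
  if (T == 0) return(NULL)
  scr_ok <- !is.na(scr_stage) & scr_stage >= scr_stage_floor
  cnt <- c(0, cumsum(scr_ok))
  cand <- which(!is.na(uo_stage) & uo_stage >= 2)
  for (h in cand) {
    lo <- max(h - co_window_h, 1L); hi <- min(h + co_window_h, T)
    if (cnt[hi + 1] - cnt[lo] > 0) {
      later <- uo_stage[h:T]
      return(structure(list(patient_id = patient_id,
                            onset_hour = h,
                            max_stage = max(2L, max(later, na.rm = TRUE)),
                            uo_criterion_met = TRUE,
                            scr_criterion_met = TRUE),
                       class = "aki_episode"))
    }
  }
  NULL
}

#' @export
print.aki_episode <- function(x, ...) {
  cat(sprintf("<aki_episode> %s: onset hour %d, max stage %d\n",
              x$patient_id, x$onset_hour, x$max_stage))
  invisible(x)
}

#' Label every patient of a cohort
#'
#' Computes baselines from the raw creatinine records (lowest value across
#' all rows of a patient, i.e. across readmissions when present), stages
#' both tracks and runs episode detection for every trajectory. Patients
#' with no creatinine records cannot be labeled and are reported as
#' event-free with `labelable = FALSE`.
#'
#' @param trajectories named list of `hourly_trajectory` objects.
#' @param cohort the `icu_cohort` the trajectories came from (for raw
#'   creatinine records).
#' @param co_window_h,scr_stage_floor passed to [detect_oliguric_aki()].
#' @return a list with `labels` (tibble: patient_id, has_event, onset_hour,
#'   max_stage, uo_criterion_met, scr_criterion_met, labelable) and
#'   `episodes` (named list of `aki_episode`).
#' @export
label_cohort <- function(trajectories, cohort, co_window_h = 12,
                         scr_stage_floor = 1) {
  scr_by <- split(cohort$scr_records$value_mg_dl,
                  cohort$scr_records$patient_id)
  pids <- names(trajectories)
  episodes <- list()
  rows <- vector("list", length(pids))
  for (i in seq_along(pids)) {
    pid <- pids[i]
    tr <- trajectories[[pid]]
    vals <- scr_by[[pid]]
    ep <- NULL
    labelable <- !is.null(vals) && length(vals) > 0
    if (labelable) {
      bl <- baseline_creatinine(vals, patient_id = pid)
      us <- stage_by_urine(tr$uo_norm)
      cs <- stage_by_creatinine(tr$scr_mg_dl, bl)
      ep <- detect_oliguric_aki(us, cs, co_window_h = co_window_h,
                                scr_stage_floor = scr_stage_floor,
                                patient_id = pid)
    }
    if (!is.null(ep)) episodes[[pid]] <- ep
    rows[[i]] <- data.frame(
      patient_id = pid,
      has_event = !is.null(ep),
      onset_hour = if (is.null(ep)) NA_integer_ else ep$onset_hour,
      max_stage = if (is.null(ep)) NA_integer_ else ep$max_stage,
      uo_criterion_met = !is.null(ep),
      scr_criterion_met = !is.null(ep),
      labelable = labelable)
  }
  list(labels = tibble::as_tibble(dplyr::bind_rows(rows)),
       episodes = episodes)
}
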