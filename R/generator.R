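#' Configuration for the synthetic ICU cohort generator
#'
#' Builds and validates the parameter set that defines a synthetic cohort.
#' Defaults emulate the acquisition regime and case mix of a large European
#' ICU database: median urine-output charting interval 1.3 h, median
#' creatinine draw interval 16.2 h, oliguric-AKI stage 2/3 prevalence 4.2%,
#' 71.1% male, and an age mix concentrated in the 60-79 bands. An
#' "eICU-like" regime is obtained with `uo_interval_median_h = 2.4`,
#' `scr_interval_median_h = 23.2`, `prevalence = 0.03`.
#'
#' Event patients carry a prodromal linear decline of diuresis
#' (`prodrome_h` hours), then a sustained oliguric phase (hourly rate below
#' `event_depth_max`, lasting `event_duration_range_h` hours), with serum
#' creatinine rising to `event_scr_fold` times its pre-event level over
#' `scr_rise_h` hours from phase start. Laboratory draws densify once
#' oliguria begins (`scr_event_interval_factor`), reflecting illness-driven
#' lab intensity. Non-event patients never satisfy the stage 2/3 rules; a
#' fraction of them get a short transient mild oliguria episode so that
#' specificity is non-trivial.
#'
#' @param n_patients number of patients.
#' @param prevalence fraction of patients given an oliguric AKI 2/3 episode.
#' @param uo_interval_median_h median urine-output inter-record interval (h).
#' @param scr_interval_median_h median creatinine inter-record interval (h).
#' @param interval_shape gamma shape of inter-record intervals (larger =
#'   tighter around the median).
#' @param scr_interval_cap_h hard cap on creatinine draw gaps (h); ICUs draw
#'   chemistry at least daily or thereabouts.
#' @param scr_event_interval_factor multiplier on creatinine gaps after
#'   oliguria onset.
#' @param scr_event_interval_cap_h gap cap after oliguria onset (h).
#' @param stay_meanlog,stay_sdlog log-normal parameters of ICU stay length (h).
#' @param stay_min_h minimum stay (h).
#' @param age_group_weights probability weights over the six age bands
#'   18-39, 40-49, 50-59, 60-69, 70-79, 80+.
#' @param male_fraction probability of male sex.
#' @param mortality_fraction probability of the in-hospital death flag.
#' @param baseline_uo_median healthy-state median hourly diuresis (ml/h/kg).
#' @param baseline_uo_sdlog hour-to-hour log-sd of healthy diuresis.
#' @param patient_effect_sdlog log-sd of the per-patient diuresis level.
#' @param baseline_scr_mean,baseline_scr_sd pre-event serum creatinine (mg/dL).
#' @param scr_noise_frac relative measurement noise on creatinine.
#' @param event_depth mean hourly diuresis during the oliguric phase (ml/h/kg).
#' @param event_depth_sd sd of hourly diuresis during the phase.
#' @param event_depth_max clip ceiling of phase diuresis; must stay below the
#'   0.5 ml/kg/h KDIGO threshold.
#' @param event_scr_fold multiplier applied to creatinine after onset.
#' @param event_duration_range_h range (h) of the oliguric phase duration;
#'   must exceed 12 h so the stage-2 run rule is reachable.
#' @param prodrome_h length of the pre-phase diuresis decline (h).
#' @param scr_rise_h hours over which creatinine ramps to its event level.
#' @param event_min_onset_h earliest phase start after admission (h).
#' @param transient_oliguria_fraction fraction of non-event patients with a
#'   short (4-9 h) mild oliguria episode.
#' @param missing_scr_fraction fraction of non-event patients with no
#'   creatinine records at all.
#' @param long_gap_prob per-record probability of a >= 9 h urine charting gap.
#' @param long_gap_range_h range of those long gaps (h).
#' @param seed integer seed; identical configs give byte-identical cohorts.
#' @return an object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_patients = 2000,
                             prevalence = 0.042,
                             uo_interval_median_h = 1.3,
                             scr_interval_median_h = 16.2,
                             interval_shape = 8,
                             scr_interval_cap_h = 28,
                             scr_event_interval_factor = 0.5,
                             scr_event_interval_cap_h = 12,
                             stay_meanlog = log(40),
                             stay_sdlog = 0.9,
                             stay_min_h = 8,
                             age_group_weights = c(0.068, 0.073, 0.155,
                                                   0.282, 0.306, 0.117),
                             male_fraction = 0.711,
                             mortality_fraction = 0.089,
                             baseline_uo_median = 1.1,
                             baseline_uo_sdlog = 0.45,
                             patient_effect_sdlog = 0.2,
                             baseline_scr_mean = 0.9,
                             baseline_scr_sd = 0.18,
                             scr_noise_frac = 0.04,
                             event_depth = 0.20,
                             event_depth_sd = 0.06,
                             event_depth_max = 0.30,
                             event_scr_fold = 2.5,
                             event_duration_range_h = c(24, 40),
                             prodrome_h = 12,
                             scr_rise_h = 6,
                             event_min_onset_h = 24,
                             transient_oliguria_fraction = 0.08,
                             missing_scr_fraction = 0.02,
                             long_gap_prob = 0.003,
                             long_gap_range_h = c(9, 18),
                             seed = 1L) {
  cfg <- as.list(environment())
  abort_if(!is.numeric(n_patients) || n_patients < 0 || n_patients != round(n_patients),
           "`n_patients` must be a non-negative integer")
  abort_if(prevalence < 0 || prevalence > 1, "`prevalence` must lie in [0, 1]")
  abort_if(uo_interval_median_h <= 0 || scr_interval_median_h <= 0,
           "interval medians must be positive")
  abort_if(any(age_group_weights < 0) || sum(age_group_weights) <= 0,
           "`age_group_weights` must be non-negative and sum to a positive value")
  cfg$age_group_weights <- age_group_weights / sum(age_group_weights)
  abort_if(event_depth_max >= 0.5,
           "`event_depth_max` must stay below the 0.5 ml/kg/h oliguria threshold")
  abort_if(length(event_duration_range_h) != 2 || event_duration_range_h[1] <= 12,
           "`event_duration_range_h` must be a range with lower bound > 12 h (stage 2 needs a run of more than 12 h)")
  abort_if(diff(event_duration_range_h) < 0, "`event_duration_range_h` must be increasing")
  abort_if(stay_min_h <= 0, "`stay_min_h` must be positive")
  abort_if(event_min_onset_h < prodrome_h,
           "`event_min_onset_h` must leave room for the prodromal decline")
  abort_if(length(seed) != 1 || !is.finite(seed), "`seed` must be a single integer")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf("  patients: %d, prevalence: %.3f, seed: %d\n",
              x$n_patients, x$prevalence, x$seed))
  cat(sprintf("  urine charting median %.1f h, creatinine draws median %.1f h\n",
              x$uo_interval_median_h, x$scr_interval_median_h))
  invisible(x)
}

age_group_levels <- function() {
  c("18-39", "40-49", "50-59", "60-69", "70-79", "80+")
}

# gamma inter-record gaps with a given median; optionally capped
draw_gaps <- function(n, median_h, shape, cap = Inf, min_gap = 0.25) {
  scale <- median_h / qgamma(0.5, shape = shape)
  pmin(pmax(rgamma(n, shape = shape, scale = scale), min_gap), cap)
}

# cumulative urine volume (ml) at continuous time t for hourly-binned rates
cum_volume_at <- function(t, vol_hourly) {
  T <- length(vol_hourly)
  cum <- c(0, cumsum(vol_hourly))
  fb <- pmin(floor(t), T)          # complete bins below t
  cum[fb + 1] + ifelse(fb < T, vol_hourly[fb + 1], 0) * pmax(t - fb, 0)
}

# one patient's true hourly diuresis profile (ml/h/kg); T whole-hour bins
simulate_uo_profile <- function(T, pe, cfg, event, ps, dur, transient, ts, tlen) {
  rate <- pe * rlnorm(T, meanlog = log(cfg$baseline_uo_median),
                      sdlog = cfg$baseline_uo_sdlog)
  rate <- pmax(rate, 0.05)
  if (event) {
    L <- cfg$prodrome_h
    pro <- seq_len(L)
    idx <- ps - L - 1 + pro                     # bins ps-L .. ps-1
    target <- pe * cfg$baseline_uo_median +
      (0.55 - pe * cfg$baseline_uo_median) * pro / L
    rate[idx] <- pmax(target + rnorm(L, 0, 0.08), 0.5)
    ph <- ps:(ps + dur - 1)                     # the oliguric phase
    rate[ph] <- pmin(pmax(rnorm(dur, cfg$event_depth, cfg$event_depth_sd),
                          0.02), cfg$event_depth_max)
    rec <- (ps + dur):min(ps + dur + 11, T)     # recovery ramp
    if (length(rec)) {
      frac <- seq_along(rec) / 12
      rate[rec] <- pmax(0.55 + frac * (pe * cfg$baseline_uo_median - 0.55) +
                          rnorm(length(rec), 0, 0.1), 0.5)
    }
  } else if (transient) {
    tb <- ts:(ts + tlen - 1)
    rate[tb] <- pmin(pmax(rnorm(tlen, 0.38, 0.05), 0.30), 0.49)
  }
  rate
}

#' Generate a synthetic ICU cohort
#'
#' Draws demographics, irregular nurse-charted urine-output records (each
#' record is the volume accumulated since the previous record), laboratory
#' serum-creatinine records, and a withheld truth table. Event patients carry
#' a stage 2/3 oliguric-AKI signature: a contiguous oliguric phase (hourly
#' diuresis below 0.5 ml/kg/h lasting more than 12 consecutive hours) with a
#' simultaneous creatinine rise to at least twice the pre-event level.
#' `truth$true_onset_hour` is the first hour at which the KDIGO stage-2
#' urine-output run rule is satisfiable (12 h after the phase starts;
#' the phase start itself is in `truth$phase_start_hour`).
#'
#' @param config a [generator_config()].
#' @return an object of class `icu_cohort`: a list with tibbles
#'   `demographics`, `uo_records`, `scr_records`, `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- as.integer(cfg$n_patients)
  base_admit <- as.POSIXct("2015-01-01 00:00:00", tz = "UTC")

  demo <- vector("list", n)
  uo_l <- vector("list", n)
  scr_l <- vector("list", n)
  truth_l <- vector("list", n)

  for (i in seq_len(n)) {
    pid <- sprintf("P%05d", i)
    sex <- if (runif(1) < cfg$male_fraction) "male" else "female"
    age_group <- sample(age_group_levels(), 1, prob = cfg$age_group_weights)
    height <- rnorm(1, if (sex == "male") 177 else 164, 7)
    height <- min(max(height, 140), 209)
    lo <- floor(height / 10) * 10
    height_range <- sprintf("%d-%d", lo, lo + 9)
    ibw <- compute_ibw(sex, c(lo, lo + 9))
    died <- runif(1) < cfg$mortality_fraction
    event <- runif(1) < cfg$prevalence

    stay <- max(rlnorm(1, cfg$stay_meanlog, cfg$stay_sdlog), cfg$stay_min_h)
    ps <- NA_integer_; dur <- NA_integer_
    transient <- FALSE; ts <- NA_integer_; tlen <- NA_integer_
    if (event) {
      dur <- as.integer(round(runif(1, cfg$event_duration_range_h[1],
                                    cfg$event_duration_range_h[2])))
      need <- cfg$event_min_onset_h + 1 + dur + 12
      for (k in 1:20) {
        if (stay >= need) break
        stay <- max(rlnorm(1, cfg$stay_meanlog, cfg$stay_sdlog), cfg$stay_min_h)
      }
      if (stay < need) stay <- need + runif(1, 0, 24)
      ps_max <- floor(stay) - dur - 12
      ps <- as.integer(floor(runif(1, cfg$event_min_onset_h + 1, ps_max + 1)))
    } else if (runif(1) < cfg$transient_oliguria_fraction && floor(stay) >= 26) {
      transient <- TRUE
      tlen <- sample(4:9, 1)
      ts <- sample(13:(floor(stay) - tlen - 1), 1)
    }
    T <- as.integer(floor(stay))

    pe <- min(max(exp(rnorm(1, 0, cfg$patient_effect_sdlog)), 0.7), 1.6)
    rate <- simulate_uo_profile(T, pe, cfg, event, ps, dur, transient, ts, tlen)
    vol <- rate * ibw

    admit <- base_admit + round(runif(1, 0, 365 * 24 * 3600))
    discharge <- admit + round(stay * 3600)

    # urine-output records: renewal process, volume = integral since previous
    max_rec <- ceiling(stay / max(cfg$uo_interval_median_h / 4, 0.25)) + 10
    gaps <- draw_gaps(max_rec, cfg$uo_interval_median_h, cfg$interval_shape)
    long <- runif(max_rec) < cfg$long_gap_prob
    gaps[long] <- runif(sum(long), cfg$long_gap_range_h[1], cfg$long_gap_range_h[2])
    tt <- cumsum(gaps)
    tt <- round(tt[tt <= stay] * 3600) / 3600
    if (length(tt)) {
      cv <- cum_volume_at(c(0, tt), vol)
      vols <- round(diff(cv), 2)
      uo_l[[i]] <- data.frame(patient_id = pid,
                              timestamp = admit + round(tt * 3600),
                              volume_ml = vols)
    }

    # creatinine records: admission chemistry, then renewal draws;
    # draws densify once the oliguric phase starts
    rho <- max(rnorm(1, cfg$baseline_scr_mean, cfg$baseline_scr_sd), 0.4)
    no_scr <- !event && runif(1) < cfg$missing_scr_fraction
    if (!no_scr) {
      st <- runif(1, 0.5, 3)
      times <- st
      while (TRUE) {
        in_event <- event && st >= ps - 1
        g <- draw_gaps(1, cfg$scr_interval_median_h *
                         (if (in_event) cfg$scr_event_interval_factor else 1),
                       cfg$interval_shape,
                       cap = if (in_event) cfg$scr_event_interval_cap_h
                             else cfg$scr_interval_cap_h,
                       min_gap = 0.5)
        st <- st + g
        if (st > stay) break
        times <- c(times, st)
      }
      times <- round(times * 3600) / 3600
      lev <- rep(rho, length(times))
      if (event) {
        rise <- pmin(pmax((times - (ps - 1)) / cfg$scr_rise_h, 0), 1)
        lev <- rho * (1 + (cfg$event_scr_fold - 1) * rise)
      }
      val <- pmax(round(lev * (1 + rnorm(length(times), 0, cfg$scr_noise_frac)), 3),
                  0.05)
      scr_l[[i]] <- data.frame(patient_id = pid,
                               timestamp = admit + round(times * 3600),
                               value_mg_dl = val)
    }

    demo[[i]] <- data.frame(patient_id = pid, sex = sex, age_group = age_group,
                            height_range = height_range,
                            admit_time = admit, discharge_time = discharge,
                            died_in_hospital = died)
    truth_l[[i]] <- data.frame(patient_id = pid, has_event = event,
                               true_onset_hour = if (event) ps + 12L else NA_integer_,
                               phase_start_hour = if (event) ps else NA_integer_)
  }

  bind_or <- function(lst, empty) {
    out <- dplyr::bind_rows(lst)
    if (nrow(out) == 0) empty else tibble::as_tibble(out)
  }
  empty_time <- as.POSIXct(character(), tz = "UTC")
  cohort <- list(
    demographics = bind_or(demo, tibble::tibble(
      patient_id = character(), sex = character(), age_group = character(),
      height_range = character(), admit_time = empty_time,
      discharge_time = empty_time, died_in_hospital = logical())),
    uo_records = bind_or(uo_l, tibble::tibble(
      patient_id = character(), timestamp = empty_time, volume_ml = numeric())),
    scr_records = bind_or(scr_l, tibble::tibble(
      patient_id = character(), timestamp = empty_time, value_mg_dl = numeric())),
    truth = bind_or(truth_l, tibble::tibble(
      patient_id = character(), has_event = logical(),
      true_onset_hour = integer(), phase_start_hour = integer()))
  )
  structure(c(cohort, list(config = cfg)), class = "icu_cohort")
}

#' @export
print.icu_cohort <- function(x, ...) {
  cat("<icu_cohort>\n")
  cat(sprintf("  %d patients, %d urine-output records, %d creatinine records\n",
              nrow(x$demographics), nrow(x$uo_records), nrow(x$scr_records)))
  if (nrow(x$truth)) {
    cat(sprintf("  oliguric-AKI 2/3 events: %d (%.1f%%)\n",
                sum(x$truth$has_event),
                100 * mean(x$truth$has_event)))
  }
  invisible(x)
}
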