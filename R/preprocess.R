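#' Ideal body weight from sex and a charted height range
#'
#' De-identified ICU exports often report height only as a decade range
#' (e.g. "170-179" cm); the midpoint of the range is used. IBW follows the
#' Devine formula — male: 50 + 0.9059 kg per cm above 152.4 cm; female:
#' 45.5 + 0.9059 kg per cm above 152.4 cm (2.3 kg per inch over 5 ft) —
#' floored at 40 kg.
#'
#' @param sex `"male"` or `"female"`.
#' @param height_range numeric height in cm: either a single exact value or
#'   a length-2 closed interval `c(lo, hi)`.
#' @return ideal body weight in kg.
#' @export
compute_ibw <- function(sex, height_range) {
  abort_if(!is.character(sex) || length(sex) != 1 ||
             !sex %in% c("male", "female"),
           paste0("unknown sex code: ", paste(sex, collapse = ",")))
  abort_if(!is.numeric(height_range) || !length(height_range) %in% c(1, 2) ||
             anyNA(height_range),
           "`height_range` must be one or two numeric heights in cm")
  abort_if(any(height_range < 120) || any(height_range > 220),
           "height range must lie within [120, 220] cm")
  abort_if(length(height_range) == 2 && diff(height_range) < 0,
           "height range must be increasing")
  h <- mean(height_range)
  base <- if (sex == "male") 50 else 45.5
  max(base + 0.9059 * (h - 152.4), 40)
}

#' Parse a "lo-hi" height range string
#'
#' @param x character vector like `"170-179"`.
#' @return a numeric matrix with columns `lo`, `hi` (cm).
#' @export
parse_height_range <- function(x) {
  parts <- regmatches(x, regexec("^\\s*([0-9]+(?:\\.[0-9]+)?)\\s*-\\s*([0-9]+(?:\\.[0-9]+)?)\\s*$", x))
  bad <- vapply(parts, length, 1L) != 3L
  abort_if(any(bad), paste0("unparseable height range: ",
                            paste(x[bad], collapse = ", ")))
  lo <- as.numeric(vapply(parts, `[[`, "", 2))
  hi <- as.numeric(vapply(parts, `[[`, "", 3))
  cbind(lo = lo, hi = hi)
}

# bin index of a time in hours since admission: bins 1..T cover (h-1, h];
# a record exactly on a boundary belongs to the earlier covered bin set.
hour_bin <- function(t) as.integer(ceiling(t - 1e-9))

#' Resample irregular urine-output records onto an hourly grid
#'
#' Nurse-charted urine records carry the volume accumulated since the
#' previous record. For a record covering a gap of `g` whole-hour bins since
#' the previous record (or admission): if `g < 9` h the volume is split
#' equally across the `g` covered bins; if `g >= 9` h the covered bins stay
#' missing and the volume is assigned to the record's own bin only. Bins
#' after the last record remain missing. Hour bins are half-open, anchored
#' at admission; applying the operation to an already-hourly stream is the
#' identity.
#'
#' @param times_h record times in hours since admission (sorted, in
#'   `(0, stay_h]`).
#' @param volumes_ml volume per record (ml), non-negative.
#' @param stay_h length of stay in hours; the grid has `floor(stay_h)` bins.
#' @param split_max_h gap threshold below which volumes are split (default
#'   9 h, strict).
#' @return numeric vector of hourly volumes (ml/h) with `NA` for missing.
#' @export
resample_urine_hourly <- function(times_h, volumes_ml, stay_h,
                                  split_max_h = 9) {
  abort_if(length(times_h) != length(volumes_ml),
           "times and volumes must have equal length")
  abort_if(any(volumes_ml < 0, na.rm = TRUE), "volumes must be non-negative")
  abort_if(is.unsorted(times_h), "record times must be sorted")
  abort_if(any(times_h < 0) || any(times_h > stay_h + 1e-9),
           "record outside the stay interval")
  T <- max(as.integer(floor(stay_h)), 0L)
  out <- rep(NA_real_, T)
  prev <- 0L
  for (k in seq_along(times_h)) {
    b <- hour_bin(times_h[k])
    if (b > T) break               # record in the fractional final hour
    if (b < 1L) b <- 1L
    g <- b - prev
    if (g == 0L) {
      out[b] <- (if (is.na(out[b])) 0 else out[b]) + volumes_ml[k]
    } else if (g < split_max_h) {
      share <- volumes_ml[k] / g
      idx <- (prev + 1L):b
      out[idx] <- ifelse(is.na(out[idx]), 0, out[idx]) + share
    } else {
      out[b] <- (if (is.na(out[b])) 0 else out[b]) + volumes_ml[k]
    }
    prev <- max(prev, b)
  }
  out
}

#' Fill hourly creatinine by capped carry-forward
#'
#' Each laboratory value lands in its hour bin (last value wins if two land
#' in one bin) and is carried forward into subsequent missing bins for at
#' most `max_carry_h` hours (default 95 h, i.e. strictly less than 4 days).
#' Bins beyond the cap, and bins before the first measurement, stay missing.
#'
#' @param times_h measurement times in hours since admission (sorted).
#' @param values_mg_dl positive creatinine values (mg/dL).
#' @param stay_h length of stay in hours.
#' @param max_carry_h maximum number of filled hours after a measurement.
#' @return numeric vector of hourly creatinine with `NA` for missing.
#' @export
fill_creatinine <- function(times_h, values_mg_dl, stay_h, max_carry_h = 95) {
  abort_if(length(times_h) != length(values_mg_dl),
           "times and values must have equal length")
  abort_if(any(values_mg_dl <= 0, na.rm = TRUE),
           "creatinine values must be positive")
  abort_if(is.unsorted(times_h), "measurement times must be sorted")
  T <- max(as.integer(floor(stay_h)), 0L)
  out <- rep(NA_real_, T)
  if (T == 0L || !length(times_h)) return(out)
  bins <- pmax(hour_bin(times_h), 1L)
  keep <- bins <= T
  bins <- bins[keep]; vals <- values_mg_dl[keep]
  if (!length(bins)) return(out)
  out[bins] <- vals                          # last value wins within a bin
  measured <- sort(unique(bins))
  for (i in seq_along(measured)) {
    b <- measured[i]
    upto <- if (i < length(measured)) measured[i + 1] - 1L else T
    upto <- min(upto, b + max_carry_h, T)
    if (upto > b) out[(b + 1L):upto] <- out[b]
  }
  out
}

#' Assemble a per-patient hourly trajectory
#'
#' Combines the hourly urine-output and creatinine sequences with the
#' patient's ideal body weight; the normalised diuresis `uo_norm` is
#' `uo_ml_per_h / ibw_kg` wherever urine output is observed (missingness
#' propagates).
#'
#' @param patient_id patient identifier.
#' @param uo_hourly hourly urine volumes (ml/h), `NA` allowed.
#' @param scr_hourly hourly creatinine (mg/dL), `NA` allowed.
#' @param ibw_kg ideal body weight (kg), positive.
#' @return an object of class `hourly_trajectory`.
#' @export
build_trajectory <- function(patient_id, uo_hourly, scr_hourly, ibw_kg) {
  abort_if(length(uo_hourly) != length(scr_hourly),
           "urine and creatinine sequences must share one length")
  abort_if(!is.numeric(ibw_kg) || length(ibw_kg) != 1 || ibw_kg <= 0,
           "`ibw_kg` must be a positive scalar")
  abort_if(any(uo_hourly < 0, na.rm = TRUE) || any(scr_hourly < 0, na.rm = TRUE),
           "trajectory values must be non-negative")
  structure(list(patient_id = patient_id,
                 uo_ml_per_h = as.numeric(uo_hourly),
                 uo_norm = as.numeric(uo_hourly) / ibw_kg,
                 scr_mg_dl = as.numeric(scr_hourly),
                 ibw_kg = ibw_kg,
                 n_hours = length(uo_hourly)),
            class = "hourly_trajectory")
}

#' @export
print.hourly_trajectory <- function(x, ...) {
  cat(sprintf("<hourly_trajectory> %s: %d h, IBW %.1f kg, %d/%d urine bins observed\n",
              x$patient_id, x$n_hours, x$ibw_kg,
              sum(!is.na(x$uo_ml_per_h)), x$n_hours))
  invisible(x)
}

#' Preprocess a raw cohort into hourly trajectories
#'
#' Runs [compute_ibw()], [resample_urine_hourly()] and [fill_creatinine()]
#' for every patient of a raw cohort.
#'
#' @param cohort an `icu_cohort`.
#' @param split_max_h urine split-rule threshold (h).
#' @param max_carry_h creatinine carry-forward cap (h).
#' @param scr_umol_per_l set `TRUE` if creatinine is charted in umol/L;
#'   values are divided by 88.4 to mg/dL. Default off.
#' @return a named list of `hourly_trajectory` objects.
#' @export
build_trajectories <- function(cohort, split_max_h = 9, max_carry_h = 95,
                               scr_umol_per_l = FALSE) {
  demo <- cohort$demographics
  uo_by <- split(cohort$uo_records, cohort$uo_records$patient_id)
  scr_by <- split(cohort$scr_records, cohort$scr_records$patient_id)
  hr <- parse_height_range(demo$height_range)
  out <- vector("list", nrow(demo))
  names(out) <- demo$patient_id
  for (i in seq_len(nrow(demo))) {
    pid <- demo$patient_id[i]
    stay <- as.numeric(difftime(demo$discharge_time[i], demo$admit_time[i],
                                units = "hours"))
    ibw <- compute_ibw(demo$sex[i], c(hr[i, 1], hr[i, 2]))
    uo <- uo_by[[pid]]
    scr <- scr_by[[pid]]
    uo_t <- if (is.null(uo)) numeric() else
      as.numeric(difftime(uo$timestamp, demo$admit_time[i], units = "hours"))
    scr_t <- if (is.null(scr)) numeric() else
      as.numeric(difftime(scr$timestamp, demo$admit_time[i], units = "hours"))
    scr_v <- if (is.null(scr)) numeric() else scr$value_mg_dl
    if (scr_umol_per_l) scr_v <- scr_v / 88.4
    uo_h <- resample_urine_hourly(uo_t, if (is.null(uo)) numeric() else uo$volume_ml,
                                  stay, split_max_h = split_max_h)
    scr_h <- fill_creatinine(scr_t, scr_v, stay, max_carry_h = max_carry_h)
    out[[i]] <- build_trajectory(pid, uo_h, scr_h, ibw)
  }
  out
}
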