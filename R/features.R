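#' Feature extraction for the multi-feature logistic model
#'
#' Summarises each 12-h urine-output window into the feature vector used by
#' the logistic model: minimum, maximum, mean, last value and least-squares
#' slope of the hourly diuresis (ml/h/kg, slope per h), the number of
#' in-window hours below the 0.5 and 0.3 ml/kg/h oliguria thresholds, the
#' creatinine value at the window end, its ratio to baseline, the age band
#' as an ordinal (1 = 18-39 ... 6 = 80+), and a male-sex indicator.
#'
#' @param windows a window tibble from [make_windows()]/[build_window_set()].
#' @param window_h window length (h).
#' @return a tibble of numeric features, one row per window.
#' @export
extract_features <- function(windows, window_h = 12) {
  uo_cols <- paste0("uo_h", seq_len(window_h))
  abort_if(!all(uo_cols %in% names(windows)),
           "`windows` lacks the uo_h* columns")
  Y <- as.matrix(windows[, uo_cols])
  abort_if(anyNA(Y), "windows must be fully observed")
  abort_if(anyNA(windows$scr) || anyNA(windows$scr_ratio) ||
             anyNA(windows$age_group) || anyNA(windows$sex),
           "missing covariate in windows")
  x <- seq_len(window_h)
  xc <- x - mean(x)
  slope <- as.numeric(Y %*% xc) / sum(xc^2)
  age_ord <- match(windows$age_group, age_group_levels())
  abort_if(anyNA(age_ord), "unknown age group label")
  tibble::tibble(
    uo_min = apply(Y, 1, min),
    uo_max = apply(Y, 1, max),
    uo_mean = rowMeans(Y),
    uo_last = as.numeric(Y[, window_h]),
    uo_slope = slope,
    hours_below_05 = rowSums(Y < 0.5),
    hours_below_03 = rowSums(Y < 0.3),
    scr = windows$scr,
    scr_ratio = windows$scr_ratio,
    age_ordinal = as.numeric(age_ord),
    sex_male = as.numeric(windows$sex == "male"))
}
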