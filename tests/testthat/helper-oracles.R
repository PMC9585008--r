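# Independent brute-force oracles used across test files.

# Urine-output KDIGO stage by re-scanning every run from scratch at each
# hour (quadratic; deliberately naive and independent of run_lengths()).
oracle_urine_stage <- function(x) {
  n <- length(x)
  out <- integer(n)
  scan_back <- function(h, pred) {
    r <- 0L
    j <- h
    while (j >= 1 && !is.na(x[j]) && pred(x[j])) {
      r <- r + 1L
      j <- j - 1L
    }
    r
  }
  for (h in seq_len(n)) {
    if (is.na(x[h])) {
      out[h] <- NA_integer_
      next
    }
    r <- scan_back(h, function(v) v < 0.5)
    r3 <- scan_back(h, function(v) v < 0.3)
    ra <- scan_back(h, function(v) v == 0)
    out[h] <- if (r3 >= 24 || ra >= 12) 3L else if (r > 12) 2L else
      if (r >= 6 && r <= 12) 1L else 0L
  }
  out
}

# AUC by exhaustive positive-negative pair counting, ties worth one half.
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# random urine sequences mixing regimes (ties, oliguria, anuria, missing)
random_uo_sequence <- function(n) {
  kind <- sample(1:3, 1)
  x <- switch(kind,
              round(runif(n, 0, 1), 2),
              round(runif(n, 0, 0.6), 2),
              round(pmax(rnorm(n, 0.25, 0.3), 0), 2))
  x[runif(n) < 0.08] <- NA
  x
}

# a fully observed control trajectory with constant rates
constant_trajectory <- function(pid = "T01", hours = 48, uo = 70, scr = 1.0,
                                ibw = 70) {
  build_trajectory(pid, rep(uo, hours), rep(scr, hours), ibw)
}

small_labels <- function(trajectories, has_event = NULL, onset = NULL,
                         labelable = NULL) {
  n <- length(trajectories)
  tibble::tibble(
    patient_id = names(trajectories),
    has_event = has_event %||% rep(FALSE, n),
    onset_hour = onset %||% rep(NA_integer_, n),
    max_stage = rep(NA_integer_, n),
    uo_criterion_met = has_event %||% rep(FALSE, n),
    scr_criterion_met = has_event %||% rep(FALSE, n),
    labelable = labelable %||% rep(TRUE, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
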