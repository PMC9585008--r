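#' ROC curve by exhaustive threshold sweep
#'
#' Sweeps every unique score (rule: positive when score >= threshold) plus
#' the degenerate all-negative threshold, so the endpoints
#' (sensitivity 1, specificity 0) and (sensitivity 0, specificity 1) are
#' always present. The AUC is the trapezoidal area, which equals the
#' Mann-Whitney concordance probability with ties counted one half.
#'
#' @param scores finite numeric scores (higher = more event-like).
#' @param labels 0/1 labels, both classes present.
#' @return an object of class `roc_curve`: list with `points` (tibble:
#'   threshold, sensitivity, specificity), `auc`, `auc_se`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  y <- as.numeric(labels)
  abort_if(!all(y %in% c(0, 1)), "labels must be 0/1")
  abort_if(anyNA(scores) || any(!is.finite(scores)), "scores must be finite")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  abort_if(n_pos == 0 || n_neg == 0, "both classes must be present")
  thr <- sort(unique(scores))
  pos_at <- tabulate(match(scores[y == 1], thr), nbins = length(thr))
  neg_at <- tabulate(match(scores[y == 0], thr), nbins = length(thr))
  tp <- rev(cumsum(rev(pos_at)))            # positives with score >= thr
  fp <- rev(cumsum(rev(neg_at)))
  sens <- c(tp / n_pos, 0)
  spec <- c(1 - fp / n_neg, 1)
  thr <- c(thr, Inf)
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (head(sens[ord], -1) + tail(sens[ord], -1)) / 2)
  structure(list(points = tibble::tibble(threshold = thr,
                                         sensitivity = sens,
                                         specificity = spec),
                 auc = auc,
                 auc_se = auc_standard_error(auc, n_pos, n_neg),
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.3f (SE %.4f), %d positives / %d negatives, %d thresholds\n",
              x$auc, x$auc_se, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' Hanley-McNeil standard error of an AUC
#'
#' `se = sqrt((A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)) /
#' (n_pos n_neg))` with `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`.
#'
#' @param auc area under the ROC curve, in `[0, 1]`.
#' @param n_pos,n_neg class counts (positive).
#' @return the standard error.
#' @export
auc_standard_error <- function(auc, n_pos, n_neg) {
  abort_if(auc < 0 || auc > 1, "`auc` must lie in [0, 1]")
  abort_if(n_pos <= 0 || n_neg <= 0, "class counts must be positive")
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Positive and negative likelihood ratios
#'
#' `LR+ = sensitivity / (1 - specificity)` (infinite at specificity 1) and
#' `LR- = (1 - sensitivity) / specificity` (infinite at specificity 0).
#' Values are returned unrounded; report rendering rounds to two decimals.
#'
#' @param sensitivity,specificity fractions in `[0, 1]`.
#' @return list with `lr_pos` and `lr_neg` (possibly `Inf`).
#' @export
likelihood_ratios <- function(sensitivity, specificity) {
  abort_if(sensitivity < 0 || sensitivity > 1 ||
             specificity < 0 || specificity > 1,
           "sensitivity and specificity must lie in [0, 1]")
  lr_pos <- if (specificity == 1) Inf else sensitivity / (1 - specificity)
  lr_neg <- if (specificity == 0) Inf else (1 - sensitivity) / specificity
  list(lr_pos = lr_pos, lr_neg = lr_neg)
}

new_operating_point <- function(roc, i, rule) {
  pt <- roc$points[i, ]
  lr <- likelihood_ratios(pt$sensitivity, pt$specificity)
  structure(list(threshold = pt$threshold,
                 sensitivity = pt$sensitivity,
                 specificity = pt$specificity,
                 lr_pos = lr$lr_pos, lr_neg = lr$lr_neg,
                 selection_rule = rule),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("<operating_point> %s: thr %.4g, sens %.1f%%, spec %.1f%%, LR+ %.2f, LR- %.2f\n",
              x$selection_rule, x$threshold, 100 * x$sensitivity,
              100 * x$specificity, x$lr_pos, x$lr_neg))
  invisible(x)
}

#' Operating point at a fixed sensitivity
#'
#' Among thresholds attaining at least the target sensitivity, picks the
#' one maximising specificity; ties break toward the higher threshold.
#'
#' @param roc a [roc_curve()].
#' @param target minimal sensitivity (default 0.80).
#' @return an `operating_point`.
#' @export
operating_point_fixed_sensitivity <- function(roc, target = 0.80) {
  ok <- which(roc$points$sensitivity >= target)
  abort_if(!length(ok), sprintf("no threshold attains sensitivity %.2f", target))
  spec <- roc$points$specificity[ok]
  best <- ok[spec == max(spec)]
  i <- best[which.max(roc$points$threshold[best])]
  new_operating_point(roc, i, "fixed_sensitivity_80")
}

#' Knee-point of a ROC curve
#'
#' The threshold closest (Euclidean distance in ROC space) to the ideal
#' corner of perfect sensitivity and specificity; ties break toward higher
#' sensitivity. Youden's J (sensitivity + specificity - 1) is available as
#' an alternative selection rule.
#'
#' @param roc a [roc_curve()].
#' @param method `"distance"` (default) or `"youden"`.
#' @return an `operating_point`.
#' @export
knee_point <- function(roc, method = c("distance", "youden")) {
  method <- match.arg(method)
  s <- roc$points$sensitivity; p <- roc$points$specificity
  crit <- if (method == "distance") -sqrt((1 - s)^2 + (1 - p)^2) else s + p - 1
  best <- which(crit == max(crit))
  i <- best[which.max(s[best])]
  new_operating_point(roc, i, "knee_point")
}

#' Aggregate window scores to one score per patient
#'
#' Alert-style semantics: by default a patient's score is the maximum over
#' their windows (an alert fires if any window crosses the threshold); mean
#' aggregation is available as an option. Patients with no windows are
#' omitted (they are reported by [build_window_set()]).
#'
#' @param scores window-level scores.
#' @param patient_id patient id per window.
#' @param agg `"max"` (default) or `"mean"`.
#' @return tibble with `patient_id` and `score`.
#' @export
patient_level_scores <- function(scores, patient_id, agg = c("max", "mean")) {
  agg <- match.arg(agg)
  abort_if(length(scores) != length(patient_id),
           "scores and patient ids must align")
  f <- if (agg == "max") max else mean
  s <- tapply(scores, patient_id, f)
  tibble::tibble(patient_id = names(s), score = as.numeric(s))
}
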