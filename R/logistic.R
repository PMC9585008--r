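standardise_fit <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(center = center, scale = scale)
}

standardise_apply <- function(X, norm) {
  sweep(sweep(X, 2, norm$center), 2, norm$scale, "/")
}

# ridge-penalised IRLS for the rare perfectly-separated case; the penalty
# (1e-6 on standardised slopes, none on the intercept) only regularises
# the diverging directions
ridge_logistic_irls <- function(X1, y, lambda = 1e-6, tol = 1e-8,
                                maxit = 100) {
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1)))
  beta <- rep(0, p)
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X1 * w)
    beta <- drop(solve(XtW %*% X1 + pen, XtW %*% z))
    mu2 <- plogis(drop(X1 %*% beta))
    ll <- sum(y * log(pmax(mu2, 1e-15)) + (1 - y) * log(pmax(1 - mu2, 1e-15))) -
      lambda / 2 * sum(beta[-1]^2)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  beta
}

#' Fit the multi-feature logistic model
#'
#' Maximum-likelihood logistic regression (binomial IRLS, convergence when
#' the deviance change falls below 1e-8 or after 100 iterations) on
#' standardised features; the standardisation constants are stored and
#' re-applied identically at prediction time. Perfect separation triggers a
#' warning and a refit with a tiny L2 penalty (1e-6) so coefficients stay
#' finite.
#'
#' @param features tibble/data.frame of numeric features
#'   ([extract_features()]).
#' @param labels 0/1 vector, both classes present.
#' @return an object of class `uo_logistic`.
#' @export
fit_logistic_model <- function(features, labels) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  abort_if(!all(y %in% c(0, 1)), "labels must be 0/1")
  abort_if(length(unique(y)) < 2, "both classes must be present to fit")
  abort_if(nrow(X) != length(y), "features and labels must align")
  norm <- standardise_fit(X)
  Xs <- standardise_apply(X, norm)
  X1 <- cbind(`(Intercept)` = 1, Xs)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm.fit(X1, y, family = binomial(),
            control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  # glm can diverge quietly when the deviance plateaus before it warns:
  # fitted values indistinguishable from 0/1 mean the MLE is at infinity
  sep <- sep || any(fit$fitted.values < 1e-8) ||
    any(fit$fitted.values > 1 - 1e-8)
  beta <- coef(fit)
  if (sep || !fit$converged || anyNA(beta)) {
    warning("(quasi-)separation detected; refitting with L2 penalty 1e-6",
            call. = FALSE)
    beta <- ridge_logistic_irls(X1, y)
    names(beta) <- colnames(X1)
  }
  structure(list(coefficients = beta, norm = norm,
                 feature_names = colnames(X),
                 separation_penalised = sep),
            class = "uo_logistic")
}

#' Predict window-level event probabilities from a logistic model
#'
#' @param object a fitted `uo_logistic`.
#' @param newdata feature tibble with the training columns.
#' @param ... unused.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict.uo_logistic <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  abort_if(ncol(X) != length(object$feature_names),
           "feature/coefficient mismatch")
  Xs <- standardise_apply(X, object$norm)
  plogis(drop(cbind(1, Xs) %*% object$coefficients))
}

#' @export
print.uo_logistic <- function(x, ...) {
  cat("<uo_logistic> multi-feature logistic model\n")
  print(round(x$coefficients, 4))
  invisible(x)
}
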