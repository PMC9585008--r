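#' Specification of the parallel-branch 1D convolutional network
#'
#' The network reads the raw 12-value hourly urine-output window through
#' parallel 1D convolution branches with kernel sizes 3, 6 and 12 — short,
#' medium and whole-window temporal patterns — each with a small filter
#' bank. Branch pre-activations are global-max-pooled over positions,
#' passed through a ReLU, concatenated, fed to one ReLU hidden layer and a
#' sigmoid output. Training is full-batch Adam on class-weighted binary
#' cross-entropy (weights inversely proportional to class frequency), with
#' early stopping on a patient-level validation split. The parameter count
#' (a few hundred) keeps CPU training to minutes at cohort scale.
#'
#' @param kernels integer kernel sizes of the parallel branches.
#' @param filters filters per branch.
#' @param hidden hidden dense units.
#' @param epochs maximum training epochs.
#' @param lr Adam learning rate.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param val_frac fraction of patients held out for early stopping.
#' @param min_positive minimum number of positive windows required to fit.
#' @param seed integer seed for initialisation and the validation split.
#' @return an object of class `convnet_spec`.
#' @export
convnet_spec <- function(kernels = c(3, 6, 12), filters = 8, hidden = 16,
                         epochs = 300, lr = 0.01, patience = 50,
                         val_frac = 0.15, min_positive = 50, seed = 42L) {
  abort_if(any(kernels < 1) || any(kernels > 12),
           "kernel sizes must lie in [1, 12]")
  structure(list(kernels = as.integer(kernels), filters = as.integer(filters),
                 hidden = as.integer(hidden), epochs = as.integer(epochs),
                 lr = lr, patience = as.integer(patience),
                 val_frac = val_frac, min_positive = as.integer(min_positive),
                 seed = as.integer(seed)),
            class = "convnet_spec")
}

cn_init_params <- function(spec, window_h) {
  W <- lapply(spec$kernels, function(k)
    matrix(rnorm(k * spec$filters, 0, sqrt(2 / k)), k, spec$filters))
  b <- lapply(spec$kernels, function(k) rep(0, spec$filters))
  n_cat <- length(spec$kernels) * spec$filters
  list(W = W, b = b,
       U = matrix(rnorm(n_cat * spec$hidden, 0, sqrt(2 / n_cat)),
                  n_cat, spec$hidden),
       c = rep(0, spec$hidden),
       v = matrix(rnorm(spec$hidden, 0, sqrt(2 / spec$hidden)), spec$hidden, 1),
       d = 0)
}

# forward pass; keep = TRUE retains intermediates for backprop
cn_forward <- function(Xs, par, spec, keep = FALSE) {
  N <- nrow(Xs)
  window_h <- ncol(Xs)
  branches <- vector("list", length(spec$kernels))
  H <- NULL
  for (bi in seq_along(spec$kernels)) {
    k <- spec$kernels[bi]
    P <- window_h - k + 1
    M <- NULL; idx <- NULL
    for (p in seq_len(P)) {
      A <- Xs[, p:(p + k - 1), drop = FALSE] %*% par$W[[bi]]
      A <- sweep(A, 2, par$b[[bi]], "+")
      if (is.null(M)) {
        M <- A; idx <- matrix(1L, N, spec$filters)
      } else {
        upd <- A > M
        M[upd] <- A[upd]
        idx[upd] <- p
      }
    }
    branches[[bi]] <- list(M = M, idx = idx, P = P, k = k)
    H <- cbind(H, pmax(M, 0))       # max-pool then ReLU (order commutes)
  }
  Gpre <- sweep(H %*% par$U, 2, par$c, "+")
  G <- pmax(Gpre, 0)
  z <- drop(G %*% par$v) + par$d
  prob <- plogis(z)
  if (!keep) return(prob)
  list(prob = prob, z = z, G = G, H = H, branches = branches, Xs = Xs)
}

cn_weighted_bce <- function(prob, y, w) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  mean(w * (-y * log(p) - (1 - y) * log(1 - p)))
}

cn_backward <- function(fw, y, w, par, spec) {
  N <- length(y)
  dz <- matrix(w * (fw$prob - y) / N, ncol = 1)
  g <- list()
  g$v <- t(fw$G) %*% dz
  g$d <- sum(dz)
  dG <- (dz %*% t(par$v)) * (fw$G > 0)
  g$U <- t(fw$H) %*% dG
  g$c <- colSums(dG)
  dH <- dG %*% t(par$U)
  g$W <- vector("list", length(spec$kernels))
  g$b <- vector("list", length(spec$kernels))
  col0 <- 0
  for (bi in seq_along(spec$kernels)) {
    br <- fw$branches[[bi]]
    cols <- col0 + seq_len(spec$filters)
    dM <- dH[, cols, drop = FALSE] * (br$M > 0)
    dW <- matrix(0, br$k, spec$filters)
    db <- rep(0, spec$filters)
    for (p in seq_len(br$P)) {
      dZp <- dM * (br$idx == p)
      dW <- dW + t(fw$Xs[, p:(p + br$k - 1), drop = FALSE]) %*% dZp
      db <- db + colSums(dZp)
    }
    g$W[[bi]] <- dW
    g$b[[bi]] <- db
    col0 <- col0 + spec$filters
  }
  g
}

# flatten/unflatten parameters for the Adam update
cn_flatten <- function(par) {
  unlist(list(par$W, par$b, par$U, par$c, par$v, par$d), use.names = FALSE)
}

cn_unflatten <- function(theta, template) {
  out <- template
  pos <- 0
  take <- function(n) {
    v <- theta[pos + seq_len(n)]
    pos <<- pos + n
    v
  }
  out$W <- lapply(template$W, function(w)
    matrix(take(length(w)), nrow(w), ncol(w)))
  out$b <- lapply(template$b, function(b) take(length(b)))
  out$U <- matrix(take(length(template$U)), nrow(template$U), ncol(template$U))
  out$c <- take(length(template$c))
  out$v <- matrix(take(length(template$v)), nrow(template$v), 1)
  out$d <- take(1)
  out
}

#' Train the 1D convolutional early-warning network
#'
#' Fits the [convnet_spec()] architecture to window-level urine-output
#' sequences with class-weighted binary cross-entropy, full-batch Adam and
#' early stopping on a patient-level validation split (no patient's windows
#' appear on both sides). A fixed seed makes the run reproducible on a
#' single CPU thread.
#'
#' @param x numeric matrix, one row per window (ml/h/kg values, oldest
#'   column first).
#' @param y 0/1 labels.
#' @param patient_id character vector assigning windows to patients (for
#'   the validation split).
#' @param spec a [convnet_spec()].
#' @return an object of class `uo_convnet`.
#' @export
fit_convnet <- function(x, y, patient_id, spec = convnet_spec()) {
  X <- as.matrix(x)
  y <- as.numeric(y)
  abort_if(!all(y %in% c(0, 1)), "labels must be 0/1")
  abort_if(length(unique(y)) < 2, "both classes must be present to fit")
  abort_if(nrow(X) != length(y) || length(patient_id) != length(y),
           "x, y and patient_id must align")
  n_pos <- sum(y == 1)
  abort_if(n_pos < spec$min_positive,
           sprintf(paste0("only %d positive windows (< %d): increase the ",
                          "cohort size or event prevalence"),
                   n_pos, spec$min_positive))
  set.seed(spec$seed)

  # patient-level validation split, stratified by patient-level outcome
  pos_pat <- unique(patient_id[y == 1])
  pats <- unique(patient_id)
  neg_pat <- setdiff(pats, pos_pat)
  take <- function(v, frac) {
    if (!length(v)) return(character())
    sample(sort(v), max(1, round(length(v) * frac)))
  }
  val_pat <- c(take(pos_pat, spec$val_frac), take(neg_pat, spec$val_frac))
  in_val <- patient_id %in% val_pat

  m <- mean(X[!in_val, ]); s <- sd(X[!in_val, ])
  if (!is.finite(s) || s < 1e-12) s <- 1
  Xs_tr <- (X[!in_val, , drop = FALSE] - m) / s
  Xs_va <- (X[in_val, , drop = FALSE] - m) / s
  y_tr <- y[!in_val]; y_va <- y[in_val]
  cw <- function(yy) {
    w1 <- length(yy) / (2 * max(sum(yy == 1), 1))
    w0 <- length(yy) / (2 * max(sum(yy == 0), 1))
    ifelse(yy == 1, w1, w0)
  }
  w_tr <- cw(y_tr); w_va <- cw(y_va)

  par <- cn_init_params(spec, ncol(X))
  theta <- cn_flatten(par)
  m1 <- v1 <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  history <- numeric(0)
  wait <- 0L
  for (ep in seq_len(spec$epochs)) {
    par <- cn_unflatten(theta, par)
    fw <- cn_forward(Xs_tr, par, spec, keep = TRUE)
    g <- cn_backward(fw, y_tr, w_tr, par, spec)
    gth <- cn_flatten(g)
    m1 <- b1 * m1 + (1 - b1) * gth
    v1 <- b2 * v1 + (1 - b2) * gth^2
    mh <- m1 / (1 - b1^ep); vh <- v1 / (1 - b2^ep)
    theta <- theta - spec$lr * mh / (sqrt(vh) + eps)
    par_new <- cn_unflatten(theta, par)
    val_loss <- cn_weighted_bce(cn_forward(Xs_va, par_new, spec), y_va, w_va)
    history <- c(history, val_loss)
    if (val_loss < best$loss - 1e-6) {
      best <- list(loss = val_loss, theta = theta, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= spec$patience) break
    }
  }
  par <- cn_unflatten(best$theta, par)
  structure(list(spec = spec, params = par,
                 norm = list(center = m, scale = s),
                 window_h = ncol(X),
                 val_loss = best$loss, best_epoch = best$epoch,
                 epochs_run = length(history), history = history),
            class = "uo_convnet")
}

#' Predict window-level event probabilities from the conv net
#'
#' A pure function of the stored weights and the input window(s); batch
#' prediction equals per-window prediction.
#'
#' @param object a fitted `uo_convnet`.
#' @param newdata numeric matrix (or single vector) of windows.
#' @param ... unused.
#' @return numeric vector of probabilities strictly inside (0, 1).
#' @export
predict.uo_convnet <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  abort_if(ncol(X) != object$window_h,
           sprintf("window length %d does not match the trained length %d",
                   ncol(X), object$window_h))
  Xs <- (X - object$norm$center) / object$norm$scale
  p <- cn_forward(Xs, object$params, object$spec)
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' @export
print.uo_convnet <- function(x, ...) {
  cat(sprintf(paste0("<uo_convnet> kernels {%s} x %d filters, %d hidden; ",
                     "best epoch %d/%d (val loss %.4f)\n"),
              paste(x$spec$kernels, collapse = ","), x$spec$filters,
              x$spec$hidden, x$best_epoch, x$epochs_run, x$val_loss))
  invisible(x)
}
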