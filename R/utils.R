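#' Round half away from zero
#'
#' Base `round()` rounds half to even; clinical tables are conventionally
#' printed with halves rounded away from zero (0.225 -> 0.23). Used for all
#' two-decimal report cells.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derive per-stage seeds from one global seed
#'
#' Fans a single integer seed out to named per-stage seeds so each pipeline
#' stage is independently reproducible. The derivation is a fixed draw of
#' integers under the global seed; all results stay below 2^31.
#'
#' @param seed integer global seed.
#' @param stages character vector of stage names.
#' @return named integer vector of seeds.
#' @export
derive_seeds <- function(seed, stages) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  setNames(sample.int(.Machine$integer.max - 1L, length(stages)), stages)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
  invisible(TRUE)
}
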