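mat_to_list <- function(m) list(dim = dim(m), data = as.numeric(m))
list_to_mat <- function(l) matrix(unlist(l$data), unlist(l$dim)[1], unlist(l$dim)[2])

#' Save a fitted model to a portable JSON file
#'
#' Serialises weights, architecture/feature metadata and standardisation
#' constants (versioned) so a model can be reloaded and applied elsewhere
#' without R-specific binary formats.
#'
#' @param model a `uo_logistic` or `uo_convnet`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "uo_logistic")) {
    payload <- list(format = "oliguard-model", version = 1L,
                    type = "uo_logistic",
                    coefficients = as.list(model$coefficients),
                    norm = lapply(model$norm, as.list),
                    feature_names = model$feature_names)
  } else if (inherits(model, "uo_convnet")) {
    payload <- list(format = "oliguard-model", version = 1L,
                    type = "uo_convnet",
                    spec = unclass(model$spec),
                    norm = model$norm,
                    window_h = model$window_h,
                    params = list(W = lapply(model$params$W, mat_to_list),
                                  b = model$params$b,
                                  U = mat_to_list(model$params$U),
                                  c = model$params$c,
                                  v = mat_to_list(model$params$v),
                                  d = model$params$d))
  } else {
    stop("unsupported model class", call. = FALSE)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model written by [write_model()]
#'
#' @param path path to a model JSON file.
#' @return the reconstructed model object.
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path)
  abort_if(!identical(p$format, "oliguard-model"), "not an oliguard model file")
  if (p$type == "uo_logistic") {
    structure(list(coefficients = unlist(p$coefficients),
                   norm = list(center = unlist(p$norm$center),
                               scale = unlist(p$norm$scale)),
                   feature_names = unlist(p$feature_names),
                   separation_penalised = FALSE),
              class = "uo_logistic")
  } else if (p$type == "uo_convnet") {
    spec_args <- lapply(p$spec[names(p$spec) %in%
                                 names(formals(convnet_spec))], unlist)
    spec <- do.call(convnet_spec, spec_args)
    structure(list(spec = spec,
                   params = list(W = lapply(p$params$W, list_to_mat),
                                 b = lapply(p$params$b, unlist),
                                 U = list_to_mat(p$params$U),
                                 c = unlist(p$params$c),
                                 v = list_to_mat(p$params$v),
                                 d = unlist(p$params$d)),
                   norm = list(center = unlist(p$norm$center),
                               scale = unlist(p$norm$scale)),
                   window_h = p$window_h,
                   val_loss = NA_real_, best_epoch = NA_integer_,
                   epochs_run = NA_integer_, history = numeric()),
              class = "uo_convnet")
  } else {
    stop("unknown model type: ", p$type, call. = FALSE)
  }
}
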