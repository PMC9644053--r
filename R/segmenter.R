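#' Segmenter contract
#'
#' Acquisition queries are decoupled from any particular network through a
#' small S3 contract. A segmenter is any object implementing:
#'
#' * `seg_train(model, labeled, validation, config)` -> fitted model
#' * `seg_predict(model, samples)` -> named list of `H x W x 2` probability
#'   arrays (sigmoid channels: femur, acetabulum), values in `[0, 1]`
#' * `seg_predict_stochastic(model, samples, k, seed)` -> [predictive_ensemble]
#' * `seg_supports_dropout(model)` -> logical
#' * `seg_is_trained(model)` -> logical
#'
#' With dropout disabled (or unsupported), `seg_predict_stochastic` must
#' return `k` identical passes.
#'
#' @param model a segmenter object.
#' @param labeled,validation,samples lists of [image_sample] objects.
#' @param config a [training_config].
#' @param k number of stochastic forward passes.
#' @param seed integer seed making the passes reproducible.
#' @name segmenter-contract
NULL

#' @rdname segmenter-contract
#' @export
seg_train <- function(model, labeled, validation, config) UseMethod("seg_train")

#' @rdname segmenter-contract
#' @export
seg_predict <- function(model, samples) UseMethod("seg_predict")

#' @rdname segmenter-contract
#' @export
seg_predict_stochastic <- function(model, samples, k = 30L, seed = 1L) {
  UseMethod("seg_predict_stochastic")
}

#' @rdname segmenter-contract
#' @export
seg_supports_dropout <- function(model) UseMethod("seg_supports_dropout")

#' @rdname segmenter-contract
#' @export
seg_is_trained <- function(model) UseMethod("seg_is_trained")

#' Bundle of stochastic forward passes
#'
#' Houses the Monte Carlo Dropout predictive distribution: `k` stochastic
#' passes over the same samples.
#'
#' @param passes list of length `k`; each element a named list (by sample id)
#'   of `H x W x 2` probability arrays.
#' @param k pass count (`>= 1`).
#' @param seed seed the passes were drawn under.
#' @return an object of class `predictive_ensemble`.
#' @export
predictive_ensemble <- function(passes, k = length(passes), seed = NA_integer_) {
  if (k < 1 || length(passes) != k) stopf("ensemble needs k >= 1 passes")
  for (p in passes) {
    for (a in p) {
      if (any(!is.finite(a)) || any(a < 0 | a > 1)) {
        stopf("ensemble probabilities must lie in [0, 1]")
      }
    }
  }
  structure(list(passes = passes, k = as.integer(k), seed = seed),
            class = "predictive_ensemble")
}

#' @export
print.predictive_ensemble <- function(x, ...) {
  cat(sprintf("<predictive_ensemble> k=%d passes over %d samples\n",
              x$k, length(x$passes[[1]])))
  invisible(x)
}

#' Constant-output stub segmenter
#'
#' A trivial segmenter emitting, for every pixel of a sample, a constant
#' probability looked up per id (with a fallback default). Used to exercise
#' the AL loop and the score-based queries without any training cost, and to
#' check entropy orderings against closed forms.
#'
#' @param probs named numeric vector: per-id constant probability (applied to
#'   both output channels), or a single unnamed value used for every sample.
#' @param default fallback probability for ids absent from `probs`.
#' @param supports_dropout whether the stub advertises dropout layers
#'   (its stochastic passes are identical either way).
#' @return an untrained segmenter of class `constant_segmenter`.
#' @export
constant_segmenter <- function(probs = 0.5, default = 0.5,
                               supports_dropout = TRUE) {
  structure(list(probs = probs, default = default,
                 supports_dropout = supports_dropout, trained = FALSE),
            class = "constant_segmenter")
}

#' @export
seg_train.constant_segmenter <- function(model, labeled, validation, config) {
  model$trained <- TRUE
  model
}

#' @export
seg_predict.constant_segmenter <- function(model, samples) {
  out <- lapply(samples, function(s) {
    p <- if (!is.null(names(model$probs)) && s$id %in% names(model$probs)) {
      unname(model$probs[[s$id]])
    } else if (is.null(names(model$probs))) {
      model$probs[[1]]
    } else {
      model$default
    }
    array(p, dim = c(dim(s$pixels), 2L))
  })
  names(out) <- sample_ids(samples)
  out
}

#' @export
seg_predict_stochastic.constant_segmenter <- function(model, samples, k = 30L,
                                                      seed = 1L) {
  one <- seg_predict(model, samples)
  predictive_ensemble(rep(list(one), k), k = as.integer(k), seed = seed)
}

#' @export
seg_supports_dropout.constant_segmenter <- function(model) {
  isTRUE(model$supports_dropout)
}

#' @export
seg_is_trained.constant_segmenter <- function(model) isTRUE(model$trained)
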