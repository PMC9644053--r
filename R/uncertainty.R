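#' Monte Carlo Dropout ensemble
#'
#' Runs `k` stochastic forward passes with dropout active at inference time.
#' Each dropout configuration is one Monte Carlo sample from the space of
#' thinned networks, so the stack of passes approximates the model's
#' predictive distribution.
#'
#' @param model a trained segmenter with dropout support (see
#'   [segmenter-contract]).
#' @param samples list of [image_sample] objects.
#' @param k number of passes (default 30).
#' @param seed integer seed; the same seed reproduces the ensemble exactly.
#' @return a [predictive_ensemble].
#' @export
mc_ensemble <- function(model, samples, k = 30L, seed = 1L) {
  if (!seg_supports_dropout(model)) {
    stopf(paste("Monte Carlo Dropout requires a model with dropout layers;",
                "this segmenter reports supports_dropout = FALSE"))
  }
  if (k < 1) stopf("k must be >= 1")
  seg_predict_stochastic(model, samples, k = as.integer(k), seed = seed)
}

#' Average prediction of an ensemble
#'
#' Elementwise arithmetic mean of the `k` stochastic passes, per sample and
#' per output channel.
#'
#' @param ensemble a [predictive_ensemble].
#' @return an object of class `mean_prediction`: list with `maps` (named list
#'   of `H x W x 2` arrays) and `k_used`.
#' @export
mean_prediction <- function(ensemble) {
  stopifnot(inherits(ensemble, "predictive_ensemble"))
  ids <- names(ensemble$passes[[1]])
  maps <- lapply(ids, function(id) {
    acc <- ensemble$passes[[1]][[id]]
    if (ensemble$k > 1) {
      for (i in 2:ensemble$k) acc <- acc + ensemble$passes[[i]][[id]]
    }
    acc / ensemble$k
  })
  names(maps) <- ids
  structure(list(maps = maps, k_used = ensemble$k), class = "mean_prediction")
}

# -p * log2(p) with the continuity convention 0 * log2(0) = 0
plog2p <- function(p) ifelse(p > 0, -p * log2(p), 0)

#' Class-wise Shannon entropy scores
#'
#' Scores each sample's predictive uncertainty: for each of the two sigmoid
#' foreground channels (femur, acetabulum) the per-pixel entropy term is
#' averaged over all `H x W` pixels, and the two channel values are then
#' averaged.
#'
#' Two variants are available. The default, `"literal"`, uses the single-term
#' form `-p log2 p`, finite on all of `[0, 1]`. The `"binary"` variant uses
#' the full two-outcome Shannon entropy
#' `-p log2 p - (1 - p) log2(1 - p)` (probabilities clipped to
#' `[1e-7, 1 - 1e-7]` before the logs). Both are maximal for maximally
#' ambiguous predictions and zero exactly when every pixel probability is 0
#' or 1.
#'
#' @param pred a `mean_prediction`, a named list of `H x W x 2` probability
#'   arrays, or a single such array.
#' @param variant `"literal"` (default) or `"binary"`.
#' @param keep_maps if `TRUE`, retain per-class per-pixel entropy maps for
#'   inspection.
#' @return an object of class `entropy_scores`: list with `scores` (named
#'   numeric, one value per sample), `variant`, and optionally `maps`.
#' @export
class_wise_entropy <- function(pred, variant = c("literal", "binary"),
                               keep_maps = FALSE) {
  variant <- match.arg(variant)
  maps <- if (inherits(pred, "mean_prediction")) {
    pred$maps
  } else if (is.array(pred) && length(dim(pred)) == 3L) {
    list(sample = pred)
  } else {
    pred
  }
  ent_maps <- lapply(maps, function(a) {
    if (any(!is.finite(a))) stopf("non-finite probabilities in prediction map")
    if (any(a < 0 | a > 1)) stopf("probabilities must lie in [0, 1]")
    if (variant == "literal") {
      plog2p(a)
    } else {
      p <- clip01(a)
      -p * log2(p) - (1 - p) * log2(1 - p)
    }
  })
  scores <- vapply(ent_maps, function(e) {
    per_class <- apply(e, 3, mean)
    mean(per_class)
  }, numeric(1))
  out <- list(scores = scores, variant = variant)
  if (keep_maps) out$maps <- ent_maps
  structure(out, class = "entropy_scores")
}

#' @export
print.entropy_scores <- function(x, ...) {
  cat(sprintf("<entropy_scores> %d samples (%s), range [%.4f, %.4f]\n",
              length(x$scores), x$variant, min(x$scores), max(x$scores)))
  invisible(x)
}
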