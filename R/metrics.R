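as_channel_array <- function(x) {
  if (inherits(x, "mask_stack")) return(mask_foreground(x))
  if (is.matrix(x)) return(array(x, dim = c(dim(x), 1L)))
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stopf("expected a matrix, H x W x C array, or mask_stack")
}

#' Dice overlap score
#'
#' The standard medical-segmentation overlap metric
#' `Dice(P, G) = 2|G n P| / (|G| + |P|)`, computed per foreground class on
#' predictions binarized at a threshold, plus the macro average over classes
#' and the joint (stacked-channel) dice. A class empty in both prediction and
#' ground truth scores 1 (an empty prediction of an absent structure is
#' perfect, and this avoids `0/0`).
#'
#' @param pred predicted probabilities or binary mask: `H x W x C` array
#'   (foreground channels), matrix (single class), or `mask_stack`
#'   (foreground channels are used).
#' @param truth ground truth in the same shape; must be binary.
#' @param threshold binarization threshold applied to `pred` (default 0.5).
#' @param class_names labels for the foreground channels.
#' @return an object of class `dice_report`: list with `per_class` (named),
#'   `macro` (mean over classes), `joint` (stacked channels) and `threshold`.
#' @examples
#' g <- matrix(c(1, 1, 0, 0), 2, 2)
#' dice_score(g, g)$macro  # 1
#' @export
dice_score <- function(pred, truth, threshold = 0.5,
                       class_names = c("femur", "acetabulum")) {
  p <- as_channel_array(pred)
  g <- as_channel_array(truth)
  if (!identical(dim(p), dim(g))) {
    stopf("shape mismatch: pred %s vs truth %s",
          paste(dim(p), collapse = "x"), paste(dim(g), collapse = "x"))
  }
  if (!is_binary(g)) stopf("ground truth mask must be binary")
  pb <- (p >= threshold) * 1
  nc <- dim(p)[3]
  per_class <- vapply(seq_len(nc), function(c) {
    P <- pb[, , c]; G <- g[, , c]
    denom <- sum(P) + sum(G)
    if (denom == 0) 1 else 2 * sum(P * G) / denom
  }, numeric(1))
  names(per_class) <- if (nc == length(class_names)) class_names else
    paste0("class", seq_len(nc))
  denom_all <- sum(pb) + sum(g)
  joint <- if (denom_all == 0) 1 else 2 * sum(pb * g) / denom_all
  structure(list(per_class = per_class, macro = mean(per_class),
                 joint = joint, threshold = threshold),
            class = "dice_report")
}

#' @export
print.dice_report <- function(x, ...) {
  cat(sprintf("<dice_report> macro %.4f (joint %.4f) at threshold %.2f\n",
              x$macro, x$joint, x$threshold))
  for (nm in names(x$per_class)) cat(sprintf("  %s: %.4f\n", nm, x$per_class[nm]))
  invisible(x)
}

#' Combined dice + focal training loss
#'
#' The training objective: a soft-dice term `1 - 2 sum(PG) / (sum(P) + sum(G))`
#' (per foreground channel, averaged over channels) plus a focal term
#' `alpha * (1 - p_t)^gamma * (-log p_t)` averaged over pixels and channels,
#' where `p_t = P` where `G = 1` and `p_t = 1 - P` where `G = 0`. Natural
#' logarithm, probabilities clipped to `[1e-7, 1 - 1e-7]`. The loss is
#' non-negative and tends to 0 as confident predictions approach the mask.
#'
#' @param pred predicted probabilities (`H x W x C` array or matrix).
#' @param truth binary ground truth, same shape.
#' @param alpha focal weighting factor in `[0, 1]` (default 0.25).
#' @param gamma focusing exponent `>= 0` (default 2); larger values
#'   down-weight easy pixels more strongly.
#' @return scalar loss value.
#' @export
dice_focal_loss <- function(pred, truth, alpha = 0.25, gamma = 2) {
  if (alpha < 0 || alpha > 1) stopf("alpha must lie in [0, 1]")
  if (gamma < 0) stopf("gamma must be >= 0")
  p <- as_channel_array(pred)
  g <- as_channel_array(truth)
  if (!identical(dim(p), dim(g))) {
    stopf("shape mismatch: pred %s vs truth %s",
          paste(dim(p), collapse = "x"), paste(dim(g), collapse = "x"))
  }
  if (!is_binary(g)) stopf("ground truth mask must be binary")
  p <- clip01(p)
  nc <- dim(p)[3]
  dice_term <- mean(vapply(seq_len(nc), function(c) {
    P <- p[, , c]; G <- g[, , c]
    1 - 2 * sum(P * G) / (sum(P) + sum(G))
  }, numeric(1)))
  pt <- ifelse(g == 1, p, 1 - p)
  focal <- mean(alpha * (1 - pt)^gamma * (-log(pt)))
  dice_term + focal
}
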