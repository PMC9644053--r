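#' Resize a grayscale image
#'
#' @param pixels `H x W` numeric matrix.
#' @param target `c(H, W)` output size.
#' @param method `"bilinear"` (images) or `"nearest"` (label masks; output
#'   values are always a subset of the input values).
#' @return resized matrix.
#' @export
resize_image <- function(pixels, target, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  target <- as.integer(target)
  if (length(target) != 2L || any(target < 1L)) {
    stopf("target size must be two positive integers")
  }
  if (identical(dim(pixels), target)) return(pixels)
  out <- EBImage::resize(pixels, w = target[1], h = target[2],
                         filter = if (method == "bilinear") "bilinear" else "none")
  matrix(as.numeric(out), target[1], target[2])
}

#' Resize an image together with its mask
#'
#' The image is resampled with bilinear interpolation; the mask channels use
#' nearest-neighbor interpolation so they remain strictly binary.
#'
#' @param image `H x W` numeric matrix.
#' @param mask a [mask_stack].
#' @param target `c(H, W)` output size (default `c(544, 448)`, the working
#'   resolution for full-size radiographs).
#' @return list with resized `image` (clipped to `[0, 1]`) and `mask`.
#' @export
resize_pair <- function(image, mask, target = c(544L, 448L)) {
  stopifnot(inherits(mask, "mask_stack"))
  img <- pmin(pmax(resize_image(image, target, "bilinear"), 0), 1)
  fem <- resize_image(mask$channels[, , 2], target, "nearest")
  ace <- resize_image(mask$channels[, , 3], target, "nearest")
  list(image = img, mask = mask_stack(fem, ace, mask$class_names))
}
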