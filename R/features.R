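#' Feature matrices for diversity and representativeness queries
#'
#' A feature matrix is an `N x D` numeric matrix with one row per sample id
#' and a provenance tag tracking the pipeline stage: `"raw"` (flattened
#' pixels), `"normalized"` (per-column min-max rescaled to `[0, 1]`) or
#' `"reduced"` (PCA projection).
#'
#' @param rows `N x D` numeric matrix.
#' @param ids ordered sample ids, one per row.
#' @param provenance one of `"raw"`, `"normalized"`, `"reduced"`.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(rows, ids, provenance = "raw") {
  provenance <- match.arg(provenance, c("raw", "normalized", "reduced"))
  rows <- as.matrix(rows)
  if (nrow(rows) != length(ids)) stopf("one row per id required")
  if (any(!is.finite(rows))) stopf("feature matrix contains non-finite entries")
  rownames(rows) <- ids
  structure(list(rows = rows, ids = as.character(ids),
                 provenance = provenance),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d x %d (%s)\n", nrow(x$rows), ncol(x$rows),
              x$provenance))
  invisible(x)
}

#' Flatten images into raw feature rows
#'
#' Each image is optionally resized to a small thumbnail (bilinear) and then
#' flattened row-major into one feature row. Thumbnails keep the subsequent
#' PCA tractable on full-size radiographs; the size is a configuration knob,
#' not part of the method itself.
#'
#' @param samples list of [image_sample] objects.
#' @param thumbnail_size optional `c(H, W)` to resize to before flattening.
#'   Required when input images have mixed dimensions.
#' @return a `feature_matrix` with provenance `"raw"`.
#' @export
flatten_images <- function(samples, thumbnail_size = NULL) {
  if (length(samples) == 0) stopf("no samples to flatten")
  dims <- vapply(samples, function(s) dim(s$pixels), integer(2))
  mixed <- length(unique(dims[1, ])) > 1 || length(unique(dims[2, ])) > 1
  if (mixed && is.null(thumbnail_size)) {
    stopf("mixed image sizes require thumbnail_size")
  }
  rows <- t(vapply(samples, function(s) {
    px <- s$pixels
    if (!is.null(thumbnail_size) &&
        !identical(dim(px), as.integer(thumbnail_size))) {
      px <- resize_image(px, thumbnail_size, method = "bilinear")
    }
    as.vector(t(px))  # row-major flatten
  }, numeric(if (is.null(thumbnail_size)) prod(dims[, 1])
             else prod(thumbnail_size))))
  if (length(samples) == 1L) rows <- matrix(rows, nrow = 1L)
  feature_matrix(rows, sample_ids(samples), "raw")
}

#' Per-column min-max normalization
#'
#' Rescales each feature column to `[0, 1]` by `(x - min) / (max - min)`.
#' Constant columns carry no information and are mapped to all-zero with a
#' warning rather than producing `0/0`.
#'
#' @param features a `feature_matrix` with provenance `"raw"`.
#' @return a `feature_matrix` with provenance `"normalized"`.
#' @export
min_max_normalize <- function(features) {
  stopifnot(inherits(features, "feature_matrix"))
  x <- features$rows
  if (nrow(x) == 0 || ncol(x) == 0) stopf("cannot normalize an empty matrix")
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  rng <- hi - lo
  const <- rng == 0
  if (any(const)) {
    warning(sprintf("%d constant feature column(s) mapped to 0", sum(const)),
            call. = FALSE)
    rng[const] <- 1
  }
  out <- sweep(sweep(x, 2, lo, "-"), 2, rng, "/")
  out[, const] <- 0
  feature_matrix(out, features$ids, "normalized")
}

#' Fit a PCA basis retaining a target fraction of variance
#'
#' Principal component analysis on normalized features, keeping the minimal
#' number of leading components whose cumulative explained-variance ratio
#' reaches `target_variance` (default 99%).
#'
#' @param features a `feature_matrix` with provenance `"normalized"`.
#' @param target_variance fraction of total variance to retain, in `(0, 1]`.
#' @return an object of class `pca_model` with fields `rotation` (`D x d`),
#'   `center`, `var_ratio` (per retained component), `n_components`,
#'   `target_variance`.
#' @export
fit_pca <- function(features, target_variance = 0.99) {
  stopifnot(inherits(features, "feature_matrix"))
  if (features$provenance != "normalized") {
    stopf("fit_pca expects normalized features (got '%s')", features$provenance)
  }
  if (nrow(features$rows) < 2) stopf("PCA needs at least 2 samples")
  if (target_variance <= 0 || target_variance > 1) {
    stopf("target_variance must be in (0, 1]")
  }
  pc <- stats::prcomp(features$rows, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  total <- sum(ev)
  if (total <= .Machine$double.eps) stopf("no informative features (zero variance)")
  ratio <- ev / total
  m <- which(cumsum(ratio) >= target_variance - 1e-12)[1]
  structure(list(rotation = pc$rotation[, seq_len(m), drop = FALSE],
                 center = pc$center,
                 var_ratio = ratio[seq_len(m)],
                 n_components = m,
                 target_variance = target_variance),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components, %.4f cumulative variance ratio\n",
              x$n_components, sum(x$var_ratio)))
  invisible(x)
}

#' Project features onto a fitted PCA basis
#'
#' Mean-centers by the model's column means and projects onto the retained
#' components, yielding the reduced pool used by the cluster-based and
#' representative queries.
#'
#' @param model a `pca_model`.
#' @param features a `feature_matrix` whose column dimension matches the
#'   model's.
#' @return a `feature_matrix` with provenance `"reduced"` (`N x d`).
#' @export
pca_transform <- function(model, features) {
  stopifnot(inherits(model, "pca_model"), inherits(features, "feature_matrix"))
  if (ncol(features$rows) != nrow(model$rotation)) {
    stopf("feature dimension %d does not match PCA model dimension %d",
          ncol(features$rows), nrow(model$rotation))
  }
  centered <- sweep(features$rows, 2, model$center, "-")
  feature_matrix(centered %*% model$rotation, features$ids, "reduced")
}
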