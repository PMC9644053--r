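#' Construct a three-channel binary mask stack
#'
#' Masks hold one binary channel per class in the fixed order background,
#' femur, acetabulum. The femoral head overlaps the acetabulum, so the two
#' foreground channels may overlap; the background channel is defined as the
#' complement of the union of the foreground channels, which makes the whole
#' stack generable from foreground annotations alone.
#'
#' @param femur,acetabulum binary `H x W` matrices (values 0/1) marking each
#'   foreground class.
#' @param class_names channel labels, background first.
#' @return an object of class `mask_stack`: a list with `channels`
#'   (`H x W x 3` binary array) and `class_names`.
#' @export
mask_stack <- function(femur, acetabulum,
                       class_names = c("background", "femur", "acetabulum")) {
  if (!is.matrix(femur) || !is.matrix(acetabulum)) {
    stopf("foreground masks must be matrices")
  }
  if (!identical(dim(femur), dim(acetabulum))) {
    stopf("foreground mask dims differ: %s vs %s",
          paste(dim(femur), collapse = "x"),
          paste(dim(acetabulum), collapse = "x"))
  }
  if (!is_binary(femur) || !is_binary(acetabulum)) {
    stopf("mask channels must be strictly binary (0/1)")
  }
  background <- 1 - pmax(femur, acetabulum)
  channels <- array(c(background, femur, acetabulum),
                    dim = c(dim(femur), 3L))
  structure(list(channels = channels, class_names = class_names),
            class = "mask_stack")
}

#' Validate and wrap a full three-channel mask array
#'
#' @param channels `H x W x 3` binary array in (background, femur, acetabulum)
#'   order. The background channel must equal the complement of the union of
#'   the foreground channels.
#' @inheritParams mask_stack
#' @return a `mask_stack`.
#' @export
as_mask_stack <- function(channels,
                          class_names = c("background", "femur", "acetabulum")) {
  if (length(dim(channels)) != 3L || dim(channels)[3] != 3L) {
    stopf("mask channels must be an H x W x 3 array")
  }
  for (c in 1:3) {
    if (!is_binary(channels[, , c])) {
      stopf("mask channel '%s' is not binary", class_names[c])
    }
  }
  expected_bg <- 1 - pmax(channels[, , 2], channels[, , 3])
  if (!all(channels[, , 1] == expected_bg)) {
    stopf("background channel must be the complement of the foreground union")
  }
  structure(list(channels = channels, class_names = class_names),
            class = "mask_stack")
}

#' Foreground channels of a mask stack
#' @param mask a `mask_stack`.
#' @return `H x W x 2` binary array (femur, acetabulum).
#' @export
mask_foreground <- function(mask) {
  stopifnot(inherits(mask, "mask_stack"))
  mask$channels[, , 2:3, drop = FALSE]
}

#' Construct an image sample
#'
#' One sample corresponds to one patient: a grayscale image with intensities
#' in `[0, 1]` and, when the ground truth is known, a three-channel binary
#' mask aligned to it.
#'
#' @param id unique sample identifier (stable string; selections are always
#'   reported as ids, never positional indices).
#' @param pixels `H x W` numeric matrix with finite values in `[0, 1]`.
#' @param mask optional `mask_stack` with matching spatial dims.
#' @return an object of class `image_sample`.
#' @export
image_sample <- function(id, pixels, mask = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stopf("sample id must be a non-empty string")
  }
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stopf("pixels must be a numeric matrix")
  }
  if (any(!is.finite(pixels))) stopf("pixels contain non-finite values (id '%s')", id)
  if (any(pixels < 0 | pixels > 1)) {
    stopf("pixels must lie in [0, 1] (id '%s')", id)
  }
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "mask_stack"))
    if (!identical(dim(mask$channels)[1:2], dim(pixels))) {
      stopf("mask dims %s do not match image dims %s (id '%s')",
            paste(dim(mask$channels)[1:2], collapse = "x"),
            paste(dim(pixels), collapse = "x"), id)
    }
  }
  structure(list(id = id, pixels = pixels, mask = mask),
            class = "image_sample")
}

#' Ids of a list of samples
#' @param samples list of [image_sample] objects.
#' @return character vector of ids in order.
#' @export
sample_ids <- function(samples) vapply(samples, function(s) s$id, character(1))

#' Build a labeled/unlabeled pool
#'
#' The pool is the central bookkeeping object of the active-learning cycle:
#' an ordered collection of samples partitioned into a labeled set `L` and an
#' unlabeled set `U`. The two partitions are always disjoint.
#'
#' @param samples list of `image_sample` objects with unique ids.
#' @param labeled_ids character vector of ids forming the initial labeled set
#'   `L0`; everything else goes to the unlabeled pool `U0`.
#' @return an object of class `al_pool` with fields `samples` (named list),
#'   `labeled_ids` and `unlabeled_ids` (character vectors in stable order).
#' @examples
#' s <- lapply(1:5, function(i)
#'   image_sample(paste0("s", i), matrix(runif(4), 2, 2)))
#' p <- make_pool(s, labeled_ids = "s1")
#' length(p$unlabeled_ids)  # 4
#' @export
make_pool <- function(samples, labeled_ids = character()) {
  ids <- sample_ids(samples)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stopf("duplicate sample id(s): %s", paste(unique(dup), collapse = ", "))
  }
  unknown <- setdiff(labeled_ids, ids)
  if (length(unknown) > 0) {
    stopf("labeled id(s) not present in samples: %s",
          paste(unknown, collapse = ", "))
  }
  names(samples) <- ids
  structure(list(samples = samples,
                 labeled_ids = ids[ids %in% labeled_ids],
                 unlabeled_ids = ids[!ids %in% labeled_ids]),
            class = "al_pool")
}

#' Move unlabeled samples into the labeled partition
#'
#' Implements the acquisition bookkeeping of one AL iteration:
#' `L_t = L_{t-1} U B` and `U_t = U_{t-1} \\ B` for a selected batch `B`.
#' Total sample count is conserved.
#'
#' @param pool an `al_pool`.
#' @param ids ids currently in the unlabeled partition.
#' @return the updated `al_pool`.
#' @export
move_to_labeled <- function(pool, ids) {
  stopifnot(inherits(pool, "al_pool"))
  ids <- as.character(ids)
  bad <- setdiff(ids, pool$unlabeled_ids)
  if (length(bad) > 0) {
    stopf("id(s) not in the unlabeled partition: %s", paste(bad, collapse = ", "))
  }
  all_ids <- names(pool$samples)
  lab <- c(pool$labeled_ids, ids)
  pool$labeled_ids <- all_ids[all_ids %in% lab]
  pool$unlabeled_ids <- setdiff(pool$unlabeled_ids, ids)
  pool
}

#' Subset pool samples by id
#' @param pool an `al_pool`.
#' @param ids ids to extract.
#' @return named list of [image_sample] objects.
#' @export
pool_samples <- function(pool, ids) pool$samples[ids]

#' @export
print.al_pool <- function(x, ...) {
  cat(sprintf("<al_pool> %d samples: %d labeled, %d unlabeled\n",
              length(x$samples), length(x$labeled_ids),
              length(x$unlabeled_ids)))
  invisible(x)
}

#' @export
print.image_sample <- function(x, ...) {
  cat(sprintf("<image_sample> id '%s', %dx%d, mask: %s\n", x$id,
              nrow(x$pixels), ncol(x$pixels),
              if (is.null(x$mask)) "none" else "3-channel binary"))
  invisible(x)
}

#' Construct a query result
#'
#' @param selected_ids ordered ids chosen by an acquisition query.
#' @param scores optional named per-id score vector.
#' @param elapsed_seconds non-negative wall time of the query.
#' @param query_name registered query name.
#' @return an object of class `query_result`.
#' @export
query_result <- function(selected_ids, scores = NULL, elapsed_seconds = 0,
                         query_name = "") {
  if (anyDuplicated(selected_ids)) stopf("selected ids must be distinct")
  if (elapsed_seconds < 0) stopf("elapsed_seconds must be >= 0")
  structure(list(selected_ids = as.character(selected_ids), scores = scores,
                 elapsed_seconds = as.numeric(elapsed_seconds),
                 query_name = query_name),
            class = "query_result")
}

#' @export
print.query_result <- function(x, ...) {
  cat(sprintf("<query_result> '%s': %d ids in %.3fs\n", x$query_name,
              length(x$selected_ids), x$elapsed_seconds))
  invisible(x)
}
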