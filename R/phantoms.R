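#' Hip-phantom generator parameters
#'
#' The generator emulates the structure of a ventrodorsal hip radiograph
#' around one joint: a bright femoral head (ellipse) partially seated in an
#' acetabular cup (annulus sector, a "crescent") that overlaps the top of
#' the head, with low foreground/background contrast and additive Gaussian
#' noise. Geometry is jittered per patient; jitter ranges are validated so
#' every shape stays fully inside the image.
#'
#' All geometric quantities are fractions of the image size, so the same
#' parameter set renders at test scale (64 x 64 default) or at the full
#' working resolution (544 x 448).
#'
#' @param n number of phantoms ("patients").
#' @param size image size `c(H, W)`.
#' @param contrast foreground/background intensity separation in `(0, 1]`;
#'   the default 0.6 gives the low-contrast regime of joint radiographs.
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units; images are clipped back to `[0, 1]`).
#' @param femur_center center of the femoral head as fractions of `(H, W)`.
#' @param femur_radius mean femoral-head radius as a fraction of `min(H, W)`.
#' @param center_jitter,radius_jitter uniform jitter half-widths (fractions).
#' @param cup_inner,cup_outer acetabulum annulus radii as multiples of the
#'   femur radius; `cup_inner < 1` seats the cup over the femoral head so
#'   the two masks overlap with a narrow gap appearance.
#' @param cup_angles annulus sector angular range in degrees (0 = right,
#'   angles increase downward; negative = above center).
#' @param angle_jitter sector rotation jitter half-width in degrees.
#' @param clone_groups,clone_size optionally render `clone_groups` distinct
#'   phantoms and include `clone_size` exact copies of each (distinct ids),
#'   making duplicate-rich pools for diversity-query checks.
#' @param seed integer seed; the corpus is a deterministic function of
#'   `(params, seed)`.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(n = 202L, size = c(64L, 64L), contrast = 0.6,
                           noise_sd = 0.08,
                           femur_center = c(0.58, 0.50),
                           femur_radius = 0.16,
                           center_jitter = 0.05, radius_jitter = 0.03,
                           cup_inner = 0.80, cup_outer = 1.25,
                           cup_angles = c(-170, -10), angle_jitter = 12,
                           clone_groups = 0L, clone_size = 2L, seed = 1L) {
  if (n < 1) stopf("n must be >= 1")
  if (contrast <= 0 || contrast > 1) stopf("contrast must lie in (0, 1]")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (cup_inner >= cup_outer) stopf("cup_inner must be < cup_outer")
  if (clone_groups > 0 && clone_groups * clone_size > n) {
    stopf("clone groups exceed corpus size")
  }
  p <- structure(list(n = as.integer(n), size = as.integer(size),
                      contrast = contrast, noise_sd = noise_sd,
                      femur_center = femur_center,
                      femur_radius = femur_radius,
                      center_jitter = center_jitter,
                      radius_jitter = radius_jitter,
                      cup_inner = cup_inner, cup_outer = cup_outer,
                      cup_angles = cup_angles, angle_jitter = angle_jitter,
                      clone_groups = as.integer(clone_groups),
                      clone_size = as.integer(clone_size),
                      seed = as.integer(seed)),
                 class = "phantom_params")
  # worst-case extent: jittered center plus outer cup radius must fit
  max_r <- (femur_radius + radius_jitter) * cup_outer * min(size)
  for (ax in 1:2) {
    lo <- (femur_center[ax] - center_jitter) * size[ax] - max_r
    hi <- (femur_center[ax] + center_jitter) * size[ax] + max_r
    if (lo < 1 || hi > size[ax]) {
      stopf("shapes not representable at requested size %dx%d: %s",
            size[1], size[2], "jitter range pushes geometry outside the image")
    }
  }
  p
}

render_phantom <- function(p) {
  H <- p$size[1]; W <- p$size[2]; m <- min(H, W)
  cy <- (p$femur_center[1] + stats::runif(1, -p$center_jitter,
                                          p$center_jitter)) * H
  cx <- (p$femur_center[2] + stats::runif(1, -p$center_jitter,
                                          p$center_jitter)) * W
  rf <- (p$femur_radius + stats::runif(1, -p$radius_jitter,
                                       p$radius_jitter)) * m
  ry <- rf * stats::runif(1, 0.92, 1.08)
  rx <- rf * stats::runif(1, 0.92, 1.08)
  rot <- stats::runif(1, -p$angle_jitter, p$angle_jitter)
  a1 <- (p$cup_angles[1] + rot) * pi / 180
  a2 <- (p$cup_angles[2] + rot) * pi / 180
  ri <- rf * p$cup_inner
  ro <- rf * p$cup_outer

  row <- matrix(seq_len(H), H, W)
  col <- matrix(seq_len(W), H, W, byrow = TRUE)
  femur <- (((row - cy) / ry)^2 + ((col - cx) / rx)^2 <= 1) * 1
  dr <- sqrt((row - cy)^2 + (col - cx)^2)
  ang <- atan2(row - cy, col - cx)
  in_sector <- ang >= a1 & ang <= a2
  acet <- (dr >= ri & dr <= ro & in_sector) * 1

  img <- 0.22 + p$contrast * (0.42 * acet + 0.62 * femur)
  if (p$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(H * W, 0, p$noise_sd), H, W)
  }
  img <- pmin(pmax(img, 0), 1)
  list(pixels = img, mask = mask_stack(femur, acet))
}

#' Generate a synthetic hip-phantom corpus
#'
#' Renders `params$n` phantoms with per-patient jittered geometry, fully
#' reproducible from `(params, seed)`. Each sample carries a three-channel
#' binary [mask_stack]; the femur and acetabulum channels overlap where the
#' cup sits over the femoral head.
#'
#' @param params a [phantom_params].
#' @return list of [image_sample] objects with ids `phantom_001`, ...
#' @export
generate_phantoms <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  with_seed(params$seed, {
    n_clone <- params$clone_groups * params$clone_size
    n_fresh <- params$n - n_clone + params$clone_groups
    rendered <- lapply(seq_len(n_fresh), function(i) render_phantom(params))
    all_r <- if (params$clone_groups > 0) {
      c(rep(rendered[seq_len(params$clone_groups)],
            each = params$clone_size),
        rendered[-seq_len(params$clone_groups)])
    } else {
      rendered
    }
    lapply(seq_len(params$n), function(i) {
      image_sample(sprintf("phantom_%03d", i), all_r[[i]]$pixels,
                   all_r[[i]]$mask)
    })
  })
}

#' Construct a corpus split
#'
#' @param test,validation,initial_labeled,unlabeled disjoint lists of
#'   [image_sample] objects; test and validation stay fixed across the whole
#'   AL cycle.
#' @return an object of class `corpus_split`.
#' @export
corpus_split <- function(test, validation, initial_labeled, unlabeled) {
  all_ids <- c(sample_ids(test), sample_ids(validation),
               sample_ids(initial_labeled), sample_ids(unlabeled))
  dup <- unique(all_ids[duplicated(all_ids)])
  if (length(dup) > 0) {
    stopf("split partitions overlap on id(s): %s", paste(dup, collapse = ", "))
  }
  structure(list(test = test, validation = validation,
                 initial_labeled = initial_labeled, unlabeled = unlabeled),
            class = "corpus_split")
}

#' @export
print.corpus_split <- function(x, ...) {
  cat(sprintf("<corpus_split> test %d / validation %d / initial %d / unlabeled %d\n",
              length(x$test), length(x$validation),
              length(x$initial_labeled), length(x$unlabeled)))
  invisible(x)
}

#' Split a corpus into test / validation / initial labeled / unlabeled
#'
#' Shuffles the ids under the given seed and partitions them by the split
#' fractions. Partition sizes are rounded half-up from `fraction * N`; the
#' remainder flows to the unlabeled pool, so the partition is always
#' disjoint and exhaustive. A non-zero fraction that rounds to an empty
#' partition is rejected.
#'
#' @param samples list of [image_sample] objects.
#' @param fractions named `c(test=, validation=, initial=)` fractions
#'   summing to at most 1 (defaults 0.15 / 0.15 / 0.03).
#' @param seed shuffle seed.
#' @return a `corpus_split`.
#' @examples
#' # 100 samples at the default fractions -> 15 / 15 / 3 / 67
#' @export
split_corpus <- function(samples,
                         fractions = c(test = 0.15, validation = 0.15,
                                       initial = 0.03),
                         seed = 1L) {
  if (sum(fractions) > 1 + 1e-9) stopf("split fractions must sum to <= 1")
  n <- length(samples)
  sizes <- floor(fractions * n + 0.5)  # round half-up
  for (nm in names(fractions)) {
    if (fractions[[nm]] > 0 && sizes[[nm]] == 0) {
      stopf("fraction for '%s' (%.3f) yields an empty partition at N=%d",
            nm, fractions[[nm]], n)
    }
  }
  if (sum(sizes) > n) stopf("rounded partition sizes exceed corpus size")
  idx <- with_seed(seed, sample.int(n))
  take <- function(k) {
    if (k == 0) return(integer(0))
    out <- idx[seq_len(k)]
    idx <<- idx[-seq_len(k)]
    out
  }
  test_i <- take(sizes[["test"]])
  val_i <- take(sizes[["validation"]])
  init_i <- take(sizes[["initial"]])
  corpus_split(test = samples[test_i], validation = samples[val_i],
               initial_labeled = samples[init_i],
               unlabeled = samples[idx])
}
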