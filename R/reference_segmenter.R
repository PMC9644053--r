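# Reference segmenter: a pixel-wise multilayer perceptron over hand-crafted
# multi-scale intensity features, with channel-wise dropout on the hidden
# layer and two sigmoid output channels (femur, acetabulum). It honors the
# full segmenter contract - fresh training per AL iteration, deterministic
# prediction, stochastic Monte Carlo Dropout passes - while staying fast
# enough that a complete multi-query experiment runs on one CPU.

# separable Gaussian blur; kernel radius clamped so tiny images stay valid
gauss_blur <- function(m, sigma) {
  r <- max(1L, min(ceiling(2.5 * sigma), nrow(m) - 1L, ncol(m) - 1L))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv_cols <- function(mat) {  # filter every column at once, replicate-pad
    n <- nrow(mat)
    mp <- rbind(mat[rep(1L, r), , drop = FALSE], mat,
                mat[rep(n, r), , drop = FALSE])
    f <- stats::filter(mp, k, sides = 2)
    matrix(f[(r + 1):(r + n), ], n, ncol(mat))
  }
  t(conv_cols(t(conv_cols(m))))
}

pixel_features <- function(pixels) {
  H <- nrow(pixels); W <- ncol(pixels)
  row <- matrix(seq_len(H), H, W) / H
  col <- matrix(seq_len(W), H, W, byrow = TRUE) / W
  rad <- sqrt((row - 0.5)^2 + (col - 0.5)^2)
  b1 <- gauss_blur(pixels, 1)
  # x^2 terms let a linear unit select an intensity band (the acetabulum
  # sits between background and femoral-head intensities)
  cbind(x = as.vector(pixels), x2 = as.vector(pixels)^2,
        b1 = as.vector(b1), b1sq = as.vector(b1)^2,
        b2 = as.vector(gauss_blur(pixels, 2)),
        b4 = as.vector(gauss_blur(pixels, 4)),
        row = as.vector(row), col = as.vector(col), rad = as.vector(rad))
}

N_FEATURES <- 9L

# package-global cache of per-sample pixel features and flattened foreground
# labels: both are model-independent, so fresh-from-scratch retraining in
# every AL iteration reuses them
.feature_cache <- new.env(parent = emptyenv())

cached_features <- function(sample) {
  key <- paste(sample$id, nrow(sample$pixels), ncol(sample$pixels),
               format(sum(sample$pixels), digits = 12), sep = "|")
  if (is.null(.feature_cache[[key]])) {
    if (length(ls(.feature_cache)) > 1200L) {
      rm(list = ls(.feature_cache), envir = .feature_cache)
    }
    G <- NULL
    strata <- NULL
    if (!is.null(sample$mask)) {
      fg <- mask_foreground(sample$mask)
      G <- cbind(as.vector(fg[, , 1]), as.vector(fg[, , 2]))
      strata <- list(femur = which(G[, 1] == 1),
                     acetabulum = which(G[, 2] == 1),
                     background = which(G[, 1] == 0 & G[, 2] == 0))
    }
    .feature_cache[[key]] <- list(X = pixel_features(sample$pixels), G = G,
                                  strata = strata)
  }
  .feature_cache[[key]]
}

#' Reference MLP segmenter
#'
#' A small trainable segmenter fulfilling the [segmenter-contract]: each
#' pixel is described by multi-scale intensity and position features, passed
#' through one ReLU hidden layer with channel-wise dropout (whole hidden
#' feature maps are dropped, as in spatial dropout for convnets), and mapped
#' to two sigmoid output channels. Trained with Adam on the combined
#' dice + focal objective, monitoring validation macro dice with
#' learning-rate reduction on plateau and early stopping.
#'
#' This stands in for a full encoder-decoder network so experiments run at
#' desk scale; any model honoring the contract can replace it.
#'
#' @param hidden hidden layer width (default 32; the acetabular crescent
#'   needs more capacity than the femoral head).
#' @param dropout dropout rate in `[0, 1)`.
#' @param seed seed for weight initialization and training randomness.
#' @return an untrained segmenter of class `mlp_segmenter`.
#' @export
reference_segmenter <- function(hidden = 32L, dropout = 0.25, seed = 1L) {
  if (dropout < 0 || dropout >= 1) stopf("dropout rate must lie in [0, 1)")
  h <- as.integer(hidden)
  w <- with_seed(seed, list(
    W1 = matrix(stats::rnorm(N_FEATURES * h, 0, sqrt(2 / N_FEATURES)),
                N_FEATURES, h),
    b1 = rep(0, h),
    W2 = matrix(stats::rnorm(h * 2, 0, sqrt(1 / h)), h, 2),
    b2 = rep(0, 2)))
  structure(list(weights = w, hidden = h, dropout = dropout,
                 seed = as.integer(seed), trained = FALSE),
            class = "mlp_segmenter")
}

#' @export
print.mlp_segmenter <- function(x, ...) {
  cat(sprintf("<mlp_segmenter> %d hidden units, dropout %.2f, %s\n",
              x$hidden, x$dropout,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

add_rows <- function(M, b) M + rep(b, each = nrow(M))

# forward pass; drop_mask is a per-hidden-unit keep vector (inverted dropout
# scaling already applied) or NULL for the deterministic path
mlp_forward <- function(w, X, drop_mask = NULL) {
  Z1 <- add_rows(X %*% w$W1, w$b1)
  H <- Z1
  H[H < 0] <- 0
  if (!is.null(drop_mask)) H <- H * rep(drop_mask, each = nrow(H))
  P <- 1 / (1 + exp(-add_rows(H %*% w$W2, w$b2)))
  list(Z1 = Z1, H = H, P = P)
}

draw_channel_mask <- function(h, rate) {
  if (rate <= 0) return(rep(1, h))
  keep <- stats::rbinom(h, 1, 1 - rate)
  if (all(keep == 0)) keep[sample.int(h, 1)] <- 1  # never drop everything
  keep / (1 - rate)
}

# gradient of the dice+focal objective w.r.t. sigmoid outputs P (rows x 2)
dice_focal_grad <- function(P, G, alpha = 0.25, gamma = 2) {
  nc <- ncol(P)
  gdice <- matrix(0, nrow(P), nc)
  for (j in seq_len(nc)) {
    sp <- sum(P[, j]); sg <- sum(G[, j]); spg <- sum(P[, j] * G[, j])
    gdice[, j] <- -(2 * G[, j] * (sp + sg) - 2 * spg) / (sp + sg)^2 / nc
  }
  pt <- clip01(ifelse(G == 1, P, 1 - P))
  dfdpt <- alpha * gamma * (1 - pt)^(gamma - 1) * log(pt) -
    alpha * (1 - pt)^gamma / pt
  gfocal <- dfdpt * (2 * G - 1) / length(P)
  gdice + gfocal
}

# class-stratified pixel subsample: the acetabular crescent covers only a
# few percent of the image, so uniform sampling starves its gradient signal;
# a quarter of the budget goes to each foreground class when available
stratified_pixels <- function(f, budget) {
  npix <- nrow(f$X)
  if (budget >= npix) return(seq_len(npix))
  quota <- budget %/% 4L
  pick <- function(pool, m) {
    if (length(pool) <= m) pool else pool[sample.int(length(pool), m)]
  }
  fem <- pick(f$strata$femur, quota)
  ace <- pick(f$strata$acetabulum, quota)
  rest <- budget - length(fem) - length(ace)
  c(fem, ace, pick(f$strata$background, rest))
}

adam_init <- function(w) lapply(w, function(p) list(m = p * 0, v = p * 0))

adam_step <- function(w, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(w)) {
    state[[nm]]$m <- beta1 * state[[nm]]$m + (1 - beta1) * grads[[nm]]
    state[[nm]]$v <- beta2 * state[[nm]]$v + (1 - beta2) * grads[[nm]]^2
    mhat <- state[[nm]]$m / (1 - beta1^t)
    vhat <- state[[nm]]$v / (1 - beta2^t)
    w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(w = w, state = state)
}

# deterministic (or channel-masked) probabilities without keeping
# intermediates; the channel mask folds into the output weights
mlp_predict_probs <- function(w, X, drop_mask = NULL) {
  H <- add_rows(X %*% w$W1, w$b1)
  H[H < 0] <- 0
  W2 <- if (is.null(drop_mask)) w$W2 else w$W2 * drop_mask
  1 / (1 + exp(-add_rows(H %*% W2, w$b2)))
}

# validation macro dice straight from cached flat features/labels
flat_macro_dice <- function(P, G, threshold = 0.5) {
  pb <- P >= threshold
  mean(vapply(1:2, function(j) {
    denom <- sum(pb[, j]) + sum(G[, j])
    if (denom == 0) 1 else 2 * sum(pb[, j] & (G[, j] == 1)) / denom
  }, numeric(1)))
}

val_macro_dice <- function(w, val_stack) {
  P <- mlp_predict_probs(w, val_stack$X)
  mean(vapply(seq_along(val_stack$starts), function(j) {
    rows <- val_stack$starts[j]:val_stack$ends[j]
    flat_macro_dice(P[rows, , drop = FALSE],
                    val_stack$G[rows, , drop = FALSE])
  }, numeric(1)))
}

stack_features <- function(feats) {
  npix <- vapply(feats, function(f) nrow(f$X), integer(1))
  ends <- cumsum(npix)
  list(X = do.call(rbind, lapply(feats, `[[`, "X")),
       G = do.call(rbind, lapply(feats, `[[`, "G")),
       starts = ends - npix + 1L, ends = ends)
}

#' @export
seg_train.mlp_segmenter <- function(model, labeled, validation, config) {
  stopifnot(inherits(config, "training_config"))
  if (!identical(config$optimizer, "adam")) {
    stopf("reference segmenter implements only the adam optimizer")
  }
  feats <- lapply(labeled, cached_features)
  for (f in feats) {
    if (is.null(f$G)) stopf("training samples must carry masks")
  }
  val_stack <- stack_features(lapply(validation, cached_features))
  w <- model$weights
  state <- adam_init(w)
  lr <- config$learning_rate
  best <- -Inf
  best_w <- w
  stall <- 0L
  step <- 0L
  with_seed(derive_seed(model$seed, 11L), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(seq_along(feats))
      for (start in seq(1, length(feats), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, length(feats))]
        XG <- lapply(feats[idx], function(f) {
          take <- stratified_pixels(f, config$pixels_per_image)
          list(X = f$X[take, , drop = FALSE], G = f$G[take, , drop = FALSE])
        })
        X <- do.call(rbind, lapply(XG, `[[`, "X"))
        G <- do.call(rbind, lapply(XG, `[[`, "G"))
        mask <- draw_channel_mask(model$hidden, model$dropout)
        fw <- mlp_forward(w, X, mask)
        dP <- dice_focal_grad(fw$P, G)
        dZ2 <- dP * fw$P * (1 - fw$P)
        dH <- (dZ2 %*% t(w$W2)) * (fw$Z1 > 0)
        dH <- dH * rep(mask, each = nrow(dH))
        grads <- list(W1 = crossprod(X, dH), b1 = colSums(dH),
                      W2 = crossprod(fw$H, dZ2), b2 = colSums(dZ2))
        step <- step + 1L
        up <- adam_step(w, grads, state, lr, step)
        w <- up$w
        state <- up$state
      }
      vd <- val_macro_dice(w, val_stack)
      if (vd > best + 1e-6) {
        best <- vd
        best_w <- w
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$early_stop_patience) break
        if (stall %% config$lr_patience == 0L) lr <- lr * config$lr_factor
      }
    }
  })
  model$weights <- best_w
  model$trained <- TRUE
  model
}

#' @export
seg_predict.mlp_segmenter <- function(model, samples) {
  out <- lapply(samples, function(s) {
    X <- cached_features(s)$X
    P <- mlp_forward(model$weights, X)$P
    array(P, dim = c(dim(s$pixels), 2L))
  })
  names(out) <- sample_ids(samples)
  out
}

#' @export
seg_predict_stochastic.mlp_segmenter <- function(model, samples, k = 30L,
                                                 seed = 1L) {
  feats <- lapply(samples, function(s) cached_features(s)$X)
  dims <- lapply(samples, function(s) dim(s$pixels))
  npix <- vapply(feats, nrow, integer(1))
  ends <- cumsum(npix)
  starts <- ends - npix + 1L
  Xall <- do.call(rbind, feats)
  ids <- sample_ids(samples)
  w <- model$weights
  # the hidden activations do not depend on the channel mask: compute once,
  # then each pass only re-applies its mask through the output weights
  Hall <- add_rows(Xall %*% w$W1, w$b1)
  Hall[Hall < 0] <- 0
  passes <- with_seed(seed, {
    lapply(seq_len(k), function(i) {
      mask <- draw_channel_mask(model$hidden, model$dropout)
      P <- 1 / (1 + exp(-add_rows(Hall %*% (w$W2 * mask), w$b2)))
      one <- lapply(seq_along(samples), function(j) {
        array(P[starts[j]:ends[j], ], dim = c(dims[[j]], 2L))
      })
      names(one) <- ids
      one
    })
  })
  predictive_ensemble(passes, k = as.integer(k), seed = seed)
}

#' @export
seg_supports_dropout.mlp_segmenter <- function(model) TRUE

#' @export
seg_is_trained.mlp_segmenter <- function(model) isTRUE(model$trained)
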