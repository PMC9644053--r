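# Small programmatic fixtures shared across the suite.

# one tiny sample with random pixels and a random (valid) mask
tiny_sample <- function(id, h = 6, w = 6, seed = NULL, value = NULL,
                        with_mask = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  px <- if (is.null(value)) matrix(runif(h * w), h, w) else matrix(value, h, w)
  mask <- NULL
  if (with_mask) {
    fem <- matrix(0, h, w); fem[2:3, 2:3] <- 1
    ace <- matrix(0, h, w); ace[3:4, 3:4] <- 1
    mask <- mask_stack(fem, ace)
  }
  image_sample(id, px, mask)
}

tiny_samples <- function(n, h = 6, w = 6, seed = 1, prefix = "s") {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    tiny_sample(sprintf("%s%03d", prefix, i), h, w)
  })
}

tiny_pool <- function(n_total, n_labeled, seed = 1, h = 6, w = 6) {
  samples <- tiny_samples(n_total, h = h, w = w, seed = seed)
  make_pool(samples, labeled_ids = sample_ids(samples)[seq_len(n_labeled)])
}

# a corpus_split around a given L0/U0 size, with small held-out sets
tiny_split <- function(n_initial, n_unlabeled, seed = 1) {
  all <- tiny_samples(n_initial + n_unlabeled + 4, seed = seed)
  corpus_split(test = all[1:2], validation = all[3:4],
               initial_labeled = all[4 + seq_len(n_initial)],
               unlabeled = all[4 + n_initial + seq_len(n_unlabeled)])
}

stub_factory <- function(p = 0.5) {
  function(seed) constant_segmenter(p)
}

# entropy of a constant-probability map under the literal single-term form
const_entropy <- function(p) ifelse(p > 0, -p * log2(p), 0)

expect_same_ids <- function(a, b) expect_identical(as.character(a),
                                                   as.character(b))
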