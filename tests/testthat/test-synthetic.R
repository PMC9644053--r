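test_that("phantom corpora are deterministic functions of (params, seed)", {
  p <- phantom_params(n = 6, seed = 4)
  a <- generate_phantoms(p)
  b <- generate_phantoms(p)
  expect_identical(a, b)
  c <- generate_phantoms(phantom_params(n = 6, seed = 5))
  expect_false(identical(a, c))
})

test_that("noiseless full-contrast phantoms have strictly brighter bones", {
  p <- phantom_params(n = 8, noise_sd = 0, contrast = 1, seed = 2)
  for (s in generate_phantoms(p)) {
    bg <- s$mask$channels[, , 1] == 1
    expect_gt(min(s$pixels[!bg]), max(s$pixels[bg]))
    # masks delineate the rendered shapes: foreground exactly where bright
    expect_true(all((s$pixels > 0.3) == !bg))
  }
})

test_that("the default corpus has unique ids and overlapping structures", {
  samples <- generate_phantoms(phantom_params(n = 202, seed = 1))
  expect_length(unique(sample_ids(samples)), 202)
  overlap <- vapply(samples, function(s) {
    fg <- mask_foreground(s$mask)
    sum(fg[, , 1] * fg[, , 2]) > 0
  }, logical(1))
  expect_gte(mean(overlap), 0.95)
})

test_that("clone groups yield exact duplicate images with distinct ids", {
  p <- phantom_params(n = 10, clone_groups = 2, clone_size = 3, seed = 6)
  s <- generate_phantoms(p)
  expect_identical(s[[1]]$pixels, s[[2]]$pixels)
  expect_identical(s[[2]]$pixels, s[[3]]$pixels)
  expect_identical(s[[4]]$pixels, s[[5]]$pixels)
  expect_false(identical(s[[1]]$pixels, s[[4]]$pixels))
  expect_length(unique(sample_ids(s)), 10)
  expect_error(phantom_params(n = 4, clone_groups = 3, clone_size = 2),
               "exceed")
})

test_that("split_corpus applies half-up rounding with remainder to the pool", {
  s100 <- tiny_samples(100)
  sp <- split_corpus(s100, seed = 1)
  expect_equal(vapply(sp, length, integer(1)),
               c(test = 15, validation = 15, initial_labeled = 3,
                 unlabeled = 67))

  s202 <- tiny_samples(202)
  sp2 <- split_corpus(s202, seed = 1)
  expect_equal(unname(vapply(sp2, length, integer(1))), c(30, 30, 6, 136))

  all_lab <- split_corpus(s100, c(test = 0, validation = 0, initial = 1))
  expect_length(all_lab$initial_labeled, 100)
  expect_length(all_lab$unlabeled, 0)

  expect_error(split_corpus(tiny_samples(5),
                            c(test = 0.01, validation = 0.3, initial = 0.3)),
               "empty partition")
})

test_that("split partitions are disjoint and exhaustive for any N and seed", {
  set.seed(12)
  for (rep in 1:8) {
    n <- sample(20:120, 1)
    sp <- split_corpus(tiny_samples(n), seed = rep)
    ids <- unlist(lapply(sp, sample_ids))
    expect_length(ids, n)
    expect_length(unique(ids), n)
  }
})

test_that("resize keeps images in range and masks strictly binary", {
  s <- generate_phantoms(phantom_params(n = 1, size = c(32, 32), seed = 3))[[1]]
  same <- resize_pair(s$pixels, s$mask, target = c(32, 32))
  expect_identical(same$image, s$pixels)
  expect_identical(same$mask$channels, s$mask$channels)

  up <- resize_pair(s$pixels, s$mask, target = c(48, 40))
  expect_equal(dim(up$image), c(48, 40))
  expect_true(all(up$image >= 0 & up$image <= 1))
  expect_true(all(up$mask$channels %in% c(0, 1)))

  # nearest-neighbor downscale: every output pixel comes from its source block
  checker <- matrix(rep(c(1, 0), 8), 4, 4)
  ms <- mask_stack(checker, matrix(0, 4, 4))
  down <- resize_pair(matrix(0.5, 4, 4), ms, target = c(2, 2))
  fem <- down$mask$channels[, , 2]
  for (i in 1:2) for (j in 1:2) {
    block <- checker[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]
    expect_true(fem[i, j] %in% block)
  }
  expect_error(resize_pair(matrix(0.5, 4, 4), ms, target = c(0, 2)),
               "positive")
})

test_that("the reference segmenter honors the contract", {
  s <- tiny_samples(3, seed = 30)
  m <- reference_segmenter(seed = 1)
  expect_false(seg_is_trained(m))
  preds <- seg_predict(m, s)  # untrained predictions still valid probabilities
  for (p in preds) expect_true(all(p >= 0 & p <= 1))

  nd <- reference_segmenter(dropout = 0, seed = 1)
  ens <- seg_predict_stochastic(nd, s, k = 3, seed = 2)
  expect_identical(ens$passes[[1]], ens$passes[[3]])

  expect_error(reference_segmenter(dropout = 1), "dropout")
})

test_that("the trained reference segmenter segments noiseless phantoms well", {
  params <- phantom_params(n = 64, noise_sd = 0, contrast = 1, seed = 3)
  sp <- split_corpus(generate_phantoms(params),
                     fractions = c(test = 0.15, validation = 0.15,
                                   initial = 0.1), seed = 1)
  m <- seg_train(reference_segmenter(seed = 5),
                 c(sp$initial_labeled, sp$unlabeled), sp$validation,
                 training_config(max_epochs = 60, learning_rate = 2e-2,
                                 pixels_per_image = 512))
  preds <- seg_predict(m, sp$test)
  macro <- mean(vapply(sp$test, function(x) {
    dice_score(preds[[x$id]], x$mask)$macro
  }, numeric(1)))
  expect_gt(macro, 0.8)
})

test_that("noisier phantoms raise the model's mean entropy", {
  params <- phantom_params(n = 48, noise_sd = 0.02, seed = 9)
  sp <- split_corpus(generate_phantoms(params),
                     fractions = c(test = 0.15, validation = 0.15,
                                   initial = 0.1), seed = 1)
  m <- seg_train(reference_segmenter(seed = 7),
                 c(sp$initial_labeled, sp$unlabeled), sp$validation,
                 training_config(max_epochs = 15, learning_rate = 2e-2,
                                 pixels_per_image = 512))
  diffs <- vapply(1:10, function(r) {
    clean <- generate_phantoms(phantom_params(n = 6, noise_sd = 0.02,
                                              seed = 100 + r))
    noisy <- generate_phantoms(phantom_params(n = 6, noise_sd = 0.25,
                                              seed = 100 + r))
    e <- function(ss) mean(class_wise_entropy(seg_predict(m, ss))$scores)
    e(noisy) - e(clean)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
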