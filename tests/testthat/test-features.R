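test_that("flatten_images produces row-major rows per sample", {
  a <- image_sample("a", matrix(c(1, 3, 2, 4) / 4, 2, 2))  # col-major fill
  b <- image_sample("b", matrix(c(5, 7, 6, 8) / 8, 2, 2))
  fm <- flatten_images(list(a, b))
  expect_equal(dim(fm$rows), c(2, 4))
  # row-major: row 1 then row 2 of the image
  expect_equal(unname(fm$rows[1, ]), c(1, 2, 3, 4) / 4)
  expect_identical(fm$provenance, "raw")

  single <- flatten_images(list(a))
  expect_equal(dim(single$rows), c(1, 4))

  mixed <- list(a, image_sample("c", matrix(0.5, 3, 3)))
  expect_error(flatten_images(mixed), "thumbnail")
  thumbed <- flatten_images(mixed, thumbnail_size = c(8, 8))
  expect_equal(ncol(thumbed$rows), 64)
})

test_that("min-max normalization rescales each column onto [0, 1]", {
  fm <- feature_matrix(cbind(c(0, 5, 10), c(1, 2, 3)), c("a", "b", "c"))
  nm <- min_max_normalize(fm)
  expect_equal(unname(nm$rows[, 1]), c(0, 0.5, 1))
  expect_identical(nm$provenance, "normalized")

  const <- feature_matrix(cbind(c(3, 3, 3), c(0, 1, 2)), c("a", "b", "c"))
  expect_warning(ncm <- min_max_normalize(const), "constant")
  expect_equal(unname(ncm$rows[, 1]), c(0, 0, 0))

  set.seed(7)
  r <- feature_matrix(matrix(rnorm(12), 4, 3), paste0("s", 1:4))
  nr <- min_max_normalize(r)$rows
  for (j in 1:3) {  # brute-force per-column extrema
    expect_equal(min(nr[, j]), 0)
    expect_equal(max(nr[, j]), 1)
  }

  # idempotence on columns already spanning [0, 1]
  again <- min_max_normalize(feature_matrix(nr, paste0("s", 1:4), "raw"))
  expect_equal(again$rows, nr)
})

test_that("fit_pca keeps the minimal component count for the variance target", {
  # points exactly on a line in 5-D: rank 1
  set.seed(1)
  t <- rnorm(10)
  line <- outer(t, c(1, 2, 3, 4, 5)) + 0.3
  fml <- feature_matrix(line, paste0("s", 1:10), "normalized")
  expect_equal(fit_pca(fml)$n_components, 1)

  # random matrix: compare against an independent eigendecomposition
  set.seed(2)
  x <- matrix(runif(200), 20, 10)
  fm <- feature_matrix(x, paste0("s", 1:20), "normalized")
  model <- fit_pca(fm, 0.99)
  ev <- sort(eigen(stats::cov(x), symmetric = TRUE)$values, decreasing = TRUE)
  oracle_m <- which(cumsum(ev) / sum(ev) >= 0.99)[1]
  expect_equal(model$n_components, oracle_m)
  # minimality: dropping the last retained component falls below the target
  expect_lt(sum(ev[seq_len(oracle_m - 1)]) / sum(ev), 0.99)

  # isotropic 2-D cloud: each axis explains about half, so both are needed
  set.seed(3)
  iso <- feature_matrix(matrix(rnorm(400), 200, 2), paste0("s", 1:200),
                        "normalized")
  expect_equal(fit_pca(iso, 0.99)$n_components, 2)

  expect_error(fit_pca(feature_matrix(matrix(1, 3, 2), paste0("s", 1:3),
                                      "normalized")), "informative")
  expect_error(fit_pca(flatten_images(tiny_samples(3))), "normalized")
})

test_that("pca_transform centers, projects, and preserves structure", {
  set.seed(4)
  x <- matrix(runif(60), 12, 5)
  fm <- feature_matrix(x, paste0("s", 1:12), "normalized")
  model <- fit_pca(fm, 0.99)
  red <- pca_transform(model, fm)
  expect_identical(red$provenance, "reduced")

  # reconstruction recovers at least the target fraction of total variance
  recon <- red$rows %*% t(model$rotation)
  centered <- sweep(x, 2, model$center, "-")
  expect_gte(sum(recon^2) / sum(centered^2), 0.99 - 1e-9)

  # the column-mean row projects to the origin
  mean_fm <- feature_matrix(matrix(colMeans(x), 1), "m", "normalized")
  expect_equal(max(abs(pca_transform(model, mean_fm)$rows)), 0)

  # 1-component model on collinear data preserves pairwise distances
  pts <- outer(c(0, 1, 3), c(2, 1))  # 3 points on a line in 2-D
  fl <- feature_matrix(pts, c("a", "b", "c"), "normalized")
  m1 <- fit_pca(fl, 0.99)
  expect_equal(m1$n_components, 1)
  r1 <- pca_transform(m1, fl)$rows
  expect_equal(as.numeric(dist(r1)), as.numeric(dist(pts)))

  expect_error(pca_transform(model,
                             feature_matrix(matrix(0.1, 2, 3),
                                            c("a", "b"), "normalized")),
               "dimension")
})

test_that("full-variance projection preserves distance rank order to centroid", {
  set.seed(5)
  for (rep in 1:5) {
    x <- matrix(runif(40), 8, 5)
    fm <- feature_matrix(x, paste0("s", 1:8), "normalized")
    model <- fit_pca(fm, 1.0)  # retain everything
    red <- pca_transform(model, fm)$rows
    d_orig <- sqrt(rowSums(sweep(x, 2, colMeans(x), "-")^2))
    d_red <- sqrt(rowSums(sweep(red, 2, colMeans(red), "-")^2))
    expect_equal(order(d_orig), order(d_red))
  }
})
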