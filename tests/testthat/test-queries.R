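# samples whose flattened features are controlled exactly: constant-intensity
# tiny images, one intensity per "group"
flat_sample <- function(id, value, h = 3, w = 3) {
  image_sample(id, matrix(value, h, w))
}

flat_pool <- function(values, n_labeled = 0, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("f%03d", seq_along(values))
  samples <- Map(flat_sample, ids, values)
  make_pool(unname(samples), labeled_ids = ids[seq_len(n_labeled)])
}

test_that("random query draws uniformly without replacement, reproducibly", {
  p <- tiny_pool(12, 2)
  all_u <- random_query(p, n = 10, seed = 3)
  expect_setequal(all_u$selected_ids, p$unlabeled_ids)

  expect_identical(random_query(p, 4, seed = 9)$selected_ids,
                   random_query(p, 4, seed = 9)$selected_ids)
  expect_error(random_query(tiny_pool(3, 3), 1), "empty")

  # frequency check: |U| = 10, n = 2, each id should appear ~20% of draws
  p10 <- tiny_pool(10, 0)
  counts <- integer(10)
  names(counts) <- p10$unlabeled_ids
  reps <- 10000
  for (i in seq_len(reps)) {
    sel <- random_query(p10, 2, seed = i)$selected_ids
    counts[sel] <- counts[sel] + 1
  }
  phat <- counts / reps
  sigma <- sqrt(0.2 * 0.8 / reps)
  expect_true(all(abs(phat - 0.2) < 3 * sigma))
})

test_that("cluster query spreads the batch across feature-space groups", {
  # pool of exactly n distinct points: all are returned
  p3 <- flat_pool(c(0.1, 0.5, 0.9))
  sel <- cluster_query(p3, 3, seed = 1, thumbnail_size = NULL)$selected_ids
  expect_setequal(sel, p3$unlabeled_ids)

  # duplicate collapse: d copies of two points, n = 2 -> one copy of each
  pd <- flat_pool(c(rep(0.2, 4), rep(0.8, 4)))
  sel2 <- cluster_query(pd, 2, seed = 2, thumbnail_size = NULL)$selected_ids
  vals <- sapply(sel2, function(id) pd$samples[[id]]$pixels[1, 1])
  expect_setequal(round(vals, 3), c(0.2, 0.8))

  # well-separated tight groups: exactly one member per group
  set.seed(5)
  centers <- c(0.1, 0.5, 0.9)
  values <- as.vector(sapply(centers, function(c) c + runif(4, -0.02, 0.02)))
  groups <- rep(1:3, each = 4)
  pg <- flat_pool(values)
  sel3 <- cluster_query(pg, 3, seed = 3, thumbnail_size = NULL)$selected_ids
  chosen_groups <- groups[match(sel3, pg$unlabeled_ids)]
  expect_setequal(chosen_groups, 1:3)
})

test_that("representativeness scores match hand-computed distances", {
  u <- feature_matrix(rbind(c(2, 0), c(4, 0)), c("u1", "u2"), "reduced")
  l <- feature_matrix(rbind(c(0, 0)), "l1", "reduced")
  r <- representativeness_scores(u, l)
  expect_equal(unname(r), c(2 - 1, 4 - 1))  # mu_L=(0,0), mu_U=(3,0)

  # coincident centroids: R identically zero
  u2 <- feature_matrix(rbind(c(1, 1), c(-1, -1)), c("a", "b"), "reduced")
  l2 <- feature_matrix(rbind(c(2, 2), c(-2, -2)), c("c", "d"), "reduced")
  expect_equal(unname(representativeness_scores(u2, l2)), c(0, 0))

  # x at the unlabeled centroid scores the full centroid separation
  u3 <- feature_matrix(rbind(c(3, 0), c(2, 0), c(4, 0)),
                       c("m", "p", "q"), "reduced")
  r3 <- representativeness_scores(u3, l)
  expect_equal(r3[["m"]], 3)

  expect_error(representativeness_scores(u, feature_matrix(
    matrix(numeric(0), 0, 2), character(0), "reduced")), "empty")
})

test_that("representative query selects the top-R ids with stable ties", {
  # total tie: all unlabeled identical -> first n in stable order
  pt <- flat_pool(c(0.9, rep(0.4, 5)), n_labeled = 1)
  sel <- representative_query(pt, 3, thumbnail_size = NULL)$selected_ids
  expect_identical(sel, pt$unlabeled_ids[1:3])

  expect_error(representative_query(flat_pool(c(0.1, 0.2)), 1), "labeled")

  # argsort oracle on random pools
  set.seed(6)
  for (rep in 1:5) {
    vals <- runif(20)
    p <- flat_pool(vals, n_labeled = 4)
    qr <- representative_query(p, 5, thumbnail_size = NULL)
    r <- qr$scores[p$unlabeled_ids]
    oracle <- names(r)[order(-r)][1:5]
    expect_identical(qr$selected_ids, oracle)
  }
})

test_that("CWE-MCD query ranks samples by entropy of the mean prediction", {
  p <- tiny_pool(3, 0)
  ids <- p$unlabeled_ids
  stub <- seg_train(constant_segmenter(
    stats::setNames(c(1.0, 0.5, 0.9), ids)), NULL, NULL, NULL)
  qr <- cwe_mcd_query(p, 1, stub, k = 3, seed = 1)
  expect_identical(qr$selected_ids, ids[2])  # p = 0.5 is most uncertain

  expect_error(cwe_mcd_query(p, 1, constant_segmenter(0.5)), "trained")

  # argsort oracle on random constant stubs
  set.seed(7)
  for (rep in 1:5) {
    p10 <- tiny_pool(10, 0, seed = rep)
    probs <- stats::setNames(runif(10), p10$unlabeled_ids)
    stub <- seg_train(constant_segmenter(probs), NULL, NULL, NULL)
    qr <- cwe_mcd_query(p10, 4, stub, k = 2, seed = 1)
    scores <- const_entropy(probs)
    oracle <- names(scores)[order(-scores)][1:4]
    expect_identical(qr$selected_ids, oracle)
  }
})

test_that("Borda fusion assigns points with shared-tie blocks", {
  r <- c(id1 = 1, id2 = 2, id3 = 3)
  e <- c(id1 = 3, id2 = 1, id3 = 2)
  b <- borda_combine(R = r, E = e)
  expect_equal(unname(b$points[, "R"]), c(0, 1, 2))
  expect_equal(unname(b$points[, "E"]), c(2, 0, 1))
  expect_equal(unname(b$combined), c(2, 1, 3))
  expect_identical(b$ordering, c("id3", "id1", "id2"))

  # exact reversal: all combined points tie; stable id order wins
  rev_b <- borda_combine(a = c(x = 1, y = 2, z = 3), b = c(x = 3, y = 2, z = 1))
  expect_true(length(unique(rev_b$combined)) == 1)
  expect_identical(rev_b$ordering, c("x", "y", "z"))

  # identical rankings in both criteria reproduce either ordering
  agree <- borda_combine(a = r, b = r * 10)
  expect_identical(agree$ordering, c("id3", "id2", "id1"))

  expect_error(borda_combine(a = c(x = 1), b = c(y = 1)), "mismatch")
})

test_that("Borda fusion is invariant to criterion order and monotone maps", {
  set.seed(8)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    ids <- paste0("id", 1:n)
    s1 <- stats::setNames(runif(n), ids)
    s2 <- stats::setNames(runif(n), ids)
    b12 <- borda_combine(s1, s2)
    b21 <- borda_combine(s2, s1)
    expect_equal(unname(b12$combined), unname(b21$combined))
    expect_identical(b12$ordering, b21$ordering)
    bmono <- borda_combine(exp(s1 * 3), s2^3 + 1)
    expect_equal(unname(bmono$combined), unname(b12$combined))
  }
})

test_that("the fused query equals brute-force Borda enumeration", {
  set.seed(9)
  p <- tiny_pool(6, 2, seed = 20)
  u_ids <- p$unlabeled_ids
  probs <- stats::setNames(runif(4, 0.3, 0.7), u_ids)
  stub <- seg_train(constant_segmenter(probs), NULL, NULL, NULL)
  qr <- representative_cwe_mcd_query(p, 2, stub, k = 2, seed = 1,
                                     thumbnail_size = NULL)

  # independent enumeration: recompute R (public pipeline) and E (closed
  # form), assign Borda points by explicit sorting, sum, argsort
  fm <- flatten_images(c(pool_samples(p, p$labeled_ids),
                         pool_samples(p, u_ids)))
  red <- pca_transform(fit_pca(suppressWarnings(min_max_normalize(fm))),
                       suppressWarnings(min_max_normalize(fm)))
  rl <- feature_matrix(red$rows[p$labeled_ids, , drop = FALSE],
                       p$labeled_ids, "reduced")
  ru <- feature_matrix(red$rows[u_ids, , drop = FALSE], u_ids, "reduced")
  r <- representativeness_scores(ru, rl)
  e <- const_entropy(probs)[u_ids]
  pts <- function(s) rank(s, ties.method = "average") - 1
  combined <- pts(r) + pts(e)
  oracle <- names(combined)[order(-combined)][1:2]
  expect_identical(qr$selected_ids, oracle)
})

test_that("every query returns distinct unlabeled ids, count = min(n, |U|)", {
  set.seed(10)
  for (rep in 1:4) {
    n_total <- sample(6:14, 1)
    n_lab <- sample(1:3, 1)
    p <- tiny_pool(n_total, n_lab, seed = 30 + rep)
    n_u <- length(p$unlabeled_ids)
    n_ask <- sample(c(2, n_u, n_u + 3), 1)
    stub <- seg_train(constant_segmenter(
      stats::setNames(runif(n_u), p$unlabeled_ids)), NULL, NULL, NULL)
    for (q in al_queries()) {
      fn <- get_query(q)
      qr <- fn(p, n_ask, model = stub, k = 2, seed = rep,
               thumbnail_size = NULL)
      expect_length(qr$selected_ids, min(n_ask, n_u))
      expect_false(anyDuplicated(qr$selected_ids) > 0)
      expect_true(all(qr$selected_ids %in% p$unlabeled_ids))
      expect_gte(qr$elapsed_seconds, 0)
    }
  }
  expect_error(get_query("nonsense"), "registered")
})
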