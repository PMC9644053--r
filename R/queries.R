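#' Acquisition queries
#'
#' Five pool-based acquisition strategies, each mapping
#' `(pool, n, context)` to a [query_result] of `min(n, |U|)` distinct
#' unlabeled ids. On the final AL iteration, when fewer than `n` unlabeled
#' samples remain, every query returns all remaining ids.
#'
#' Registered names: `"random"`, `"cluster"`, `"representative"`,
#' `"cwe_mcd"`, `"representative_cwe_mcd"`.
#'
#' @name acquisition-queries
NULL

timed <- function(expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- force(expr)
  list(value = value, elapsed = max(proc.time()[["elapsed"]] - t0, 0))
}

check_unlabeled <- function(pool) {
  stopifnot(inherits(pool, "al_pool"))
  if (length(pool$unlabeled_ids) == 0) stopf("unlabeled pool is empty")
}

# stable top-m by descending score: ties broken by input (id) order
top_ids_by_score <- function(scores, m) {
  ord <- order(-scores)  # order() is stable, preserving id order on ties
  names(scores)[ord][seq_len(m)]
}

#' Random baseline query
#'
#' Uniform sampling without replacement from the unlabeled pool.
#'
#' @param pool an [make_pool] pool.
#' @param n batch size.
#' @param seed integer seed; the same seed reproduces the selection.
#' @return a [query_result].
#' @export
random_query <- function(pool, n = 15L, seed = 1L) {
  check_unlabeled(pool)
  if (n < 1) stopf("n must be >= 1")
  tm <- timed({
    u <- pool$unlabeled_ids
    m <- min(n, length(u))
    with_seed(seed, sample(u, m))
  })
  query_result(tm$value, elapsed_seconds = tm$elapsed, query_name = "random")
}

# K-Means++ seeding: D^2-weighted sampling of k distinct rows of X
kmeanspp_centers <- function(X, k, seed = 1L) {
  n <- nrow(X)
  stopifnot(k <= n)
  with_seed(seed, {
    idx <- integer(k)
    idx[1] <- sample.int(n, 1)
    if (k > 1) {
      d2 <- rowSums(sweep(X, 2, X[idx[1], ], "-")^2)
      for (j in 2:k) {
        tot <- sum(d2)
        idx[j] <- if (tot <= 0) {
          sample(setdiff(seq_len(n), idx[seq_len(j - 1)]), 1)
        } else {
          sample.int(n, 1, prob = d2 / tot)
        }
        d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[j], ], "-")^2))
      }
    }
    X[idx, , drop = FALSE]
  })
}

# greedy centroid -> element assignment by ascending distance, each element
# used once; guarantees k distinct elements
nearest_to_centroids <- function(centers, X, ids) {
  k <- nrow(centers)
  D <- matrix(0, k, nrow(X))
  for (j in seq_len(k)) {
    D[j, ] <- sqrt(rowSums(sweep(X, 2, centers[j, ], "-")^2))
  }
  chosen <- character(0)
  used_el <- rep(FALSE, nrow(X))
  used_ct <- rep(FALSE, k)
  for (step in seq_len(k)) {
    Dm <- D
    Dm[used_ct, ] <- Inf
    Dm[, used_el] <- Inf
    w <- which(Dm == min(Dm), arr.ind = TRUE)[1, ]
    used_ct[w[1]] <- TRUE
    used_el[w[2]] <- TRUE
    chosen <- c(chosen, ids[w[2]])
  }
  chosen
}

# shared feature pipeline: flatten -> min-max -> PCA(target) -> reduced rows
reduce_features <- function(samples, thumbnail_size, target_variance = 0.99) {
  raw <- flatten_images(samples, thumbnail_size)
  norm <- suppressWarnings(min_max_normalize(raw))
  if (all(norm$rows == 0) || nrow(norm$rows) < 2) return(NULL)  # degenerate
  model <- fit_pca(norm, target_variance)
  pca_transform(model, norm)
}

#' Cluster-based diversity query
#'
#' Flattens the unlabeled images, min-max normalizes per feature, reduces by
#' PCA at 99% explained variance, partitions the reduced pool into `n`
#' clusters with K-Means++ seeding, and selects, for each centroid, the
#' nearest pool element by Euclidean distance. When two centroids share a
#' nearest element, assignment proceeds greedily by ascending
#' centroid-to-element distance with each element used once, so the batch is
#' always `n` distinct samples spread across feature space.
#'
#' @inheritParams random_query
#' @param thumbnail_size `c(H, W)` thumbnail used for the pixel features.
#' @param target_variance PCA explained-variance target.
#' @return a [query_result].
#' @export
cluster_query <- function(pool, n = 15L, seed = 1L,
                          thumbnail_size = c(64L, 64L),
                          target_variance = 0.99) {
  check_unlabeled(pool)
  if (n < 1) stopf("n must be >= 1")
  tm <- timed({
    u_ids <- pool$unlabeled_ids
    m <- min(n, length(u_ids))
    reduced <- reduce_features(pool_samples(pool, u_ids), thumbnail_size,
                               target_variance)
    if (is.null(reduced)) {
      u_ids[seq_len(m)]  # all images identical: stable-order fallback
    } else {
      X <- reduced$rows
      ux <- unique(X)
      n_distinct <- nrow(ux)
      k <- min(m, n_distinct)
      centers <- if (k == 1) {
        matrix(colMeans(X), nrow = 1)
      } else if (k == n_distinct) {
        ux  # one point per cluster: K-Means is trivially converged
      } else {
        init <- kmeanspp_centers(ux, k, seed = seed)
        with_seed(seed,
                  stats::kmeans(X, centers = init, iter.max = 50L))$centers
      }
      sel <- nearest_to_centroids(as.matrix(centers), X, u_ids)
      if (length(sel) < m) {  # fewer distinct points than n: top up stably
        sel <- c(sel, setdiff(u_ids, sel)[seq_len(m - length(sel))])
      }
      sel
    }
  })
  query_result(tm$value, elapsed_seconds = tm$elapsed, query_name = "cluster")
}

#' Representativeness scores
#'
#' For each unlabeled sample `x` in the reduced feature space,
#' `R(x) = d(x, mu_L) - d(x, mu_U)` where `mu_L` and `mu_U` are the
#' centroids (arithmetic means; a single K-Means cluster converges to the
#' mean) of the labeled and unlabeled reduced features and `d` is Euclidean
#' distance. High `R` marks samples typical of the unlabeled pool yet far
#' from the current training data.
#'
#' @param reduced_unlabeled,reduced_labeled `feature_matrix` objects sharing
#'   one PCA basis.
#' @return named numeric vector of `R` values over the unlabeled ids.
#' @export
representativeness_scores <- function(reduced_unlabeled, reduced_labeled) {
  stopifnot(inherits(reduced_unlabeled, "feature_matrix"),
            inherits(reduced_labeled, "feature_matrix"))
  if (nrow(reduced_labeled$rows) == 0) stopf("labeled feature set is empty")
  if (ncol(reduced_unlabeled$rows) != ncol(reduced_labeled$rows)) {
    stopf("labeled and unlabeled features must share one basis")
  }
  mu_l <- colMeans(reduced_labeled$rows)
  mu_u <- colMeans(reduced_unlabeled$rows)
  X <- reduced_unlabeled$rows
  r <- sqrt(rowSums(sweep(X, 2, mu_l, "-")^2)) -
       sqrt(rowSums(sweep(X, 2, mu_u, "-")^2))
  names(r) <- reduced_unlabeled$ids
  r
}

# shared basis for representative sampling: normalize and reduce L and U
# jointly so the centroid distances in R(x) are comparable
reduced_labeled_unlabeled <- function(pool, thumbnail_size,
                                      target_variance = 0.99) {
  l_ids <- pool$labeled_ids
  u_ids <- pool$unlabeled_ids
  all_samples <- pool_samples(pool, c(l_ids, u_ids))
  reduced <- reduce_features(all_samples, thumbnail_size, target_variance)
  if (is.null(reduced)) {
    d0 <- matrix(0, length(c(l_ids, u_ids)), 1)
    reduced <- feature_matrix(d0, c(l_ids, u_ids), "reduced")
  }
  list(labeled = feature_matrix(reduced$rows[l_ids, , drop = FALSE], l_ids,
                                "reduced"),
       unlabeled = feature_matrix(reduced$rows[u_ids, , drop = FALSE], u_ids,
                                  "reduced"))
}

#' Representative sampling query
#'
#' Scores every unlabeled sample with [representativeness_scores] (labeled
#' and unlabeled features normalized and PCA-reduced in one shared basis)
#' and selects the `n` highest-`R` ids; ties break by stable id order.
#'
#' @inheritParams cluster_query
#' @return a [query_result] carrying the per-id `R` scores.
#' @export
representative_query <- function(pool, n = 15L,
                                 thumbnail_size = c(64L, 64L),
                                 target_variance = 0.99) {
  check_unlabeled(pool)
  if (length(pool$labeled_ids) == 0) {
    stopf("representative sampling requires a non-empty labeled partition")
  }
  tm <- timed({
    rl <- reduced_labeled_unlabeled(pool, thumbnail_size, target_variance)
    r <- representativeness_scores(rl$unlabeled, rl$labeled)
    m <- min(n, length(r))
    list(ids = top_ids_by_score(r, m), scores = r)
  })
  query_result(tm$value$ids, scores = tm$value$scores,
               elapsed_seconds = tm$elapsed, query_name = "representative")
}

#' Class-wise entropy Monte Carlo Dropout query (CWE-MCD)
#'
#' Runs a `k`-pass Monte Carlo Dropout ensemble over the unlabeled pool,
#' averages the passes, scores each sample by class-wise Shannon entropy and
#' selects the `n` most uncertain ids (stable tie-break).
#'
#' @inheritParams random_query
#' @param model a trained segmenter with dropout support.
#' @param k number of MCD passes (default 30).
#' @param entropy entropy variant, see [class_wise_entropy].
#' @return a [query_result] carrying the per-id entropy scores.
#' @export
cwe_mcd_query <- function(pool, n = 15L, model, k = 30L, seed = 1L,
                          entropy = "literal") {
  check_unlabeled(pool)
  if (!seg_is_trained(model)) stopf("CWE-MCD requires a trained model")
  tm <- timed({
    samples <- pool_samples(pool, pool$unlabeled_ids)
    ens <- mc_ensemble(model, samples, k = k, seed = seed)
    e <- class_wise_entropy(mean_prediction(ens), variant = entropy)$scores
    m <- min(n, length(e))
    list(ids = top_ids_by_score(e, m), scores = e)
  })
  query_result(tm$value$ids, scores = tm$value$scores,
               elapsed_seconds = tm$elapsed, query_name = "cwe_mcd")
}

#' Borda-count rank fusion
#'
#' Combines several "higher is better" score maps over one id set. Within
#' each criterion the best of `m` ids receives `m - 1` points down to 0 for
#' the worst; tied ids share the mean of their point block (standard
#' fractional ranking). Combined points are the sum over criteria; the final
#' ordering is by descending combined points with ties broken by stable id
#' order. The fusion is invariant to the order of the criteria and to any
#' strictly increasing transformation of a criterion's scores.
#'
#' @param ... two or more named numeric score vectors covering the same ids.
#' @return an object of class `borda_ranking`: list with `points` (matrix,
#'   id x criterion), `combined` (named numeric) and `ordering` (ids, best
#'   first).
#' @export
borda_combine <- function(...) {
  maps <- list(...)
  if (length(maps) == 1L && is.list(maps[[1]]) && !is.numeric(maps[[1]])) {
    maps <- maps[[1]]
  }
  if (length(maps) < 2) stopf("Borda fusion needs at least two criteria")
  ids <- names(maps[[1]])
  if (is.null(ids)) stopf("score maps must be named by id")
  for (i in seq_along(maps)) {
    extra <- setdiff(names(maps[[i]]), ids)
    missing <- setdiff(ids, names(maps[[i]]))
    if (length(extra) || length(missing)) {
      stopf("criterion %d id set mismatch; missing: {%s}; extra: {%s}", i,
            paste(missing, collapse = ", "), paste(extra, collapse = ", "))
    }
  }
  points <- vapply(maps, function(s) rank(s[ids], ties.method = "average") - 1,
                   numeric(length(ids)))
  if (length(ids) == 1L) points <- matrix(points, nrow = 1)
  rownames(points) <- ids
  if (is.null(names(maps))) {
    colnames(points) <- paste0("criterion", seq_along(maps))
  }
  combined <- rowSums(points)
  names(combined) <- ids
  structure(list(points = points, combined = combined,
                 ordering = top_ids_by_score(combined, length(ids))),
            class = "borda_ranking")
}

#' @export
print.borda_ranking <- function(x, ...) {
  cat(sprintf("<borda_ranking> %d ids x %d criteria; best: %s\n",
              nrow(x$points), ncol(x$points), x$ordering[1]))
  invisible(x)
}

#' Representative CWE-MCD fusion query
#'
#' Computes the representativeness scores `R` and the class-wise entropy
#' scores `E` separately over the unlabeled pool, fuses the two rankings by
#' Borda count, and selects the `n` ids with the highest combined points.
#'
#' @inheritParams cwe_mcd_query
#' @inheritParams cluster_query
#' @return a [query_result] carrying the combined Borda points as scores.
#' @export
representative_cwe_mcd_query <- function(pool, n = 15L, model, k = 30L,
                                         seed = 1L,
                                         thumbnail_size = c(64L, 64L),
                                         target_variance = 0.99,
                                         entropy = "literal") {
  check_unlabeled(pool)
  if (!seg_is_trained(model)) stopf("CWE-MCD requires a trained model")
  if (length(pool$labeled_ids) == 0) {
    stopf("representative sampling requires a non-empty labeled partition")
  }
  tm <- timed({
    rl <- reduced_labeled_unlabeled(pool, thumbnail_size, target_variance)
    r <- representativeness_scores(rl$unlabeled, rl$labeled)
    samples <- pool_samples(pool, pool$unlabeled_ids)
    ens <- mc_ensemble(model, samples, k = k, seed = seed)
    e <- class_wise_entropy(mean_prediction(ens), variant = entropy)$scores
    fused <- borda_combine(representativeness = r, entropy = e)
    m <- min(n, length(fused$combined))
    list(ids = fused$ordering[seq_len(m)], scores = fused$combined)
  })
  query_result(tm$value$ids, scores = tm$value$scores,
               elapsed_seconds = tm$elapsed,
               query_name = "representative_cwe_mcd")
}

#' Registered query names
#' @return character vector of the five registered acquisition query names.
#' @export
al_queries <- function() {
  c("random", "cluster", "representative", "cwe_mcd", "representative_cwe_mcd")
}

#' Look up a query function by registered name
#'
#' @param name one of [al_queries()].
#' @return a function `(pool, n, model, k, seed, ...)` -> [query_result];
#'   queries that need no model or seed ignore those arguments.
#' @export
get_query <- function(name) {
  if (!name %in% al_queries()) {
    stopf("unknown query '%s'; registered: %s", name,
          paste(al_queries(), collapse = ", "))
  }
  switch(name,
    random = function(pool, n, model = NULL, k = 30L, seed = 1L,
                      thumbnail_size = c(64L, 64L), entropy = "literal") {
      random_query(pool, n, seed = seed)
    },
    cluster = function(pool, n, model = NULL, k = 30L, seed = 1L,
                       thumbnail_size = c(64L, 64L), entropy = "literal") {
      cluster_query(pool, n, seed = seed, thumbnail_size = thumbnail_size)
    },
    representative = function(pool, n, model = NULL, k = 30L, seed = 1L,
                              thumbnail_size = c(64L, 64L),
                              entropy = "literal") {
      representative_query(pool, n, thumbnail_size = thumbnail_size)
    },
    cwe_mcd = function(pool, n, model, k = 30L, seed = 1L,
                       thumbnail_size = c(64L, 64L), entropy = "literal") {
      cwe_mcd_query(pool, n, model, k = k, seed = seed, entropy = entropy)
    },
    representative_cwe_mcd = function(pool, n, model, k = 30L, seed = 1L,
                                      thumbnail_size = c(64L, 64L),
                                      entropy = "literal") {
      representative_cwe_mcd_query(pool, n, model, k = k, seed = seed,
                                   thumbnail_size = thumbnail_size,
                                   entropy = entropy)
    })
}
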