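#' Training-harness configuration
#'
#' Mirrors the training protocol of the experiment: Adam, learning rate
#' 1e-2, batch size 8 images, up to 500 epochs, learning rate reduced by a
#' factor of 0.1 after 8 epochs without improvement of the monitored
#' validation dice, early stopping after 10 such epochs.
#'
#' @param optimizer optimizer name (the reference segmenter implements
#'   `"adam"`).
#' @param learning_rate initial learning rate.
#' @param batch_size images per gradient step.
#' @param max_epochs epoch cap.
#' @param lr_factor multiplicative learning-rate reduction on plateau.
#' @param lr_patience epochs without improvement before reducing the rate.
#' @param early_stop_patience epochs without improvement before halting.
#' @param monitor monitored metric (validation macro dice).
#' @param pixels_per_image pixel rows subsampled per image per step
#'   (reference segmenter implementation knob).
#' @return an object of class `training_config`.
#' @export
training_config <- function(optimizer = "adam", learning_rate = 1e-2,
                            batch_size = 8L, max_epochs = 500L,
                            lr_factor = 0.1, lr_patience = 8L,
                            early_stop_patience = 10L, monitor = "val_dice",
                            pixels_per_image = 768L) {
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 monitor = monitor,
                 pixels_per_image = as.integer(pixels_per_image)),
            class = "training_config")
}

#' Active-learning experiment configuration
#'
#' @param query registered query name (see [al_queries]).
#' @param n acquisition batch size per iteration (default 15).
#' @param k Monte Carlo Dropout passes (default 30).
#' @param repeats full-cycle repetitions to average over (default 10).
#' @param fractions named split fractions `c(test=, validation=, initial=)`;
#'   defaults 15% / 15% / 3%, remainder to the unlabeled pool.
#' @param train a [training_config].
#' @param seed master seed; every random stream of the experiment derives
#'   from it.
#' @param entropy entropy variant for uncertainty queries
#'   (see [class_wise_entropy]).
#' @param thumbnail_size thumbnail for the feature-space queries.
#' @return an object of class `al_config`.
#' @export
al_config <- function(query = "random", n = 15L, k = 30L, repeats = 10L,
                      fractions = c(test = 0.15, validation = 0.15,
                                    initial = 0.03),
                      train = training_config(), seed = 1L,
                      entropy = "literal", thumbnail_size = c(64L, 64L)) {
  if (n < 1) stopf("n must be >= 1")
  if (repeats < 1) stopf("repeats must be >= 1")
  if (sum(fractions) > 1 + 1e-9) stopf("split fractions must sum to <= 1")
  stopifnot(inherits(train, "training_config"))
  structure(list(query = query, n = as.integer(n), k = as.integer(k),
                 repeats = as.integer(repeats), fractions = fractions,
                 train = train, seed = as.integer(seed), entropy = entropy,
                 thumbnail_size = thumbnail_size),
            class = "al_config")
}

query_needs_model <- function(name) {
  name %in% c("cwe_mcd", "representative_cwe_mcd")
}

evaluate_model <- function(model, samples) {
  preds <- seg_predict(model, samples)
  reports <- lapply(samples, function(s) {
    dice_score(preds[[s$id]], s$mask)
  })
  per_class <- rowMeans(vapply(reports, function(r) r$per_class, numeric(2)))
  list(macro = mean(vapply(reports, function(r) r$macro, numeric(1))),
       joint = mean(vapply(reports, function(r) r$joint, numeric(1))),
       femur = per_class[["femur"]], acetabulum = per_class[["acetabulum"]])
}

train_fresh <- function(model_factory, seed, labeled, validation, config) {
  model <- model_factory(seed)
  seg_train(model, labeled, validation, config$train)
}

#' Run one active-learning cycle
#'
#' The full experiment engine for a single repeat: starting from the initial
#' labeled set `L0` and unlabeled pool `U0`, each iteration `t` runs the
#' acquisition query on `U_t` (timed), reveals the held ground-truth masks
#' of the selected batch (the simulated oracle), retrains a fresh model from
#' scratch on `L_t`, and evaluates the test dice. The loop ends when the
#' pool is empty, after exactly `ceiling(|U0| / n)` acquisitions. Test and
#' validation sets never enter the pool.
#'
#' @param split a `corpus_split` (see [split_corpus]) with non-empty
#'   `initial_labeled`, `test` and `validation` components.
#' @param model_factory function `(seed) -> untrained segmenter`.
#' @param config an [al_config].
#' @param repeat_index identifier stored in the record (default 1).
#' @return an object of class `al_run_record`: a data.frame with one row per
#'   iteration `t = 0..T` and columns `query`, `repeat`, `iteration`,
#'   `n_labeled`, `dice_test_macro`, `dice_joint`, `dice_femur`,
#'   `dice_acetabulum`, `query_seconds` (`NA` at `t = 0`, where no query
#'   runs).
#' @export
run_al_cycle <- function(split, model_factory, config, repeat_index = 1L) {
  stopifnot(inherits(split, "corpus_split"), inherits(config, "al_config"))
  if (length(split$initial_labeled) == 0) stopf("initial labeled set is empty")
  if (length(split$test) == 0 || length(split$validation) == 0) {
    stopf("test and validation sets must be non-empty")
  }
  probe <- model_factory(derive_seed(config$seed, 0L, repeat_index))
  if (query_needs_model(config$query) && !seg_supports_dropout(probe)) {
    stopf("query '%s' needs Monte Carlo Dropout but the model factory %s",
          config$query, "produces a dropout-free model")
  }
  qfun <- get_query(config$query)
  pool <- make_pool(c(split$initial_labeled, split$unlabeled),
                    labeled_ids = sample_ids(split$initial_labeled))
  total <- length(pool$samples)

  rows <- list()
  model <- train_fresh(model_factory,
                       derive_seed(config$seed, 1L, repeat_index * 1000L),
                       pool_samples(pool, pool$labeled_ids),
                       split$validation, config)
  ev <- evaluate_model(model, split$test)
  rows[[1]] <- data.frame(query = config$query, "repeat" = repeat_index,
                          iteration = 0L,
                          n_labeled = length(pool$labeled_ids),
                          dice_test_macro = ev$macro, dice_joint = ev$joint,
                          dice_femur = ev$femur,
                          dice_acetabulum = ev$acetabulum,
                          query_seconds = NA_real_, check.names = FALSE)
  t <- 0L
  while (length(pool$unlabeled_ids) > 0) {
    t <- t + 1L
    qseed <- derive_seed(config$seed, 2L, repeat_index * 1000L + t)
    qr <- qfun(pool, config$n, model = model, k = config$k, seed = qseed,
               thumbnail_size = config$thumbnail_size,
               entropy = config$entropy)
    pool <- move_to_labeled(pool, qr$selected_ids)
    stopifnot(length(pool$labeled_ids) + length(pool$unlabeled_ids) == total)
    model <- train_fresh(model_factory,
                         derive_seed(config$seed, 1L,
                                     repeat_index * 1000L + t),
                         pool_samples(pool, pool$labeled_ids),
                         split$validation, config)
    ev <- evaluate_model(model, split$test)
    rows[[t + 1L]] <- data.frame(query = config$query,
                                 "repeat" = repeat_index, iteration = t,
                                 n_labeled = length(pool$labeled_ids),
                                 dice_test_macro = ev$macro,
                                 dice_joint = ev$joint,
                                 dice_femur = ev$femur,
                                 dice_acetabulum = ev$acetabulum,
                                 query_seconds = qr$elapsed_seconds,
                                 check.names = FALSE)
  }
  record <- do.call(rbind, rows)
  class(record) <- c("al_run_record", class(record))
  record
}

#' Run a repeated active-learning experiment
#'
#' Repeats the full AL cycle `config$repeats` times, each with a distinct
#' seed derived from the master seed by a fixed counter scheme, and averages
#' the per-iteration metrics across repeats.
#'
#' @param split a `corpus_split`, or a function `(seed) -> corpus_split` to
#'   regenerate the corpus per repeat.
#' @inheritParams run_al_cycle
#' @return an object of class `al_experiment`: list with `records` (row-bound
#'   [run_al_cycle] records) and `average` (data.frame of per-iteration mean
#'   dice and query time across repeats).
#' @export
run_experiment <- function(split, model_factory, config) {
  stopifnot(inherits(config, "al_config"))
  records <- lapply(seq_len(config$repeats), function(r) {
    cfg_r <- config
    cfg_r$seed <- derive_seed(config$seed, 3L, r)
    sp <- if (is.function(split)) split(cfg_r$seed) else split
    run_al_cycle(sp, model_factory, cfg_r, repeat_index = r)
  })
  all_rows <- do.call(rbind, records)
  avg <- stats::aggregate(
    all_rows[c("n_labeled", "dice_test_macro", "dice_joint", "dice_femur",
               "dice_acetabulum", "query_seconds")],
    by = list(query = all_rows$query, iteration = all_rows$iteration),
    FUN = function(v) mean(v))  # query_seconds at t=0 stays NA
  avg <- avg[order(avg$iteration), , drop = FALSE]
  rownames(avg) <- NULL
  structure(list(records = all_rows, average = avg, config = config),
            class = "al_experiment")
}

#' @export
print.al_experiment <- function(x, ...) {
  cat(sprintf("<al_experiment> query '%s', %d repeats, %d iterations\n",
              x$config$query, x$config$repeats, max(x$average$iteration)))
  print(x$average[, c("iteration", "n_labeled", "dice_test_macro")],
        row.names = FALSE)
  invisible(x)
}

#' Fully-supervised upper bound
#'
#' Trains a fresh model once on everything trainable (`L0` plus the whole
#' unlabeled pool with labels revealed) and evaluates on the test set. This
#' is the performance ceiling the AL curves are compared against.
#'
#' @inheritParams run_al_cycle
#' @return a list with `dice` (test [dice_score]-style summary) and
#'   `n_labeled` (training-set size used).
#' @export
run_upper_bound <- function(split, model_factory, config) {
  stopifnot(inherits(split, "corpus_split"), inherits(config, "al_config"))
  labeled <- c(split$initial_labeled, split$unlabeled)
  model <- train_fresh(model_factory, derive_seed(config$seed, 4L, 0L),
                       labeled, split$validation, config)
  ev <- evaluate_model(model, split$test)
  list(dice = ev, n_labeled = length(labeled))
}
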