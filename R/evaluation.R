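#' Fraction of correctly identified windows
#'
#' @param predicted,truth Equal-length integer label vectors.
#' @return The exact-match fraction in `[0, 1]`.
#' @export
compute_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("alignment error: predicted and truth differ in length")
  if (length(truth) == 0L) stop("empty label sequences")
  mean(as.integer(predicted) == as.integer(truth))
}

#' Confusion matrix of an identification run
#'
#' @param predicted,truth Integer label vectors with values in `[0, K)`.
#' @param K Number of classes.
#' @return A `K x K` integer matrix; entry `(i, j)` counts windows of true
#'   class `i - 1` predicted as class `j - 1`.
#' @export
confusion_matrix <- function(predicted, truth, K) {
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  K <- as.integer(K)
  if (length(predicted) != length(truth))
    stop("alignment error: predicted and truth differ in length")
  if (length(truth) > 0L &&
      (min(predicted, truth) < 0L || max(predicted, truth) >= K))
    stop(sprintf("domain error: labels must lie in [0, %d)", K))
  m <- matrix(tabulate(truth * K + predicted + 1L, nbins = K * K),
              nrow = K, byrow = TRUE)
  dimnames(m) <- list(true = as.character(0:(K - 1L)),
                      predicted = as.character(0:(K - 1L)))
  m
}

#' Score a trained classifier on a test window set
#'
#' @param fit A trained [gait_fit] (or `gait_model`).
#' @param test A [window_set()] of held-out windows.
#' @return An object of class `eval_report`: list with `accuracy`,
#'   `confusion` (rows = true class), `n_test` and `label_names`.
#' @export
evaluate_model <- function(fit, test) {
  stopifnot(inherits(test, "window_set"))
  model <- if (inherits(fit, "gait_fit")) fit$model else fit
  pred <- identify(model, test)
  K <- model$config$n_classes
  structure(list(accuracy = compute_accuracy(pred, test$labels),
                 confusion = confusion_matrix(pred, test$labels, K),
                 n_test = n_windows(test),
                 label_names = test$label_names),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.2f%% on %d test windows (%d subjects)\n",
              100 * x$accuracy, x$n_test, nrow(x$confusion)))
  invisible(x)
}

#' Repeated runs over a set of split seeds
#'
#' Re-splits, re-trains and re-tests the classifier once per repeat for
#' each split seed, mirroring the protocol of reporting a mean and variance
#' per seed group. Within a group the split is fixed by the seed; repeats
#' differ in the training seed (derived as `1000 * seed + repeat`).
#'
#' @param windows A full (unsplit) [window_set()].
#' @param arch An [arch_config()] template; its `n_classes`, `window_len`
#'   and `n_features` are set from the data.
#' @param config A [train_config()]; its seed is overridden per repeat.
#' @param seeds Integer vector of split seeds (default `c(10, 20, 40, 50)`).
#' @param repeats Runs per seed group (default 3).
#' @param test_fraction Held-out fraction (default 0.3).
#' @return A data frame of class `experiment_table` with one row per seed:
#'   `seed`, `n_runs`, `n_train`, `n_test`, `mean_accuracy`,
#'   `var_accuracy` (population variance across the runs in the group).
#'   Per-run accuracies are kept in `attr(, "runs")`.
#' @export
seeded_repeats <- function(windows, arch, config, seeds = c(10L, 20L, 40L, 50L),
                           repeats = 3L, test_fraction = 0.3) {
  stopifnot(length(seeds) >= 1L, repeats >= 1L)
  arch <- adapt_arch(arch, windows)
  runs <- data.frame()
  for (s in seeds) {
    sp <- split_train_test(windows, test_fraction, seed = s)
    for (r in seq_len(repeats)) {
      cfg <- config
      cfg$seed <- as.integer(1000L * s + r)
      fit <- train_model(build_architecture(arch), sp$train, config = cfg)
      rep_ <- evaluate_model(fit, sp$test)
      runs <- rbind(runs, data.frame(seed = s, run = r,
                                     n_train = n_windows(sp$train),
                                     n_test = n_windows(sp$test),
                                     accuracy = rep_$accuracy))
    }
  }
  tab <- do.call(rbind, lapply(split(runs, runs$seed), function(g) {
    data.frame(seed = g$seed[1L], n_runs = nrow(g), n_train = g$n_train[1L],
               n_test = g$n_test[1L], mean_accuracy = mean(g$accuracy),
               var_accuracy = mean((g$accuracy - mean(g$accuracy))^2))
  }))
  tab <- tab[order(match(tab$seed, seeds)), ]
  rownames(tab) <- NULL
  attr(tab, "runs") <- runs
  class(tab) <- c("experiment_table", class(tab))
  tab
}

#' Accelerometer/gyroscope ablation on a shared split
#'
#' Trains three classifiers on the same train/test partition: vertical
#' acceleration only, vertical rotation only, and both channels fused into
#' a two-feature window, then scores each on the shared test windows.
#'
#' @param acc_ws,gyro_ws Single-channel [window_set()]s built from the
#'   accelerometer and gyroscope projections of the same recordings (equal
#'   window grid and labels).
#' @param arch Architecture template (features/classes adapted per run).
#' @param config A [train_config()].
#' @param test_fraction,seed Split parameters shared by the three runs.
#' @return An `experiment_table` data frame with rows `acc_only`,
#'   `gyro_only`, `fused` and columns `condition`, `n_features`, `n_train`,
#'   `n_test`, `accuracy`.
#' @export
sensor_ablation <- function(acc_ws, gyro_ws, arch, config,
                            test_fraction = 0.3, seed = 10L) {
  fused <- ws_bind_features(acc_ws, gyro_ws)  # also validates alignment
  conditions <- list(acc_only = acc_ws, gyro_only = gyro_ws, fused = fused)
  n <- n_windows(acc_ws)
  perm_split <- split_train_test(acc_ws, test_fraction, seed = seed)
  rows <- lapply(names(conditions), function(nm) {
    ws <- conditions[[nm]]
    tr <- ws_subset(ws, perm_split$train_idx)
    te <- ws_subset(ws, perm_split$test_idx)
    a <- adapt_arch(arch, ws)
    fit <- train_model(build_architecture(a), tr, config = config)
    data.frame(condition = nm, n_features = dim(ws$windows)[3L],
               n_train = n_windows(tr), n_test = n_windows(te),
               accuracy = evaluate_model(fit, te)$accuracy)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  class(tab) <- c("experiment_table", class(tab))
  tab
}

#' Window-size sweep
#'
#' Re-packages the same preprocessed corpus at several window lengths,
#' resizes the network input accordingly (the LSTM stack always spans as
#' many timesteps as the window holds), re-splits with the same seed, and
#' reports accuracy per size.
#'
#' @param corpus A list with one entry per subject, each a named list of
#'   time-aligned [scalar_series()] channels (as returned by
#'   [preprocess_recording()]).
#' @param sizes Integer window lengths to try (each stride is
#'   `floor(T / 2)`).
#' @param arch Architecture template; `window_len` is overridden per size.
#' @param config A [train_config()].
#' @param test_fraction,seed Split parameters (the split is redrawn per
#'   size because re-windowing changes the number of windows).
#' @param features Channel names to use (default first channel of each
#'   subject).
#' @return An `experiment_table` data frame: `window_len`, `duration_s`,
#'   `n_train`, `n_test`, `accuracy`. Sizes exceeding the shortest series
#'   are skipped with a warning.
#' @export
window_size_sweep <- function(corpus, sizes, arch, config,
                              test_fraction = 0.3, seed = 10L,
                              features = NULL) {
  stopifnot(length(sizes) >= 1L, all(sizes >= 2L))
  fs <- corpus[[1L]][[1L]]$sampling_rate_hz
  shortest <- min(vapply(corpus, function(u) length(u[[1L]]$values), integer(1L)))
  rows <- list()
  for (T_ in as.integer(sizes)) {
    if (T_ > shortest) {
      warning(sprintf("window length %d exceeds the shortest series (%d); skipped",
                      T_, shortest))
      next
    }
    ws <- corpus_windows(corpus, window_len = T_, stride = max(1L, T_ %/% 2L),
                         features = features)
    sp <- split_train_test(ws, test_fraction, seed = seed)
    a <- adapt_arch(arch, ws)
    fit <- train_model(build_architecture(a), sp$train, config = config)
    rows[[length(rows) + 1L]] <-
      data.frame(window_len = T_, duration_s = T_ / fs,
                 n_train = n_windows(sp$train), n_test = n_windows(sp$test),
                 accuracy = evaluate_model(fit, sp$test)$accuracy)
  }
  if (length(rows) == 0L) stop("no window size was usable")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  class(tab) <- c("experiment_table", class(tab))
  tab
}

# internal: fit an architecture template to a window set's shape; the gate
# bias init offset is the known DC level of each channel (gravity for
# vertical acceleration, zero for vertical rotation)
adapt_arch <- function(arch, ws) {
  stopifnot(inherits(arch, "arch_config"))
  arch$window_len <- ws$window_len
  arch$n_features <- dim(ws$windows)[3L]
  arch$n_classes <- length(ws$label_names)
  arch$input_offset <- ifelse(ws$feature_names == "vertical_acceleration",
                              9.81, 0)
  arch
}

#' Package a preprocessed multi-subject corpus into one labeled window set
#'
#' @param corpus List with one entry per subject: a named list of
#'   time-aligned [scalar_series()] channels.
#' @param window_len,stride Window geometry (defaults 150 / 75).
#' @param features Character vector of channel names to include; `NULL`
#'   uses the first channel only.
#' @return A merged [window_set()] with subjects labeled `0 .. K-1` in
#'   corpus order.
#' @export
corpus_windows <- function(corpus, window_len = 150L,
                           stride = max(1L, floor(window_len / 2)),
                           features = NULL) {
  stopifnot(length(corpus) >= 1L)
  if (is.null(features)) features <- names(corpus[[1L]])[1L]
  subj_names <- vapply(corpus, function(u) u[[1L]]$subject_id, character(1L))
  sets <- lapply(seq_along(corpus), function(i) {
    chans <- corpus[[i]][features]
    if (any(vapply(chans, is.null, logical(1L))))
      stop(sprintf("subject '%s' lacks channel(s) %s", subj_names[i],
                   paste(setdiff(features, names(corpus[[i]])), collapse = ", ")))
    make_windows(chans, window_len = window_len, stride = stride, label = 0L)
  })
  merge_cohorts(sets)
}

#' Write an experiment table to CSV
#'
#' @param table An `experiment_table` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_experiment_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read an experiment table back from CSV
#'
#' @param path CSV path written by [write_experiment_csv()].
#' @return The `experiment_table` data frame.
#' @export
read_experiment_csv <- function(path) {
  tab <- utils::read.csv(path)
  class(tab) <- c("experiment_table", class(tab))
  tab
}
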