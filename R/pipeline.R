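#' Run the full identification pipeline on a recorded or simulated corpus
#'
#' Preprocesses every subject's recording (gravity estimation, vertical
#' projection, edge trimming), packages the requested channels into labeled
#' windows, splits train/test, trains the classifier and scores it on the
#' held-out windows.
#'
#' @param recordings Named list with one entry per subject, each a list with
#'   an accelerometer series `acc` and optionally a gyroscope series `gyro`
#'   (the `recordings` field of [simulate_cohort()], or [read_cohort()]
#'   output).
#' @param features Channels to classify on: subset of
#'   `c("vertical_acceleration", "vertical_rotation")`.
#' @param half_window_m Gravity half-window in samples (default 150).
#' @param trim_samples Samples trimmed from each end (default 150).
#' @param window_len,stride Window geometry (defaults 150 / 75).
#' @param arch An [arch_config()] template (shape fields adapted to the
#'   data).
#' @param config A [train_config()].
#' @param test_fraction,split_seed Train/test split parameters.
#' @return A list of class `pipeline_result`: `fit` ([train_model()]
#'   result), `report` ([evaluate_model()] result), `split`, `windows` and
#'   the preprocessed `corpus`.
#' @export
run_identification <- function(recordings,
                               features = "vertical_acceleration",
                               half_window_m = 150L, trim_samples = 150L,
                               window_len = 150L,
                               stride = max(1L, floor(window_len / 2)),
                               arch = arch_preset("ID1"),
                               config = train_config(),
                               test_fraction = 0.3, split_seed = 10L) {
  corpus <- lapply(recordings, function(r) {
    preprocess_recording(r$acc, gyro = r$gyro, half_window_m = half_window_m,
                         trim_samples = trim_samples)
  })
  ws <- corpus_windows(corpus, window_len = window_len, stride = stride,
                       features = features)
  sp <- split_train_test(ws, test_fraction, seed = split_seed)
  a <- adapt_arch(arch, ws)
  fit <- train_model(build_architecture(a), sp$train, config = config)
  structure(list(fit = fit, report = evaluate_model(fit, sp$test),
                 split = sp, windows = ws, corpus = corpus),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}
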