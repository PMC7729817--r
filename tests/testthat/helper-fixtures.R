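# Shared fixtures, built in code and memoized across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

# small random triaxial series on a uniform grid
random_series <- function(n = 400, fs = 50, sensor = "accelerometer",
                          subject = "s0", seed = 1) {
  withr::with_seed(seed, {
    t <- (seq_len(n) - 1) / fs
    base <- if (sensor == "accelerometer") c(0, 0, 9.81) else c(0, 0, 0)
    xyz <- matrix(rep(base, each = n), n, 3) +
      matrix(rnorm(3 * n, sd = 0.8), n, 3) +
      2 * sin(2 * pi * 1.9 * t)
    triaxial_series(t, xyz, sensor = sensor, subject_id = subject,
                    sampling_rate_hz = fs)
  })
}

# apply a fixed rotation to the sensor frame of a series
rotate_series <- function(series, R) {
  triaxial_series(series$time_s, series$xyz %*% t(R), sensor = series$sensor,
                  subject_id = series$subject_id,
                  sampling_rate_hz = series$sampling_rate_hz)
}

# a tiny architecture that trains in milliseconds; shapes only
tiny_arch <- function(window_len = 10L, n_features = 1L, n_classes = 2L) {
  arch_config(window_len = window_len, n_features = n_features,
              lstm_units = c(3L, 4L), dense_units = 5L, n_classes = n_classes)
}

# directly constructed separable window set (no pipeline), K classes by
# oscillation frequency
toy_window_set <- function(n = 60, window_len = 20L, K = 2L, seed = 3,
                           offset = 0) {
  withr::with_seed(seed, {
    t <- (seq_len(window_len) - 1) / 50
    w <- array(0, dim = c(n, window_len, 1L))
    lab <- (seq_len(n) - 1L) %% K
    for (i in seq_len(n)) {
      f <- 1.4 + lab[i] * 1.0 / max(1, K - 1)
      w[i, , 1L] <- offset + 2 * sin(2 * pi * f * t + runif(1, 0, 2 * pi)) +
        rnorm(window_len, sd = 0.2)
    }
    window_set(w, lab, paste0("s", seq_len(K) - 1L), "vertical_acceleration",
               stride = window_len)
  })
}

# the standard easy cohort used by the end-to-end checks (memoized: the
# simulation is cheap but the preprocessed corpus is reused many times)
easy_cohort <- function() {
  memo("easy_cohort", function() {
    simulate_cohort(8, duration_s = 120, fs_hz = 50, seed = 7,
                    separability = "easy")
  })
}

easy_corpus <- function() {
  memo("easy_corpus", function() {
    lapply(easy_cohort()$recordings,
           function(r) preprocess_recording(r$acc, gyro = r$gyro))
  })
}
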