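#' Sliding per-axis mean vectors
#'
#' For every sample i, averages each axis over the centered window of the
#' `m` previous and `m` following samples (indices `[i - m, i + m]`,
#' truncated at the series edges). The mean vector approximates the constant
#' gravity component in the sensor frame: gait oscillations average out over
#' a window that spans several strides, leaving the (orientation-dependent)
#' projection of gravity onto the device axes.
#'
#' @param series A [triaxial_series()].
#' @param half_window_m Positive integer half-window `m` in samples.
#'   The default 150 gives a `2 m = 300` sample (6 s at 50 Hz) window.
#' @return An object of class `mean_vector_track`: list with `means`
#'   (L x 3 matrix), `half_window_m` and `source_sensor`.
#' @export
sliding_mean_vectors <- function(series, half_window_m = 150L) {
  stopifnot(inherits(series, "triaxial_series"))
  m <- as.integer(half_window_m)
  if (is.na(m) || m < 1L)
    stop("half_window_m must be a positive integer")
  L <- nrow(series$xyz)
  if (L < 1L) stop("insufficient data: empty series")
  idx <- seq_len(L)
  lo <- pmax(1L, idx - m)
  hi <- pmin(L, idx + m)
  # prefix sums give every truncated-window mean in O(L)
  cs <- rbind(0, apply(series$xyz, 2L, cumsum))
  means <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
  colnames(means) <- c("x", "y", "z")
  structure(list(means = means, half_window_m = m,
                 source_sensor = series$sensor),
            class = "mean_vector_track")
}

#' Normalize mean vectors to unit gravity estimates
#'
#' Divides each windowed mean vector by its Euclidean norm, yielding the
#' per-sample unit vector pointing along the estimated gravity direction in
#' the sensor frame.
#'
#' @param means A [sliding_mean_vectors()] result.
#' @return An object of class `gravity_track`: list with `unit` (L x 3
#'   matrix of unit vectors), `half_window_m` and `source_sensor`.
#' @export
to_unit_gravity <- function(means) {
  stopifnot(inherits(means, "mean_vector_track"))
  nrm <- sqrt(rowSums(means$means^2))
  bad <- which(nrm < 1e-12)
  if (length(bad) > 0L)
    stop(sprintf(paste0("degenerate gravity estimate at index %d (|mean| < 1e-12); ",
                        "the sensor appears stationary or zeroed"), bad[1L]))
  structure(list(unit = means$means / nrm, half_window_m = means$half_window_m,
                 source_sensor = means$source_sensor),
            class = "gravity_track")
}

#' Estimate the gravity track of a recording
#'
#' Convenience composition of [sliding_mean_vectors()] and
#' [to_unit_gravity()].
#'
#' @inheritParams sliding_mean_vectors
#' @return A `gravity_track`.
#' @export
estimate_gravity <- function(series, half_window_m = 150L) {
  to_unit_gravity(sliding_mean_vectors(series, half_window_m))
}

#' Scalar series of projected samples
#'
#' One real value per time step: the vertical acceleration `acc_g` (m/s^2)
#' or vertical rotation rate `w_g` (rad/s), i.e. the scalar projection of
#' the tri-axial sample onto the estimated unit gravity vector.
#'
#' @param values Finite numeric vector.
#' @param quantity `"vertical_acceleration"` or `"vertical_rotation"`.
#' @param subject_id Opaque subject label.
#' @param sampling_rate_hz Positive sampling rate in Hz.
#' @return An object of class `scalar_series`.
#' @export
scalar_series <- function(values,
                          quantity = c("vertical_acceleration", "vertical_rotation"),
                          subject_id = "unknown", sampling_rate_hz = 50) {
  quantity <- match.arg(quantity)
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("scalar series values must be finite")
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be a positive real")
  structure(list(values = values, quantity = quantity,
                 subject_id = as.character(subject_id),
                 sampling_rate_hz = as.numeric(sampling_rate_hz)),
            class = "scalar_series")
}

#' @export
print.scalar_series <- function(x, ...) {
  cat(sprintf("<scalar_series> %s, subject '%s', %d samples @ %.2f Hz\n",
              x$quantity, x$subject_id, length(x$values), x$sampling_rate_hz))
  invisible(x)
}

#' @export
length.scalar_series <- function(x) length(x$values)

#' Project acceleration onto the gravity direction
#'
#' Computes the vertical acceleration `acc_g[i] = acc[i] . g_hat[i]`, the dot
#' product of each tri-axial accelerometer sample with the unit gravity
#' vector estimated at the same instant. The projection is signed and
#' (approximately) independent of how the device was oriented on the body.
#'
#' @param series An accelerometer [triaxial_series()].
#' @param gravity A [estimate_gravity()] track derived from the same series.
#' @return A [scalar_series()] with quantity `"vertical_acceleration"`.
#' @export
project_vertical_acceleration <- function(series, gravity) {
  stopifnot(inherits(series, "triaxial_series"), inherits(gravity, "gravity_track"))
  if (series$sensor != "accelerometer")
    stop("vertical acceleration requires an accelerometer series")
  if (nrow(series$xyz) != nrow(gravity$unit))
    stop("alignment error: series and gravity track differ in length")
  scalar_series(rowSums(series$xyz * gravity$unit),
                quantity = "vertical_acceleration",
                subject_id = series$subject_id,
                sampling_rate_hz = series$sampling_rate_hz)
}

#' Project angular velocity onto the gravity direction
#'
#' Computes the vertical rotation rate `w_g[i] = w[i] . g_hat[i]`. The unit
#' gravity track must come from the time-aligned accelerometer channel of
#' the same recording — gyroscope means carry no gravity information.
#'
#' @param gyro A gyroscope [triaxial_series()].
#' @param gravity A `gravity_track` built from the accelerometer channel.
#' @return A [scalar_series()] with quantity `"vertical_rotation"`.
#' @export
project_vertical_rotation <- function(gyro, gravity) {
  stopifnot(inherits(gyro, "triaxial_series"), inherits(gravity, "gravity_track"))
  if (gyro$sensor != "gyroscope")
    stop("vertical rotation requires a gyroscope series")
  if (!identical(gravity$source_sensor, "accelerometer"))
    stop("usage error: the gravity track must be estimated from the accelerometer channel")
  if (nrow(gyro$xyz) != nrow(gravity$unit))
    stop("alignment error: gyroscope series and gravity track differ in length")
  scalar_series(rowSums(gyro$xyz * gravity$unit),
                quantity = "vertical_rotation",
                subject_id = gyro$subject_id,
                sampling_rate_hz = gyro$sampling_rate_hz)
}

#' Trim the edges of a scalar series
#'
#' Removes `trim_samples` values from each end. The first and last moments
#' of a walk typically capture the subject starting and stopping, where the
#' oscillation is weak and uninformative.
#'
#' @param series A [scalar_series()].
#' @param trim_samples Non-negative integer; `2 * trim_samples` must be
#'   smaller than the series length. Default 150 samples (3 s at 50 Hz).
#' @return The trimmed `scalar_series` (metadata preserved).
#' @export
trim_edges <- function(series, trim_samples = 150L) {
  stopifnot(inherits(series, "scalar_series"))
  k <- as.integer(trim_samples)
  if (is.na(k) || k < 0L) stop("trim_samples must be a non-negative integer")
  L <- length(series$values)
  if (2L * k >= L)
    stop(sprintf("insufficient data: cannot trim %d samples from each end of %d", k, L))
  if (k == 0L) return(series)
  series$values <- series$values[(k + 1L):(L - k)]
  series
}

#' Preprocess one recording into orientation-invariant scalar channels
#'
#' Full preprocessing chain: gravity estimation from the accelerometer,
#' projection of the accelerometer (and optionally the synchronized
#' gyroscope) onto the gravity direction, then edge trimming.
#'
#' @param acc Accelerometer [triaxial_series()].
#' @param gyro Optional gyroscope `triaxial_series` sharing timestamps with
#'   `acc`.
#' @param half_window_m Gravity half-window in samples (default 150).
#' @param trim_samples Samples trimmed from each end (default 150).
#' @return A named list of [scalar_series()]: `vertical_acceleration` and,
#'   when `gyro` is given, `vertical_rotation`.
#' @export
preprocess_recording <- function(acc, gyro = NULL, half_window_m = 150L,
                                 trim_samples = 150L) {
  gravity <- estimate_gravity(acc, half_window_m)
  out <- list(vertical_acceleration =
                trim_edges(project_vertical_acceleration(acc, gravity), trim_samples))
  if (!is.null(gyro)) {
    if (length(gyro$time_s) != length(acc$time_s))
      stop("alignment error: accelerometer and gyroscope lengths differ")
    out$vertical_rotation <-
      trim_edges(project_vertical_rotation(gyro, gravity), trim_samples)
  }
  out
}
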