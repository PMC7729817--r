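#' Tri-axial sensor series
#'
#' Container for one timestamped X/Y/Z stream recorded by a single inertial
#' sensor (accelerometer in m/s^2 or gyroscope in rad/s) on one subject.
#'
#' @param time_s Numeric vector of timestamps in seconds, strictly increasing.
#' @param xyz Numeric matrix with 3 columns (x, y, z), one row per timestamp.
#' @param sensor Either `"accelerometer"` or `"gyroscope"`.
#' @param subject_id Opaque subject label (coerced to character).
#' @param sampling_rate_hz Nominal sampling rate in Hz. If `NULL`, estimated
#'   as `(n - 1) / (t_last - t_first)`.
#'
#' @return An object of class `triaxial_series`: a list with fields
#'   `subject_id`, `sensor`, `sampling_rate_hz`, `time_s` and `xyz`.
#' @export
triaxial_series <- function(time_s, xyz, sensor = c("accelerometer", "gyroscope"),
                            subject_id = "unknown", sampling_rate_hz = NULL) {
  sensor <- match.arg(sensor)
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  time_s <- as.numeric(time_s)
  if (ncol(xyz) != 3L)
    stop("`xyz` must have exactly 3 columns (x, y, z)")
  if (length(time_s) != nrow(xyz))
    stop("length(time_s) must equal nrow(xyz)")
  if (length(time_s) < 1L)
    stop("insufficient data: empty series")
  if (anyNA(time_s) || anyNA(xyz) || any(!is.finite(xyz)))
    stop("timestamps and samples must be finite and non-missing")
  if (length(time_s) > 1L && any(diff(time_s) <= 0))
    stop("ordering error: timestamps must be strictly increasing")
  if (is.null(sampling_rate_hz)) {
    if (length(time_s) < 2L)
      stop("insufficient data: need >= 2 samples to estimate the sampling rate")
    sampling_rate_hz <- (length(time_s) - 1) / (time_s[length(time_s)] - time_s[1L])
  }
  sampling_rate_hz <- as.numeric(sampling_rate_hz)
  if (!is.finite(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be a positive real")
  colnames(xyz) <- c("x", "y", "z")
  structure(
    list(subject_id = as.character(subject_id), sensor = sensor,
         sampling_rate_hz = sampling_rate_hz, time_s = time_s, xyz = xyz),
    class = "triaxial_series")
}

#' @export
print.triaxial_series <- function(x, ...) {
  cat(sprintf("<triaxial_series> subject '%s', %s, %d samples @ %.2f Hz (%.1f s)\n",
              x$subject_id, x$sensor, length(x$time_s), x$sampling_rate_hz,
              diff(range(x$time_s))))
  invisible(x)
}

#' @export
length.triaxial_series <- function(x) length(x$time_s)

#' CSV column dialects for sensor logs
#'
#' A dialect names the timestamp and axis columns of a sensor CSV export and
#' declares the timestamp unit. `csv_dialect()` builds one;
#' `csv_dialect_sdc()` is the Sensor-Data-Collector-style export
#' (`attr_time`/`attr_x`/`attr_y`/`attr_z`, milliseconds) and
#' `csv_dialect_generic()` the plain `t,x,y,z` layout in seconds.
#'
#' @param time,x,y,z Column names in the CSV header.
#' @param time_unit `"s"` or `"ms"`.
#' @return A list of class `csv_dialect`.
#' @export
csv_dialect <- function(time = "t", x = "x", y = "y", z = "z",
                        time_unit = c("s", "ms")) {
  time_unit <- match.arg(time_unit)
  structure(list(time = time, x = x, y = y, z = z, time_unit = time_unit),
            class = "csv_dialect")
}

#' @rdname csv_dialect
#' @export
csv_dialect_sdc <- function() {
  csv_dialect(time = "attr_time", x = "attr_x", y = "attr_y", z = "attr_z",
              time_unit = "ms")
}

#' @rdname csv_dialect
#' @export
csv_dialect_generic <- function() csv_dialect()

#' Read a tri-axial sensor log from CSV
#'
#' Parses a comma-separated sensor export into a validated
#' [triaxial_series()]. Rows with missing values are dropped and counted;
#' duplicated timestamps are collapsed (first occurrence kept) with a
#' warning; timestamps that go backwards are an error. Timestamp gaps larger
#' than 3 nominal sampling periods are counted in the load report but not
#' repaired.
#'
#' @param path Path to an existing CSV file with a header row.
#' @param dialect A [csv_dialect()]. The default `NULL` tries the
#'   Sensor-Data-Collector layout first, then the generic `t,x,y,z` layout.
#' @inheritParams triaxial_series
#'
#' @return A `triaxial_series` with an attribute `"load_report"`: a list with
#'   `n_rows_read`, `n_dropped_na`, `n_dropped_dup` and `n_gaps` (gaps longer
#'   than 3 nominal periods).
#' @export
read_triaxial_csv <- function(path, dialect = NULL,
                              sensor = c("accelerometer", "gyroscope"),
                              subject_id = "unknown") {
  sensor <- match.arg(sensor)
  if (!file.exists(path))
    stop(sprintf("file not found: '%s'", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (is.null(dialect)) {
    dialect <- if (all(unlist(csv_dialect_sdc()[c("time", "x", "y", "z")]) %in%
                       names(df))) csv_dialect_sdc() else csv_dialect_generic()
  }
  need <- unlist(dialect[c("time", "x", "y", "z")])
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop(sprintf("format error: missing column(s) %s in '%s'",
                 paste(sQuote(missing_cols), collapse = ", "), path))
  tm <- as.numeric(df[[dialect$time]])
  xyz <- cbind(as.numeric(df[[dialect$x]]), as.numeric(df[[dialect$y]]),
               as.numeric(df[[dialect$z]]))
  n_read <- length(tm)
  ok <- is.finite(tm) & is.finite(xyz[, 1L]) & is.finite(xyz[, 2L]) &
    is.finite(xyz[, 3L])
  n_na <- sum(!ok)
  tm <- tm[ok]; xyz <- xyz[ok, , drop = FALSE]
  if (dialect$time_unit == "ms") tm <- tm / 1000
  n_dup <- 0L
  if (length(tm) > 1L) {
    d <- diff(tm)
    if (any(d < 0))
      stop("ordering error: timestamps decrease; the log is not time-sorted")
    if (any(d == 0)) {
      keep <- c(TRUE, d > 0)
      n_dup <- sum(!keep)
      warning(sprintf("dropped %d duplicated timestamp(s) in '%s'", n_dup, path))
      tm <- tm[keep]; xyz <- xyz[keep, , drop = FALSE]
    }
  }
  if (length(tm) < 2L)
    stop(sprintf("insufficient data: fewer than 2 valid rows in '%s'", path))
  series <- triaxial_series(tm, xyz, sensor = sensor, subject_id = subject_id)
  n_gaps <- sum(diff(tm) > 3 / series$sampling_rate_hz)
  if (n_gaps > 0L)
    message(sprintf("'%s': %d gap(s) longer than 3 nominal periods (left unrepaired)",
                    path, n_gaps))
  attr(series, "load_report") <- list(n_rows_read = n_read, n_dropped_na = n_na,
                                      n_dropped_dup = n_dup, n_gaps = n_gaps)
  series
}

#' Write a tri-axial series to CSV
#'
#' Writes a `t,x,y,z` CSV (timestamps in seconds) at full double precision,
#' so that [read_triaxial_csv()] inverts it bit-exactly.
#'
#' @param series A [triaxial_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_triaxial_csv <- function(series, path) {
  stopifnot(inherits(series, "triaxial_series"))
  if (length(series$time_s) == 0L)
    stop("refusing to write an empty series")
  lines <- c("t,x,y,z",
             sprintf("%.17g,%.17g,%.17g,%.17g", series$time_s,
                     series$xyz[, 1L], series$xyz[, 2L], series$xyz[, 3L]))
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop(sprintf("cannot write '%s': %s",
                                                   path, conditionMessage(e))))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Resample a series to a uniform rate
#'
#' Linearly interpolates each axis onto a uniform grid at `target_hz`
#' spanning `[t_first, t_last]`. Used to bring foreign exports (e.g. ~200 Hz
#' phone logs) to the nominal 50 Hz of the reference corpus.
#'
#' @param series A [triaxial_series()] with at least 2 samples.
#' @param target_hz Positive target rate in Hz.
#' @return A `triaxial_series` sampled at exactly `target_hz`.
#' @export
resample_to_rate <- function(series, target_hz) {
  stopifnot(inherits(series, "triaxial_series"))
  if (!is.numeric(target_hz) || length(target_hz) != 1L || target_hz <= 0)
    stop("target_hz must be a positive real")
  if (length(series$time_s) < 2L)
    stop("insufficient data: need >= 2 samples to resample")
  t0 <- series$time_s[1L]
  t1 <- series$time_s[length(series$time_s)]
  # small tolerance so an exactly spanning grid keeps its final point
  n_out <- floor((t1 - t0) * target_hz + 1e-9) + 1L
  grid <- t0 + (seq_len(n_out) - 1L) / target_hz
  xyz <- vapply(1:3, function(j) {
    stats::approx(series$time_s, series$xyz[, j], xout = grid,
                  method = "linear", rule = 2)$y
  }, numeric(n_out))
  triaxial_series(grid, xyz, sensor = series$sensor,
                  subject_id = series$subject_id, sampling_rate_hz = target_hz)
}
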