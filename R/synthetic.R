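# Synthetic gait corpus generator. A signal-level surrogate for a recorded
# walking corpus: each subject is a quasi-periodic vertical oscillation
# (harmonics of an individual step frequency) superimposed on gravity, plus
# small horizontal components and sensor noise, observed in an arbitrary
# fixed device orientation. It is not a biomechanical model; its job is to
# carry subject-discriminative periodic structure through the exact
# preprocessing and classification pipeline.

#' Draw a uniformly random 3D rotation matrix
#'
#' QR-based draw: orthonormalizes a Gaussian matrix, fixes the sign
#' convention (positive R diagonal) and flips one column if needed so the
#' determinant is +1. Consumes the current RNG stream.
#'
#' @return A 3 x 3 orthonormal matrix with determinant +1.
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3L] <- -Q[, 3L]
  Q
}

#' Draw a cohort of synthetic walker profiles
#'
#' Each profile fixes a subject's gait signature: a step frequency, the
#' amplitudes and phases of its first `n_harmonics` harmonics, a noise
#' level, a gyroscope oscillation amplitude, and the (arbitrary, fixed)
#' orientation of the device on the body. In `"easy"` mode step
#' frequencies are spread over 1.4-2.6 Hz with pairwise gaps of at least
#' 0.15 Hz (when the cohort size permits) and noise is low; `"hard"` mode
#' draws frequencies independently (overlap allowed) with higher noise.
#'
#' @param n_users Cohort size.
#' @param seed Integer seed; the draw is fully determined by it.
#' @param separability `"easy"` or `"hard"`.
#' @param n_harmonics Harmonics of the step frequency per subject
#'   (default 3).
#' @return A list of `n_users` objects of class `synthetic_profile`.
#' @export
sample_profiles <- function(n_users, seed = 1L,
                            separability = c("easy", "hard"),
                            n_harmonics = 3L) {
  separability <- match.arg(separability)
  stopifnot(n_users >= 1L, n_harmonics >= 1L)
  with_local_seed(seed, {
    f_lo <- 1.4; f_hi <- 2.6
    if (separability == "easy") {
      base <- if (n_users == 1L) mean(c(f_lo, f_hi)) else
        seq(f_lo, f_hi, length.out = n_users)
      gap <- if (n_users > 1L) base[2L] - base[1L] else 0.3
      freqs <- base + stats::runif(n_users, -0.2, 0.2) * gap * 0.2
      noise_sd <- 0.3
    } else {
      freqs <- stats::runif(n_users, f_lo, f_hi)
      noise_sd <- 1.0
    }
    lapply(seq_len(n_users), function(i) {
      amps <- c(stats::runif(1L, 1.5, 3.0),
                stats::runif(n_harmonics - 1L, 0.2, 1.5) /
                  seq_len(n_harmonics - 1L))
      structure(list(
        subject_id = sprintf("subj%02d", i - 1L),
        step_frequency_hz = freqs[i],
        harmonic_amps = amps[seq_len(n_harmonics)],
        harmonic_phases = stats::runif(n_harmonics, 0, 2 * pi),
        noise_sd = noise_sd,
        gyro_amp = stats::runif(1L, 0.5, 1.5),
        device_rotation = random_rotation(),
        gravity_mag = 9.81), class = "synthetic_profile")
    })
  })
}

#' @rdname sample_profiles
#' @param ... Passed on to [sample_profiles()].
#' @export
sample_profile <- function(seed = 1L, separability = c("easy", "hard"), ...) {
  sample_profiles(1L, seed = seed, separability = match.arg(separability), ...)[[1L]]
}

#' Simulate one walk recording
#'
#' Builds the body-frame signals, then rotates them into the sensor frame
#' by the profile's device orientation. The vertical (gravity-axis) body
#' acceleration is `gravity_mag + sum_k amp_k sin(2 pi k f t + phase_k) +
#' N(0, noise_sd)`; horizontal components are smaller out-of-phase
#' oscillations with independent noise. The gyroscope oscillates around
#' zero with amplitude `gyro_amp` at the same step frequency. Noise is
#' drawn in the body frame (before rotation), so two recordings of the
#' same profile and seed that differ only in `device_rotation` project
#' back to identical vertical series.
#'
#' @param profile A `synthetic_profile`.
#' @param duration_s Recording length in seconds (default 600, ~10 min).
#' @param fs_hz Sampling rate (default 50).
#' @param seed Seed for the sensor-noise draws.
#' @return A list with accelerometer and gyroscope [triaxial_series()]
#'   sharing one timestamp grid.
#' @export
simulate_walk <- function(profile, duration_s = 600, fs_hz = 50, seed = 1L) {
  stopifnot(inherits(profile, "synthetic_profile"),
            duration_s * fs_hz >= 2)
  n <- floor(duration_s * fs_hz)
  t <- (seq_len(n) - 1L) / fs_hz
  f <- profile$step_frequency_hz
  vert <- rep(profile$gravity_mag, n)
  gyro_v <- numeric(n)
  for (k in seq_along(profile$harmonic_amps)) {
    ph <- profile$harmonic_phases[k]
    vert <- vert + profile$harmonic_amps[k] * sin(2 * pi * k * f * t + ph)
    gyro_v <- gyro_v + profile$gyro_amp / k * sin(2 * pi * k * f * t + ph + pi / 3)
  }
  a1 <- profile$harmonic_amps[1L]
  with_local_seed(seed, {
    body_acc <- cbind(
      x = 0.3 * a1 * sin(2 * pi * f * t + profile$harmonic_phases[1L] + pi / 2) +
        stats::rnorm(n, 0, profile$noise_sd / 2),
      y = 0.2 * a1 * sin(4 * pi * f * t + profile$harmonic_phases[1L]) +
        stats::rnorm(n, 0, profile$noise_sd / 2),
      z = vert + stats::rnorm(n, 0, profile$noise_sd))
    body_gyro <- cbind(
      x = 0.3 * profile$gyro_amp * sin(2 * pi * f * t) +
        stats::rnorm(n, 0, profile$noise_sd / 10),
      y = 0.3 * profile$gyro_amp * cos(2 * pi * f * t) +
        stats::rnorm(n, 0, profile$noise_sd / 10),
      z = gyro_v + stats::rnorm(n, 0, profile$noise_sd / 10))
    R <- profile$device_rotation
    list(acc = triaxial_series(t, body_acc %*% t(R), sensor = "accelerometer",
                               subject_id = profile$subject_id,
                               sampling_rate_hz = fs_hz),
         gyro = triaxial_series(t, body_gyro %*% t(R), sensor = "gyroscope",
                                subject_id = profile$subject_id,
                                sampling_rate_hz = fs_hz))
  })
}

#' Simulate a labeled multi-subject corpus
#'
#' Draws `n_users` profiles, simulates one walk per subject, and (optionally)
#' writes the recordings as CSV files in the package's sensor dialect plus a
#' JSON manifest. Deterministic in `seed`.
#'
#' @param n_users Number of subjects (>= 2).
#' @param duration_s Per-subject recording length in seconds (default 600,
#'   i.e. 30,000 samples at 50 Hz).
#' @param fs_hz Sampling rate (default 50).
#' @param seed Master seed for profiles and per-subject noise.
#' @param separability `"easy"` or `"hard"` (see [sample_profiles()]).
#' @param out_dir If non-`NULL`, directory to write
#'   `<subject>_acc.csv` / `<subject>_gyro.csv` files and `manifest.json`.
#' @return A list of class `synthetic_cohort`: `profiles`, `recordings`
#'   (per subject: `acc` and `gyro` series) and `out_dir`.
#' @export
simulate_cohort <- function(n_users, duration_s = 600, fs_hz = 50, seed = 1L,
                            separability = c("easy", "hard"), out_dir = NULL) {
  separability <- match.arg(separability)
  stopifnot(n_users >= 2L)
  profiles <- sample_profiles(n_users, seed = seed, separability = separability)
  noise_seeds <- with_local_seed(seed + 1L, sample.int(.Machine$integer.max - 1L,
                                                       n_users))
  recordings <- lapply(seq_len(n_users), function(i) {
    simulate_walk(profiles[[i]], duration_s, fs_hz, seed = noise_seeds[i])
  })
  names(recordings) <- vapply(profiles, `[[`, character(1L), "subject_id")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(recordings)) {
      write_triaxial_csv(recordings[[nm]]$acc,
                         file.path(out_dir, paste0(nm, "_acc.csv")))
      write_triaxial_csv(recordings[[nm]]$gyro,
                         file.path(out_dir, paste0(nm, "_gyro.csv")))
    }
    manifest <- list(
      n_users = n_users, duration_s = duration_s, fs_hz = fs_hz,
      seed = seed, separability = separability,
      subjects = names(recordings),
      step_frequency_hz = vapply(profiles, `[[`, numeric(1L),
                                 "step_frequency_hz"),
      files = lapply(names(recordings), function(nm) {
        list(acc = paste0(nm, "_acc.csv"), gyro = paste0(nm, "_gyro.csv"))
      }))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(profiles = profiles, recordings = recordings,
                 out_dir = out_dir), class = "synthetic_cohort")
}

#' Read a simulated corpus back from disk
#'
#' @param dir Directory written by [simulate_cohort()].
#' @return A named list of recordings (per subject: `acc`, `gyro`).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  recs <- lapply(seq_along(manifest$subjects), function(i) {
    nm <- manifest$subjects[i]
    list(acc = read_triaxial_csv(file.path(dir, paste0(nm, "_acc.csv")),
                                 dialect = csv_dialect_generic(),
                                 sensor = "accelerometer", subject_id = nm),
         gyro = read_triaxial_csv(file.path(dir, paste0(nm, "_gyro.csv")),
                                  dialect = csv_dialect_generic(),
                                  sensor = "gyroscope", subject_id = nm))
  })
  names(recs) <- manifest$subjects
  recs
}
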