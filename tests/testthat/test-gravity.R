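test_that("sliding means match hand-computed truncated windows", {
  s <- triaxial_series((0:2) / 50, rbind(c(1, 0, 0), c(0, 1, 0), c(1, 0, 0)),
                       sampling_rate_hz = 50)
  mv <- sliding_mean_vectors(s, half_window_m = 1)
  expect_equal(unname(mv$means[2L, ]), c(2 / 3, 1 / 3, 0))
  expect_equal(unname(mv$means[1L, ]), c(1 / 2, 1 / 2, 0))  # edge-truncated
  expect_equal(unname(mv$means[3L, ]), c(1 / 2, 1 / 2, 0))

  const <- triaxial_series((0:49) / 50,
                           matrix(rep(c(0, 0, 9.81), each = 50), 50, 3),
                           sampling_rate_hz = 50)
  for (m in c(1, 7, 200))
    expect_true(all(abs(sliding_mean_vectors(const, m)$means[, 3L] - 9.81) < 1e-12))
})

test_that("sliding means agree with direct window averages on random input", {
  s <- random_series(n = 137, seed = 8)
  m <- 9L
  mv <- sliding_mean_vectors(s, m)
  direct <- t(vapply(seq_len(137), function(i) {
    idx <- max(1L, i - m):min(137L, i + m)
    colMeans(s$xyz[idx, , drop = FALSE])
  }, numeric(3L)))
  expect_equal(unname(mv$means), unname(direct), tolerance = 1e-12)
})

test_that("unit gravity vectors are normalized, degenerate means rejected", {
  s <- triaxial_series((0:1) / 50, rbind(c(0, 0, 9.81), c(3, 4, 0)),
                       sampling_rate_hz = 50)
  mv <- sliding_mean_vectors(s, 1)
  mv$means <- rbind(c(0, 0, 9.81), c(3, 4, 0))  # exact hand cases
  g <- to_unit_gravity(mv)
  expect_equal(unname(g$unit[1L, ]), c(0, 0, 1))
  expect_equal(unname(g$unit[2L, ]), c(0.6, 0.8, 0))

  mv$means[2L, ] <- c(0, 0, 0)
  expect_error(to_unit_gravity(mv), "degenerate.*index 2")

  g <- estimate_gravity(random_series(n = 300, seed = 2), 25)
  expect_true(all(abs(sqrt(rowSums(g$unit^2)) - 1) < 1e-9))
})

test_that("projections match hand dot products", {
  acc <- triaxial_series((0:1) / 50, rbind(c(0, 0, 9.81), c(1, 0, 0)),
                         sampling_rate_hz = 50)
  g <- estimate_gravity(acc, 1)
  g$unit <- rbind(c(0, 0, 1), c(2, 1, 0) / sqrt(5))
  v <- project_vertical_acceleration(acc, g)
  expect_equal(v$values, c(9.81, 2 / sqrt(5)))
  expect_equal(v$values[2L], 0.894427, tolerance = 1e-6)
  expect_identical(v$quantity, "vertical_acceleration")

  gyro <- triaxial_series((0:1) / 50, rbind(c(0, 0, 0.5), c(1, 1, 0)),
                          sensor = "gyroscope", sampling_rate_hz = 50)
  g$unit <- rbind(c(0, 0, 1), c(0, 0, 1))
  w <- project_vertical_rotation(gyro, g)
  expect_equal(w$values, c(0.5, 0))
  expect_identical(w$quantity, "vertical_rotation")
})

test_that("projection contracts: sensor kinds, gravity provenance, lengths", {
  acc <- random_series(n = 50)
  gyro <- random_series(n = 50, sensor = "gyroscope")
  g_acc <- estimate_gravity(acc, 5)
  expect_error(project_vertical_acceleration(gyro, g_acc), "accelerometer")
  g_gyro <- to_unit_gravity(sliding_mean_vectors(gyro, 5))
  expect_error(project_vertical_rotation(gyro, g_gyro), "usage error")
  g_short <- g_acc
  g_short$unit <- g_short$unit[1:40, ]
  expect_error(project_vertical_acceleration(acc, g_short), "alignment error")
})

test_that("constant acceleration along any direction projects to its magnitude", {
  for (seed in 1:5) {
    v <- withr::with_seed(seed, rnorm(3))
    v <- v / sqrt(sum(v^2))
    c0 <- 9.5
    s <- triaxial_series((0:99) / 50, matrix(rep(c0 * v, each = 100), 100, 3),
                         sampling_rate_hz = 50)
    out <- project_vertical_acceleration(s, estimate_gravity(s, 10))
    expect_true(max(abs(out$values - c0)) < 1e-9)
  }
})

test_that("projecting a window mean onto its own unit gravity gives the mean's norm", {
  s <- random_series(n = 200, seed = 13)
  mv <- sliding_mean_vectors(s, 20)
  g <- to_unit_gravity(mv)
  got <- rowSums(mv$means * g$unit)
  expect_equal(got, sqrt(rowSums(mv$means^2)), tolerance = 1e-9)
})

test_that("the vertical projections are invariant to device orientation", {
  acc <- random_series(n = 350, seed = 4)
  gyro <- random_series(n = 350, sensor = "gyroscope", seed = 5)
  g <- estimate_gravity(acc, 30)
  ref_acc <- project_vertical_acceleration(acc, g)$values
  ref_gyr <- project_vertical_rotation(gyro, g)$values
  worst <- 0
  withr::with_seed(42, {
    for (i in 1:30) {
      R <- random_rotation()
      gR <- estimate_gravity(rotate_series(acc, R), 30)
      aR <- project_vertical_acceleration(rotate_series(acc, R), gR)$values
      wR <- project_vertical_rotation(rotate_series(gyro, R), gR)$values
      worst <- max(worst, max(abs(aR - ref_acc)), max(abs(wR - ref_gyr)))
    }
  })
  expect_lt(worst, 1e-9)
})

test_that("edge trimming slices symmetrically and guards its precondition", {
  s <- scalar_series(1:10, subject_id = "a")
  out <- trim_edges(s, 2)
  expect_equal(out$values, 3:8)
  expect_identical(out$subject_id, "a")
  expect_equal(trim_edges(s, 0)$values, 1:10)
  expect_error(trim_edges(s, 5), "insufficient data")
})
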