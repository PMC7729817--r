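test_that("accuracy is the exact-match fraction", {
  expect_equal(compute_accuracy(c(0, 1, 2), c(0, 1, 2)), 1.0)
  expect_equal(compute_accuracy(c(1, 2, 0), c(0, 1, 2)), 0.0)
  expect_equal(compute_accuracy(c(0, 1, 2, 2), c(0, 1, 2, 3)), 0.75)
  expect_error(compute_accuracy(0:2, 0:3), "alignment error")
})

test_that("confusion matrices count true-by-predicted pairs", {
  expect_equal(unname(confusion_matrix(c(0, 0, 1), c(0, 0, 1), 2)),
               rbind(c(2, 0), c(0, 1)))
  expect_equal(unname(confusion_matrix(1, 0, 2)), rbind(c(0, 1), c(0, 0)))
  expect_error(confusion_matrix(2, 0, 2), "domain error")

  # cross-operation oracle: trace = accuracy * n; margins conserved
  withr::with_seed(17, {
    for (i in 1:100) {
      K <- sample(2:9, 1)
      n <- sample(5:60, 1)
      truth <- sample(0:(K - 1), n, replace = TRUE)
      pred <- sample(0:(K - 1), n, replace = TRUE)
      cm <- confusion_matrix(pred, truth, K)
      expect_equal(sum(cm), n)
      expect_equal(sum(diag(cm)), compute_accuracy(pred, truth) * n)
      expect_equal(unname(rowSums(cm)), unname(tabulate(truth + 1L, K)))
    }
  })
})

test_that("evaluation reports are internally consistent", {
  ws <- toy_window_set(n = 30, window_len = 10, K = 3)
  fit <- train_model(build_architecture(tiny_arch(10, 1, 3)), ws,
                     config = train_config(epochs = 2, batch_size = 10,
                                           validation_fraction = 0, seed = 1))
  rep_ <- evaluate_model(fit, ws)
  expect_equal(sum(rep_$confusion), rep_$n_test)
  expect_equal(sum(diag(rep_$confusion)) / rep_$n_test, rep_$accuracy)
})

test_that("experiment tables round-trip through CSV", {
  tab <- structure(data.frame(window_len = c(12L, 150L),
                              duration_s = c(0.24, 3),
                              n_train = c(100L, 10L), n_test = c(40L, 4L),
                              accuracy = c(0.5, 0.9)),
                   class = c("experiment_table", "data.frame"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_experiment_csv(tab, p)
  back <- read_experiment_csv(p)
  expect_equal(as.data.frame(back), as.data.frame(tab))
})

test_that("seeded repeats report per-group means and population variance", {
  ws <- toy_window_set(n = 40, window_len = 10, K = 2)
  cfg <- train_config(epochs = 2, batch_size = 8, validation_fraction = 0)
  tab <- seeded_repeats(ws, tiny_arch(10, 1, 2), cfg, seeds = c(10L, 20L),
                        repeats = 2L)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$seed, c(10L, 20L))
  runs <- attr(tab, "runs")
  for (s in c(10L, 20L)) {
    g <- runs[runs$seed == s, ]
    expect_equal(tab$mean_accuracy[tab$seed == s], mean(g$accuracy))
    expect_equal(tab$var_accuracy[tab$seed == s],
                 mean((g$accuracy - mean(g$accuracy))^2))
  }
  # a single deterministic run per group has zero variance
  tab1 <- seeded_repeats(ws, tiny_arch(10, 1, 2), cfg, seeds = 10L,
                         repeats = 1L)
  expect_equal(tab1$var_accuracy, 0)
})

test_that("sensor ablation trains the three conditions on one shared split", {
  acc <- toy_window_set(n = 40, window_len = 10, K = 2, seed = 1)
  gyr <- toy_window_set(n = 40, window_len = 10, K = 2, seed = 2)
  gyr$feature_names <- "vertical_rotation"
  cfg <- train_config(epochs = 2, batch_size = 8, validation_fraction = 0)
  tab <- sensor_ablation(acc, gyr, tiny_arch(10, 1, 2), cfg, seed = 3)
  expect_equal(tab$condition, c("acc_only", "gyro_only", "fused"))
  expect_equal(tab$n_features, c(1L, 1L, 2L))
  expect_equal(unique(tab$n_train), 28L)
  expect_equal(unique(tab$n_test), 12L)
  # misaligned labels are rejected
  bad <- gyr
  bad$labels <- rev(bad$labels)
  expect_error(sensor_ablation(acc, bad, tiny_arch(10, 1, 2), cfg),
               "alignment error")
})

test_that("the window-size sweep re-windows, re-sizes and reports durations", {
  corpus <- list(
    u0 = list(vertical_acceleration =
                scalar_series(withr::with_seed(1, rnorm(200)) +
                                sin(2 * pi * 1.5 * (0:199) / 50),
                              subject_id = "u0")),
    u1 = list(vertical_acceleration =
                scalar_series(withr::with_seed(2, rnorm(200)) +
                                sin(2 * pi * 2.3 * (0:199) / 50),
                              subject_id = "u1")))
  cfg <- train_config(epochs = 1, batch_size = 4, validation_fraction = 0)
  tab <- window_size_sweep(corpus, 20L, tiny_arch(), cfg, seed = 5)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$duration_s, 20 / 50)
  total <- count_windows(200, 20, 10) * 2L
  expect_equal(tab$n_train + tab$n_test, total)
  expect_warning(tab2 <- window_size_sweep(corpus, c(20L, 500L), tiny_arch(),
                                           cfg, seed = 5),
                 "exceeds the shortest")
  expect_equal(tab2$window_len, 20L)
})
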