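test_that("analytic parameter counts match the built models' weight tallies", {
  printed <- c(ID1 = 91355L, ID2 = 87875L, ID3 = 96365L, ID4 = 89255L,
               ID5 = 141755L)
  for (id in names(printed)) {
    cfg <- arch_preset(id)
    expect_identical(count_trainable_params(cfg), printed[[id]])
    m <- build_architecture(cfg)
    expect_equal(gaitid:::model_weight_tally(m), printed[[id]])
  }
  # hand-summed toy: two LSTM(1) layers (12 each) + dense 1->1 (2)
  toy <- arch_config(window_len = 4, n_features = 1, lstm_units = c(1, 1),
                     dense_units = integer(0), n_classes = 1)
  expect_identical(count_trainable_params(toy), 26L)
  # counts do not depend on the window length
  expect_identical(count_trainable_params(arch_preset("ID1", window_len = 300)),
                   count_trainable_params(arch_preset("ID1", window_len = 12)))
})

test_that("the layer manifest mirrors the configured stack", {
  m <- build_architecture(arch_preset("ID5"))
  expect_equal(nrow(m$manifest), 5L)
  expect_equal(m$manifest$output_width, c(100, 100, 100, 90, 15))
  expect_equal(m$manifest$type, c("lstm", "lstm", "dense", "dense", "dense"))
  expect_equal(sum(m$manifest$params), 141755)

  m2 <- build_architecture(arch_preset("ID5", n_features = 2))
  expect_equal(m2$manifest$input_width[1L], 2)
  expect_equal(m2$manifest$output_width, m$manifest$output_width)
})

test_that("backpropagation matches central finite differences", {
  cfg <- arch_config(window_len = 5, n_features = 2, lstm_units = c(3, 4),
                     dense_units = 5, n_classes = 3)
  m <- build_architecture(cfg, init_seed = 42)
  withr::with_seed(1, {
    X <- array(rnorm(4 * 5 * 2), dim = c(4, 5, 2))
  })
  Y <- unclass(encode_one_hot(c(0L, 1L, 2L, 1L), 3L))
  fw <- gaitid:::net_forward(m, X, keep_cache = TRUE)
  gr <- gaitid:::net_backward(m, fw, Y)
  loss_at <- function(mm) gaitid:::cross_entropy(gaitid:::net_forward(mm, X)$probs, Y)
  eps <- 1e-6
  worst <- 0
  withr::with_seed(2, {
    for (l in seq_along(m$layers)) {
      for (p in names(gr[[l]])) {
        w <- m$layers[[l]][[p]]
        for (j in sample(length(w), min(10L, length(w)))) {
          m2 <- m
          m2$layers[[l]][[p]][j] <- w[j] + eps
          up <- loss_at(m2)
          m2$layers[[l]][[p]][j] <- w[j] - eps
          dn <- loss_at(m2)
          num <- (up - dn) / (2 * eps)
          ana <- gr[[l]][[p]][j]
          worst <- max(worst, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
        }
      }
    }
  })
  expect_lt(worst, 1e-4)
})

test_that("softmax outputs are proper distributions, batch-size invariant", {
  ws <- toy_window_set(n = 20, window_len = 10, K = 3)
  m <- build_architecture(tiny_arch(10, 1, 3), init_seed = 7)
  p <- predict_proba(m, ws)
  expect_equal(dim(p), c(20L, 3L))
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  one_by_one <- t(vapply(seq_len(20), function(i)
    predict_proba(m, gaitid:::ws_subset(ws, i))[1L, ], numeric(3L)))
  expect_equal(one_by_one, p, tolerance = 1e-6)
})

test_that("a single-class model degenerates to constant probability 1", {
  ws <- toy_window_set(n = 6, window_len = 10, K = 1)
  m <- build_architecture(tiny_arch(10, 1, 1))
  expect_equal(as.vector(predict_proba(m, ws)), rep(1, 6))
  expect_equal(identify(m, ws), rep(0L, 6))
})

test_that("identification is the argmax with low-index tie-breaking", {
  ws <- toy_window_set(n = 12, window_len = 10, K = 3)
  m <- build_architecture(tiny_arch(10, 1, 3), init_seed = 5)
  p <- predict_proba(m, ws)
  expect_identical(identify(m, ws),
                   as.integer(apply(p, 1L, which.max)) - 1L)
  # zeroed output layer makes every class equiprobable: ties resolve to 0
  m$layers[[4L]]$W[] <- 0
  m$layers[[4L]]$b[] <- 0
  expect_true(all(abs(predict_proba(m, ws) - 1 / 3) < 1e-12))
  expect_identical(identify(m, ws), rep(0L, 12))
})

test_that("training history bookkeeping and determinism", {
  ws <- toy_window_set(n = 64, window_len = 10, K = 2)
  cfg <- train_config(epochs = 1, batch_size = 16, seed = 3,
                      validation_fraction = 0.1)
  fit <- train_model(build_architecture(tiny_arch(10, 1, 2)), ws, config = cfg)
  expect_equal(nrow(fit$history), 1L)
  expect_true(all(is.finite(fit$history$loss)))
  expect_true(is.finite(fit$history$val_accuracy))

  cfg$epochs <- 4L
  f1 <- train_model(build_architecture(tiny_arch(10, 1, 2)), ws, config = cfg)
  f2 <- train_model(build_architecture(tiny_arch(10, 1, 2)), ws, config = cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$layers, f2$model$layers)

  expect_error(train_model(build_architecture(tiny_arch(10, 1, 2)), ws,
                           config = train_config(epochs = 1, batch_size = 64,
                                                 validation_fraction = 0.1)),
               "batch_size")
  expect_error(train_model(build_architecture(tiny_arch(12, 1, 2)), ws,
                           config = cfg),
               "configuration error")
})

test_that("a separable two-subject cohort is learned within 15 epochs", {
  coh <- simulate_cohort(2, duration_s = 60, fs_hz = 50, seed = 3,
                         separability = "easy")
  res <- run_identification(
    coh$recordings, arch = arch_preset("ID1"),
    config = train_config(epochs = 15, batch_size = 16, seed = 4,
                          validation_fraction = 0),
    split_seed = 10)
  h <- res$fit$history
  expect_gt(h$accuracy[nrow(h)], 0.95)
  expect_lt(h$loss[nrow(h)], h$loss[1L])
  expect_gt(res$report$accuracy, 0.95)
})
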