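# Forward/backward passes, Adam, and the training loop for the stacked-LSTM
# classifier. Everything operates on minibatch matrices so the heavy work is
# BLAS matrix products; caches keep per-timestep gate activations for
# backpropagation through time.

sigmoid <- function(x) 1 / (1 + exp(-x))

# internal: slice an n x T x F batch array into a list of T (n x F) matrices
slice_timesteps <- function(X) {
  n <- dim(X)[1L]; Tlen <- dim(X)[2L]; F_ <- dim(X)[3L]
  lapply(seq_len(Tlen), function(t) matrix(X[, t, ], n, F_))
}

# internal: one LSTM layer over a batch. Returns the hidden sequence, the
# final state, and (if keep_cache) the gate activations needed by
# lstm_backward. Gate layout in the 4h kernel columns: input, forget,
# candidate, output.
lstm_forward <- function(layer, Xlist, keep_cache = FALSE) {
  n <- nrow(Xlist[[1L]]); h <- layer$units; Tlen <- length(Xlist)
  si <- seq_len(h); sf <- h + si; sg <- 2L * h + si; so <- 3L * h + si
  B <- matrix(layer$b, n, 4L * h, byrow = TRUE)
  H <- matrix(0, n, h); C <- matrix(0, n, h)
  Hseq <- vector("list", Tlen)
  cache <- if (keep_cache) vector("list", Tlen) else NULL
  Hall <- if (keep_cache) c(list(H), vector("list", Tlen)) else NULL
  for (t in seq_len(Tlen)) {
    Z <- Xlist[[t]] %*% layer$W + H %*% layer$U + B
    I <- sigmoid(Z[, si, drop = FALSE])
    Fg <- sigmoid(Z[, sf, drop = FALSE])
    G <- tanh(Z[, sg, drop = FALSE])
    O <- sigmoid(Z[, so, drop = FALSE])
    Cprev <- C
    C <- Fg * Cprev + I * G
    Hc <- tanh(C)
    H <- O * Hc
    Hseq[[t]] <- H
    if (keep_cache) {
      cache[[t]] <- list(I = I, Fg = Fg, G = G, O = O, Hc = Hc, Cprev = Cprev)
      Hall[[t + 1L]] <- H
    }
  }
  list(Hseq = Hseq, Hlast = H,
       cache = if (keep_cache) list(steps = cache, Hall = Hall, Xlist = Xlist))
}

# internal: backpropagation through time for one LSTM layer.
# dHseq: list of upstream gradients per timestep (NULL entries mean zero);
# returns kernel gradients and the gradient w.r.t. the layer inputs.
lstm_backward <- function(layer, cache, dHseq, need_dX = TRUE) {
  steps <- cache$steps; Hall <- cache$Hall; Xlist <- cache$Xlist
  Tlen <- length(steps)
  n <- nrow(Xlist[[1L]]); h <- layer$units
  dW <- matrix(0, nrow(layer$W), ncol(layer$W))
  dU <- matrix(0, h, 4L * h)
  db <- numeric(4L * h)
  dXlist <- if (need_dX) vector("list", Tlen) else NULL
  dHnext <- matrix(0, n, h); dCnext <- matrix(0, n, h)
  for (t in Tlen:1L) {
    s <- steps[[t]]
    dH <- dHnext
    if (!is.null(dHseq[[t]])) dH <- dH + dHseq[[t]]
    dO <- dH * s$Hc * s$O * (1 - s$O)
    dC <- dCnext + dH * s$O * (1 - s$Hc^2)
    dI <- dC * s$G * s$I * (1 - s$I)
    dF <- dC * s$Cprev * s$Fg * (1 - s$Fg)
    dG <- dC * s$I * (1 - s$G^2)
    dZ <- cbind(dI, dF, dG, dO)
    dW <- dW + crossprod(Xlist[[t]], dZ)
    dU <- dU + crossprod(Hall[[t]], dZ)
    db <- db + colSums(dZ)
    if (need_dX) dXlist[[t]] <- tcrossprod(dZ, layer$W)
    dHnext <- tcrossprod(dZ, layer$U)
    dCnext <- dC * s$Fg
  }
  list(W = dW, U = dU, b = db, dXlist = dXlist)
}

# internal: full forward pass. Returns class probabilities and, when
# keep_cache, everything backward() needs. The declared constant input
# component (config$input_offset, e.g. gravity on the vertical-acceleration
# channel) is subtracted at entry: a fixed reparameterization of the first
# layer's bias that keeps the gate pre-activations centered for raw sensor
# magnitudes throughout training, not just at initialization.
net_forward <- function(model, X, keep_cache = FALSE) {
  layers <- model$layers
  Xlist <- slice_timesteps(X)
  n <- dim(X)[1L]
  off <- model$config$input_offset
  if (!is.null(off) && any(off != 0)) {
    offm <- matrix(off, n, length(off), byrow = TRUE)
    Xlist <- lapply(Xlist, `-`, offm)
  }
  caches <- if (keep_cache) vector("list", length(layers))
  l1 <- lstm_forward(layers[[1L]], Xlist, keep_cache)
  if (keep_cache) caches[[1L]] <- l1$cache
  l2 <- lstm_forward(layers[[2L]], l1$Hseq, keep_cache)
  if (keep_cache) caches[[2L]] <- l2$cache
  A <- l2$Hlast
  dense_in <- if (keep_cache) vector("list", length(layers))
  for (i in 3:length(layers)) {
    if (keep_cache) dense_in[[i]] <- A
    Z <- A %*% layers[[i]]$W + matrix(layers[[i]]$b, n, layers[[i]]$units,
                                      byrow = TRUE)
    A <- if (layers[[i]]$activation == "relu") pmax(Z, 0) else softmax_rows(Z)
  }
  list(probs = A,
       cache = if (keep_cache) list(lstm = caches, dense_in = dense_in,
                                    Tlen = length(Xlist)))
}

# internal: numerically stable row softmax
softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# internal: mean categorical cross-entropy of probabilities against one-hot
# targets (probabilities floored to avoid log(0))
cross_entropy <- function(probs, Y) {
  -mean(rowSums(Y * log(pmax(probs, 1e-12))))
}

# internal: gradients of the mean cross-entropy loss w.r.t. every kernel.
# Uses the softmax + cross-entropy shortcut dZ = (P - Y)/n at the output.
net_backward <- function(model, fw, Y) {
  layers <- model$layers
  n <- nrow(Y)
  grads <- vector("list", length(layers))
  dA <- (fw$probs - Y) / n  # gradient at the softmax pre-activation
  for (i in length(layers):3L) {
    A_in <- fw$cache$dense_in[[i]]
    grads[[i]] <- list(W = crossprod(A_in, dA), b = colSums(dA))
    dA <- tcrossprod(dA, layers[[i]]$W)
    if (i > 3L) {
      # upstream layer is dense + ReLU: gate by its positive outputs
      dA <- dA * (A_in > 0)
    }
  }
  # second LSTM contributed only its final state
  Tlen <- fw$cache$Tlen
  dHseq2 <- vector("list", Tlen)
  dHseq2[[Tlen]] <- dA
  g2 <- lstm_backward(layers[[2L]], fw$cache$lstm[[2L]], dHseq2, need_dX = TRUE)
  grads[[2L]] <- g2[c("W", "U", "b")]
  g1 <- lstm_backward(layers[[1L]], fw$cache$lstm[[1L]], g2$dXlist,
                      need_dX = FALSE)
  grads[[1L]] <- g1[c("W", "U", "b")]
  grads
}

# internal: fresh Adam state mirroring the model's parameter shapes
adam_init <- function(layers) {
  lapply(layers, function(l) {
    nm <- if (l$type == "lstm") c("W", "U", "b") else c("W", "b")
    stats::setNames(lapply(nm, function(p) {
      list(m = array(0, dim = dim(l[[p]]) %||% length(l[[p]])),
           v = array(0, dim = dim(l[[p]]) %||% length(l[[p]])))
    }), nm)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: one Adam update over every parameter, t = 1-based step counter
adam_step <- function(layers, grads, state, step, lr, beta1, beta2, eps) {
  bc1 <- 1 - beta1^step
  bc2 <- 1 - beta2^step
  for (i in seq_along(layers)) {
    for (p in names(state[[i]])) {
      g <- grads[[i]][[p]]
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      layers[[i]][[p]] <- layers[[i]][[p]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}

#' Training configuration
#'
#' @param epochs Training epochs (default 75).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters (defaults
#'   1e-3, 0.9, 0.999, 1e-7).
#' @param clip_norm Global gradient-norm ceiling: when the concatenated
#'   gradient's Euclidean norm exceeds it, all gradients are rescaled to
#'   that norm before the Adam update (default 0.5; `Inf` disables).
#'   Backpropagation through 150 timesteps occasionally produces exploding
#'   gradients that would otherwise poison Adam's second-moment estimates
#'   and stall training.
#' @param validation_fraction Fraction of the training windows held out for
#'   per-epoch validation monitoring, in `[0, 1)` (default 0.05; set 0 to
#'   disable).
#' @param seed Integer seed governing weight initialization, the validation
#'   carve-out and minibatch shuffling. Identical seed and data give an
#'   identical training history.
#' @param verbose Print per-epoch metrics.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 75L, batch_size = 32L, learning_rate = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7,
                         clip_norm = 0.5, validation_fraction = 0.05,
                         seed = 10L, verbose = FALSE) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0, clip_norm > 0,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, clip_norm = clip_norm,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

# internal: rescale gradients so their global Euclidean norm is <= ceiling
clip_gradients <- function(grads, ceiling) {
  if (!is.finite(ceiling)) return(grads)
  total <- sum(vapply(grads, function(g) sum(vapply(g, function(x) sum(x * x),
                                                    numeric(1L))),
                      numeric(1L)))
  nrm <- sqrt(total)
  if (nrm <= ceiling) return(grads)
  lapply(grads, function(g) lapply(g, `*`, ceiling / nrm))
}

#' Train the gait classifier
#'
#' Minibatch Adam on categorical cross-entropy. Weights are re-initialized
#' from `config$seed` before fitting, then a validation subset (if
#' requested) is carved from the training windows, and the remainder is
#' shuffled into minibatches each epoch. Reported per-epoch training
#' metrics are the running averages over that epoch's minibatches;
#' validation metrics are computed on the held-out subset after each epoch.
#'
#' @param model A [build_architecture()] model.
#' @param train A [window_set()] of training windows whose shape matches
#'   the model (`T`, `F`) .
#' @param labels Optional [encode_one_hot()] matrix; defaults to encoding
#'   `train$labels` with the model's `n_classes`.
#' @param config A [train_config()].
#' @return An object of class `gait_fit`: list with the trained `model`,
#'   `history` (data frame: epoch, loss, accuracy, val_loss, val_accuracy)
#'   and the `train_config` used.
#' @export
train_model <- function(model, train, labels = NULL, config = train_config()) {
  stopifnot(inherits(model, "gait_model"), inherits(train, "window_set"),
            inherits(config, "train_config"))
  cfg <- model$config
  if (train$window_len != cfg$window_len ||
      dim(train$windows)[3L] != cfg$n_features)
    stop(sprintf("configuration error: model expects %d x %d windows, data is %d x %d",
                 cfg$window_len, cfg$n_features, train$window_len,
                 dim(train$windows)[3L]))
  if (is.null(labels)) labels <- encode_one_hot(train$labels, cfg$n_classes)
  labels <- unclass(labels)
  if (nrow(labels) != n_windows(train) || ncol(labels) != cfg$n_classes)
    stop("configuration error: label matrix shape does not match data/model")
  n <- n_windows(train)

  with_local_seed(config$seed, {
    model$layers <- init_layers(cfg)
    n_val <- as.integer(round(n * config$validation_fraction))
    if (n_val > 0L) {
      val_idx <- sample.int(n, n_val)
      tr_idx <- setdiff(seq_len(n), val_idx)
    } else {
      val_idx <- integer(0L)
      tr_idx <- seq_len(n)
    }
    if (config$batch_size > length(tr_idx))
      stop("configuration error: batch_size exceeds the training-set size")
    Xtr <- train$windows[tr_idx, , , drop = FALSE]
    Ytr <- labels[tr_idx, , drop = FALSE]
    Xval <- train$windows[val_idx, , , drop = FALSE]
    Yval <- labels[val_idx, , drop = FALSE]
    ntr <- length(tr_idx)

    state <- adam_init(model$layers)
    step <- 0L
    hist <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_,
                       accuracy = NA_real_, val_loss = NA_real_,
                       val_accuracy = NA_real_)
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(ntr)
      loss_sum <- 0; hit_sum <- 0
      for (start in seq(1L, ntr, by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1L, ntr)]
        Xb <- Xtr[idx, , , drop = FALSE]
        Yb <- Ytr[idx, , drop = FALSE]
        fw <- net_forward(model, Xb, keep_cache = TRUE)
        loss <- cross_entropy(fw$probs, Yb)
        if (!is.finite(loss))
          stop(sprintf("divergence error: non-finite loss at epoch %d", ep))
        grads <- clip_gradients(net_backward(model, fw, Yb), config$clip_norm)
        step <- step + 1L
        upd <- adam_step(model$layers, grads, state, step,
                         config$learning_rate, config$beta1, config$beta2,
                         config$epsilon)
        model$layers <- upd$layers
        state <- upd$state
        loss_sum <- loss_sum + loss * length(idx)
        hit_sum <- hit_sum +
          sum(max.col(fw$probs, ties.method = "first") ==
              max.col(Yb, ties.method = "first"))
      }
      hist$loss[ep] <- loss_sum / ntr
      hist$accuracy[ep] <- hit_sum / ntr
      if (n_val > 0L) {
        pv <- predict_proba_raw(model, Xval)
        hist$val_loss[ep] <- cross_entropy(pv, Yval)
        hist$val_accuracy[ep] <-
          mean(max.col(pv, ties.method = "first") ==
               max.col(Yval, ties.method = "first"))
      }
      if (config$verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.4f  val_acc %s", ep,
                        hist$loss[ep], hist$accuracy[ep],
                        ifelse(n_val > 0L, sprintf("%.4f", hist$val_accuracy[ep]), "-")))
    }
    structure(list(model = model, history = hist, train_config = config),
              class = "gait_fit")
  })
}

#' @export
print.gait_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<gait_fit> %d epochs; final train acc %.3f, loss %.4f%s\n",
              nrow(x$history), last$accuracy, last$loss,
              if (is.finite(last$val_accuracy))
                sprintf("; val acc %.3f", last$val_accuracy) else ""))
  invisible(x)
}

# internal: forward in chunks (prediction only); X an n x T x F array
predict_proba_raw <- function(model, X, chunk = 512L) {
  n <- dim(X)[1L]
  if (n == 0L) return(matrix(0, 0L, model$config$n_classes))
  out <- matrix(0, n, model$config$n_classes)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    out[idx, ] <- net_forward(model, X[idx, , , drop = FALSE])$probs
  }
  out
}

#' Class probabilities for a set of windows
#'
#' @param object A trained [gait_fit] (or bare `gait_model`).
#' @param windows A [window_set()] matching the model's input shape.
#' @return An `n x K` matrix; each row is a softmax distribution over
#'   subjects (non-negative, summing to 1).
#' @export
predict_proba <- function(object, windows) {
  model <- if (inherits(object, "gait_fit")) object$model else object
  stopifnot(inherits(model, "gait_model"), inherits(windows, "window_set"))
  if (windows$window_len != model$config$window_len ||
      dim(windows$windows)[3L] != model$config$n_features)
    stop("configuration error: window shape does not match the model")
  predict_proba_raw(model, windows$windows)
}

#' Identify the subject of each window
#'
#' Inverts the one-hot categorization: each window is assigned the subject
#' with the highest softmax probability (ties broken toward the lowest
#' index).
#'
#' @inheritParams predict_proba
#' @return Integer vector of 0-based subject labels.
#' @export
identify <- function(object, windows) {
  p <- predict_proba(object, windows)
  max.col(p, ties.method = "first") - 1L
}
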