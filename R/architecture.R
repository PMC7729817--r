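#' Architecture configuration for the gait classifier
#'
#' Describes the stacked-LSTM network: two LSTM layers (the first returning
#' its full hidden sequence, the second only its final state), a stack of
#' fully connected ReLU layers, and a softmax output with one neuron per
#' subject.
#'
#' @param window_len Timesteps `T` per input window (default 150).
#' @param n_features Input channels `F` (1 = vertical acceleration only,
#'   2 = acceleration + vertical rotation).
#' @param lstm_units Integer pair: memory units of the two LSTM layers.
#' @param dense_units Integer vector of hidden fully connected layer widths.
#' @param n_classes Number of subjects `K` (output width).
#' @param input_offset Known constant (DC) component of each input channel,
#'   subtracted from the input inside the network's forward pass — a fixed
#'   reparameterization of the first LSTM's bias that keeps the gates in
#'   their linear range on raw (unnormalized) sensor values. Vertical
#'   acceleration oscillates around standard gravity (9.81 m/s^2),
#'   vertical rotation around 0. Default: zeros.
#' @return An object of class `arch_config`.
#' @export
arch_config <- function(window_len = 150L, n_features = 1L,
                        lstm_units = c(50L, 100L), dense_units = c(100L, 90L),
                        n_classes = 15L, input_offset = NULL) {
  window_len <- as.integer(window_len); n_features <- as.integer(n_features)
  lstm_units <- as.integer(lstm_units); dense_units <- as.integer(dense_units)
  n_classes <- as.integer(n_classes)
  if (length(lstm_units) != 2L || any(lstm_units < 1L))
    stop("lstm_units must be a pair of positive integers")
  if (length(dense_units) > 0L && any(dense_units < 1L))
    stop("dense_units must be positive integers")
  stopifnot(window_len >= 1L, n_features >= 1L, n_classes >= 1L)
  if (is.null(input_offset)) input_offset <- numeric(n_features)
  input_offset <- as.numeric(input_offset)
  if (length(input_offset) == 1L) input_offset <- rep(input_offset, n_features)
  if (length(input_offset) != n_features)
    stop("input_offset must have one value per feature channel")
  structure(list(window_len = window_len, n_features = n_features,
                 lstm_units = lstm_units, dense_units = dense_units,
                 n_classes = n_classes, input_offset = input_offset),
            class = "arch_config")
}

# the five benchmarked layer configurations; all share the two-LSTM trunk
.arch_presets <- list(
  ID1 = list(lstm_units = c(50L, 100L),  dense_units = c(100L, 90L)),
  ID2 = list(lstm_units = c(50L, 100L),  dense_units = c(100L, 60L)),
  ID3 = list(lstm_units = c(50L, 100L),  dense_units = c(100L, 90L, 60L)),
  ID4 = list(lstm_units = c(50L, 100L),  dense_units = c(100L, 60L, 30L)),
  ID5 = list(lstm_units = c(100L, 100L), dense_units = c(100L, 90L))
)

#' Named architecture presets
#'
#' The five benchmark configurations ID1-ID5. All use two stacked LSTM
#' layers followed by fully connected ReLU layers and a softmax output;
#' they differ in the first LSTM's memory units and the hidden layer
#' widths:
#' ID1 LSTM(50, 100) + dense(100, 90); ID2 LSTM(50, 100) + dense(100, 60);
#' ID3 LSTM(50, 100) + dense(100, 90, 60); ID4 LSTM(50, 100) +
#' dense(100, 60, 30); ID5 LSTM(100, 100) + dense(100, 90).
#'
#' @param id One of `"ID1"` .. `"ID5"`.
#' @param n_classes Number of subjects (default 15).
#' @param window_len,n_features Input shape overrides.
#' @return An [arch_config()].
#' @export
arch_preset <- function(id = c("ID1", "ID2", "ID3", "ID4", "ID5"),
                        n_classes = 15L, window_len = 150L, n_features = 1L) {
  id <- match.arg(id)
  p <- .arch_presets[[id]]
  cfg <- arch_config(window_len = window_len, n_features = n_features,
                     lstm_units = p$lstm_units, dense_units = p$dense_units,
                     n_classes = n_classes)
  cfg$preset <- id
  cfg
}

#' Analytic count of trainable parameters
#'
#' Sums, over the layer stack, `4 * (h * (d + h) + h)` for an LSTM layer
#' with input width `d` and `h` memory units (input/forget/candidate/output
#' gate kernels, recurrent kernels and biases) and `d * h + h` for a dense
#' layer `d -> h`. Independent of the window length `T`: LSTM weights are
#' shared across timesteps.
#'
#' @param config An [arch_config()].
#' @return The total number of trainable scalars (integer).
#' @export
count_trainable_params <- function(config) {
  stopifnot(inherits(config, "arch_config"))
  widths <- layer_widths(config)
  total <- 0
  for (i in seq_len(nrow(widths))) {
    d <- widths$input_width[i]; h <- widths$output_width[i]
    total <- total + if (widths$type[i] == "lstm") 4 * (h * (d + h) + h) else d * h + h
  }
  as.integer(total)
}

# internal: the layer stack as a table of (type, input_width, output_width)
layer_widths <- function(config) {
  types <- c("lstm", "lstm", rep("dense", length(config$dense_units)), "dense")
  outs <- c(config$lstm_units, config$dense_units, config$n_classes)
  ins <- c(config$n_features, outs[-length(outs)])
  data.frame(type = types, input_width = ins, output_width = outs)
}

#' Build the stacked-LSTM network
#'
#' Materializes the layer stack of an [arch_config()]. Input and dense
#' kernels are Glorot-uniform, recurrent kernels orthogonal per gate, and
#' forget-gate biases start at 1 ([train_model()] re-initializes from its
#' own seed before fitting). The network subtracts `config$input_offset`
#' (the known DC component of the raw input, e.g. gravity on the
#' vertical-acceleration channel) from its input at entry — equivalent to
#' re-expressing the first LSTM's bias, and what keeps the gates in their
#' linear range on unnormalized sensor values. The first LSTM emits its
#' hidden state at every timestep to feed the second; the second emits only
#' its final state, which the dense head classifies.
#'
#' @param config An [arch_config()].
#' @param init_seed Seed for the initial (pre-training) weights.
#' @return An object of class `gait_model`: list with `config`, `layers`
#'   (weight arrays) and `manifest`, a data frame listing each layer's type,
#'   input/output width and parameter count.
#' @export
build_architecture <- function(config, init_seed = 0L) {
  stopifnot(inherits(config, "arch_config"))
  model <- structure(list(config = config, layers = NULL, manifest = NULL),
                     class = "gait_model")
  model$layers <- with_local_seed(init_seed, init_layers(config))
  widths <- layer_widths(config)
  widths$params <- vapply(seq_len(nrow(widths)), function(i) {
    d <- widths$input_width[i]; h <- widths$output_width[i]
    if (widths$type[i] == "lstm") 4 * (h * (d + h) + h) else d * h + h
  }, numeric(1L))
  widths$activation <- c("tanh/sigmoid", "tanh/sigmoid",
                         rep("relu", length(config$dense_units)), "softmax")
  model$manifest <- widths
  model
}

#' @export
print.gait_model <- function(x, ...) {
  cat(sprintf("<gait_model> %s: T=%d, F=%d, K=%d, %s trainable parameters\n",
              if (is.null(x$config$preset)) "custom" else x$config$preset,
              x$config$window_len, x$config$n_features, x$config$n_classes,
              format(count_trainable_params(x$config), big.mark = ",")))
  print(x$manifest)
  invisible(x)
}

# internal: draw fresh weights for every layer. Input and dense kernels are
# Glorot uniform; recurrent kernels are orthogonal per gate; forget-gate
# biases start at 1. The constant input component (config$input_offset) is
# handled structurally in net_forward, not here.
init_layers <- function(config) {
  widths <- layer_widths(config)
  layers <- vector("list", nrow(widths))
  for (i in seq_len(nrow(widths))) {
    d <- widths$input_width[i]; h <- widths$output_width[i]
    if (widths$type[i] == "lstm") {
      b <- numeric(4L * h)
      b[(h + 1L):(2L * h)] <- 1  # forget gate opens at init
      layers[[i]] <- list(
        type = "lstm", input_size = d, units = h,
        return_sequences = (i == 1L),
        W = glorot(d, 4L * h), U = orthogonal_gates(h), b = b)
    } else {
      layers[[i]] <- list(
        type = "dense", input_size = d, units = h,
        activation = if (i == nrow(widths)) "softmax" else "relu",
        W = glorot(d, h), b = numeric(h))
    }
  }
  layers
}

# internal: Glorot/Xavier uniform draw for a d x h kernel
glorot <- function(d, h) {
  lim <- sqrt(6 / (d + h))
  matrix(stats::runif(d * h, -lim, lim), d, h)
}

# internal: h x 4h recurrent kernel, one random orthogonal block per gate
orthogonal_gates <- function(h) {
  do.call(cbind, lapply(1:4, function(g) {
    qr_ <- qr(matrix(stats::rnorm(h * h), h, h))
    qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))), h)
  }))
}

# internal: tally of scalars actually stored in the built model's weights;
# cross-checks the analytic count
model_weight_tally <- function(model) {
  sum(vapply(model$layers, function(l) {
    length(l$W) + length(l$b) + if (l$type == "lstm") length(l$U) else 0L
  }, numeric(1L)))
}
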