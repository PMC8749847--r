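# Bi-modular sequential network: a tapered 3-layer LSTM sub-network
# (defaults 128/64/64, tanh) feeding a tapered 3-layer MLP (64/32/32, tanh,
# optional batch normalization after the first dense layer, dropout after a
# configurable dense layer) and a softmax output over the emotion classes.

#' Network configuration
#'
#' Declarative description of the bi-modular architecture. Unit counts must
#' be non-increasing within each sub-network (the tapered design); pass
#' `allow_non_tapered = TRUE` to override for experimentation.
#'
#' @param input_dim Per-frame input width `D`.
#' @param sequence_length Number of frames `T` per sequence.
#' @param lstm_units Units of the three (or more) LSTM layers.
#' @param mlp_units Units of the dense layers before the output.
#' @param n_classes Number of output classes.
#' @param activation Hidden activation; only `"tanh"` is supported.
#' @param batchnorm_after_first_mlp Insert batch normalization after the
#'   first dense layer?
#' @param batchnorm_momentum Momentum of the running-statistics update
#'   (`running <- momentum * running + (1 - momentum) * batch`).
#' @param dropout_position Which dense layer's output is dropped out
#'   (1-based; 0 disables dropout).
#' @param dropout_rate Dropout probability in `[0, 1)`.
#' @param allow_non_tapered Skip the tapered-design check.
#' @return An object of class `network_config`.
#' @export
network_config <- function(input_dim, sequence_length,
                           lstm_units = c(128L, 64L, 64L),
                           mlp_units = c(64L, 32L, 32L),
                           n_classes = 4L,
                           activation = "tanh",
                           batchnorm_after_first_mlp = FALSE,
                           batchnorm_momentum = 0.1,
                           dropout_position = 2L,
                           dropout_rate = 0.2,
                           allow_non_tapered = FALSE) {
  if (!is_count(input_dim)) gm_stop("'input_dim' must be a positive integer",
                                    "config")
  if (!is_count(sequence_length))
    gm_stop("'sequence_length' must be a positive integer", "config")
  lstm_units <- as.integer(lstm_units); mlp_units <- as.integer(mlp_units)
  if (!length(lstm_units) || any(lstm_units < 1L) ||
      !length(mlp_units) || any(mlp_units < 1L))
    gm_stop("unit lists must be positive integers", "config")
  if (!allow_non_tapered &&
      (any(diff(lstm_units) > 0L) || any(diff(mlp_units) > 0L)))
    gm_stop(paste0("unit counts must be non-increasing within each ",
                   "sub-network (tapered design); got LSTM [",
                   paste(lstm_units, collapse = ","), "], MLP [",
                   paste(mlp_units, collapse = ","),
                   "]. Use allow_non_tapered = TRUE to override."), "config")
  if (!is_count(n_classes, min = 2L))
    gm_stop("'n_classes' must be >= 2", "config")
  if (!identical(activation, "tanh"))
    gm_stop("only the 'tanh' hidden activation is supported", "config")
  if (!is_number(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1)
    gm_stop("'dropout_rate' must be in [0, 1)", "config")
  if (!is.numeric(dropout_position) || length(dropout_position) != 1L ||
      dropout_position < 0 || dropout_position > length(mlp_units))
    gm_stop(sprintf("'dropout_position' must be 0 (off) or in 1..%d",
                    length(mlp_units)), "config")
  if (!is_number(batchnorm_momentum) || batchnorm_momentum < 0 ||
      batchnorm_momentum >= 1)
    gm_stop("'batchnorm_momentum' must be in [0, 1)", "config")
  structure(
    list(input_dim = as.integer(input_dim),
         sequence_length = as.integer(sequence_length),
         lstm_units = lstm_units, mlp_units = mlp_units,
         n_classes = as.integer(n_classes), activation = activation,
         batchnorm_after_first_mlp = isTRUE(batchnorm_after_first_mlp),
         batchnorm_momentum = batchnorm_momentum,
         dropout_position = as.integer(dropout_position),
         dropout_rate = dropout_rate),
    class = "network_config")
}

#' Count network parameters (closed form)
#'
#' Each LSTM layer with fan-in `d` and `u` units contributes
#' `4 * (u*d + u^2 + u)` parameters (four gates, each with an input kernel,
#' a recurrent kernel and a bias); each dense layer `d -> u` contributes
#' `d*u + u`; batch normalization on `u` units contributes `4*u` (scale,
#' shift and the two running statistics). The output layer is counted as a
#' dense layer. With the default architecture this reproduces 295,684
#' parameters for input width 273, 295,940 with batch normalization, and
#' 180,484 for raw-coordinate input width 48.
#'
#' @param x A [network_config()] (closed form) or a model built by
#'   [init_network()] (the sizes of the actually allocated arrays are
#'   summed, providing an independent cross-check).
#' @param ... Unused.
#' @return Total parameter count (integer).
#' @examples
#' cfg <- network_config(input_dim = 273, sequence_length = 240)
#' count_parameters(cfg)  # 295684
#' @export
count_parameters <- function(x, ...) UseMethod("count_parameters")

#' @export
count_parameters.network_config <- function(x, ...) {
  total <- 0
  d <- x$input_dim
  for (u in x$lstm_units) {
    total <- total + 4 * (u * d + u * u + u)
    d <- u
  }
  for (k in seq_along(x$mlp_units)) {
    u <- x$mlp_units[k]
    total <- total + d * u + u
    if (k == 1L && x$batchnorm_after_first_mlp) total <- total + 4 * u
    d <- u
  }
  total <- total + d * x$n_classes + x$n_classes
  as.integer(total)
}

#' @export
count_parameters.gait_model <- function(x, ...) {
  n <- 0L
  for (layer in x$layers) {
    n <- n + sum(vapply(layer[intersect(names(layer),
                                        c("Wx", "Wa", "b", "W",
                                          "gamma", "beta",
                                          "run_mean", "run_var"))],
                        length, integer(1)))
  }
  as.integer(n)
}

#' Build the layer-by-layer model specification
#'
#' Expands a [network_config()] into a table of layer descriptors (kind,
#' fan-in, fan-out, activation, trainable and auxiliary parameter counts).
#' The total must equal [count_parameters()].
#'
#' @param config A [network_config()].
#' @return A `model_spec`: a data.frame of layer descriptors with the config
#'   attached as an attribute.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  rows <- list()
  d <- config$input_dim
  for (k in seq_along(config$lstm_units)) {
    u <- config$lstm_units[k]
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("lstm_%d", k), kind = "lstm", fan_in = d, fan_out = u,
      activation = "tanh", trainable = 4 * (u * d + u * u + u),
      auxiliary = 0)
    d <- u
  }
  for (k in seq_along(config$mlp_units)) {
    u <- config$mlp_units[k]
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("dense_%d", k), kind = "dense", fan_in = d,
      fan_out = u, activation = "tanh", trainable = d * u + u,
      auxiliary = 0)
    if (k == 1L && config$batchnorm_after_first_mlp)
      rows[[length(rows) + 1L]] <- data.frame(
        layer = "batchnorm_1", kind = "batchnorm", fan_in = u, fan_out = u,
        activation = "identity", trainable = 2 * u, auxiliary = 2 * u)
    if (k == config$dropout_position && config$dropout_rate > 0)
      rows[[length(rows) + 1L]] <- data.frame(
        layer = sprintf("dropout_%d", k), kind = "dropout", fan_in = u,
        fan_out = u, activation = "identity", trainable = 0, auxiliary = 0)
    d <- u
  }
  rows[[length(rows) + 1L]] <- data.frame(
    layer = "output", kind = "dense", fan_in = d,
    fan_out = config$n_classes, activation = "softmax",
    trainable = d * config$n_classes + config$n_classes, auxiliary = 0)
  spec <- do.call(rbind, rows)
  stopifnot(sum(spec$trainable + spec$auxiliary) ==
              count_parameters(config))
  structure(spec, config = config, class = c("model_spec", "data.frame"))
}

# ---- weight initialization -------------------------------------------------

glorot_uniform <- function(nr, nc, fan_in = nr, fan_out = nc) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# Semi-orthogonal square init for recurrent kernels.
random_orthogonal <- function(u) {
  qr.Q(qr(matrix(stats::rnorm(u * u), u, u)))
}

#' Instantiate a model with initialized weights
#'
#' Input and dense kernels use Glorot-uniform initialization; recurrent
#' kernels are per-gate orthogonal; gate biases are zero except the forget
#' gate (1, the usual stabilizing choice); batch-norm scale/shift start at
#' 1/0. The softmax output layer is zero-initialized by default so that an
#' untrained model emits exactly uniform class probabilities and early
#' training is driven by the learned signal rather than by a random readout
#' (see the methods vignette); set `final_layer_init = "glorot"` for a
#' random readout.
#'
#' @param config A [network_config()].
#' @param seed Integer seed for the initializer.
#' @param final_layer_init `"zeros"` (default) or `"glorot"`.
#' @return An object of class `gait_model` (layers with weights, the config
#'   and the [build_network()] spec).
#' @export
init_network <- function(config, seed = 1L, final_layer_init = "zeros") {
  stopifnot(inherits(config, "network_config"))
  if (!final_layer_init %in% c("zeros", "glorot"))
    gm_stop("'final_layer_init' must be 'zeros' or 'glorot'", "config")
  layers <- list()
  withr::with_seed(derive_seed(seed), {
    d <- config$input_dim
    for (u in config$lstm_units) {
      Wx <- glorot_uniform(d, 4L * u, fan_in = d, fan_out = 4L * u)
      Wa <- do.call(cbind, replicate(4L, random_orthogonal(u),
                                     simplify = FALSE))
      b <- rep(0, 4L * u)
      b[(u + 1L):(2L * u)] <- 1  # forget-gate bias
      layers[[length(layers) + 1L]] <- list(type = "lstm", units = u,
                                            Wx = Wx, Wa = Wa, b = b)
      d <- u
    }
    for (k in seq_along(config$mlp_units)) {
      u <- config$mlp_units[k]
      layers[[length(layers) + 1L]] <- list(
        type = "dense", units = u, activation = "tanh",
        W = glorot_uniform(d, u), b = rep(0, u))
      if (k == 1L && config$batchnorm_after_first_mlp)
        layers[[length(layers) + 1L]] <- list(
          type = "batchnorm", units = u, gamma = rep(1, u), beta = rep(0, u),
          run_mean = rep(0, u), run_var = rep(1, u),
          momentum = config$batchnorm_momentum, eps = 1e-3)
      if (k == config$dropout_position && config$dropout_rate > 0)
        layers[[length(layers) + 1L]] <- list(type = "dropout",
                                              rate = config$dropout_rate)
      d <- u
    }
    W_out <- if (final_layer_init == "zeros")
      matrix(0, d, config$n_classes)
    else glorot_uniform(d, config$n_classes)
    layers[[length(layers) + 1L]] <- list(
      type = "dense", units = config$n_classes, activation = "softmax",
      W = W_out, b = rep(0, config$n_classes))
  })
  structure(list(config = config, layers = layers,
                 spec = build_network(config), class_names = NULL),
            class = "gait_model")
}

#' @export
print.gait_model <- function(x, ...) {
  cat(sprintf("<gait_model> input [%d, %d] -> %d classes, %s parameters\n",
              x$config$sequence_length, x$config$input_dim,
              x$config$n_classes,
              format(count_parameters(x$config), big.mark = ",")))
  print(as.data.frame(x$spec))
  invisible(x)
}

# ---- reference LSTM cell (independent oracle path) -------------------------

#' Per-gate LSTM cell weights
#'
#' Container for the reference cell: per-gate input kernels (`units x
#' input_dim`), recurrent kernels (`units x units`) and biases, for the
#' input (i), forget (f), candidate (c) and output (o) gates.
#'
#' @param W_ix,W_fx,W_cx,W_ox Input kernels, `units x input_dim`.
#' @param W_ia,W_fa,W_ca,W_oa Recurrent kernels, `units x units`.
#' @param b_i,b_f,b_c,b_o Bias vectors of length `units`.
#' @return An object of class `lstm_cell_weights`.
#' @export
lstm_cell_weights <- function(W_ix, W_fx, W_cx, W_ox,
                              W_ia, W_fa, W_ca, W_oa,
                              b_i, b_f, b_c, b_o) {
  u <- nrow(W_ix); d <- ncol(W_ix)
  mats <- list(W_ix = W_ix, W_fx = W_fx, W_cx = W_cx, W_ox = W_ox)
  recs <- list(W_ia = W_ia, W_fa = W_fa, W_ca = W_ca, W_oa = W_oa)
  bias <- list(b_i = b_i, b_f = b_f, b_c = b_c, b_o = b_o)
  for (nm in names(mats))
    if (!identical(dim(mats[[nm]]), c(u, d)))
      gm_stop(sprintf("'%s' must be %d x %d", nm, u, d), "contract")
  for (nm in names(recs))
    if (!identical(dim(recs[[nm]]), c(u, u)))
      gm_stop(sprintf("'%s' must be %d x %d", nm, u, u), "contract")
  for (nm in names(bias))
    if (length(bias[[nm]]) != u)
      gm_stop(sprintf("'%s' must have length %d", nm, u), "contract")
  w <- c(mats, recs, bias, list(units = u, input_dim = d))
  if (!all(vapply(c(mats, recs, bias), function(m) all(is.finite(m)),
                  logical(1))))
    gm_stop("weights contain non-finite values", "contract")
  structure(w, class = "lstm_cell_weights")
}

#' One LSTM cell step (reference implementation)
#'
#' Standard-gate update evaluated literally, gate by gate:
#' `i = sigmoid(W_ix x + W_ia a + b_i)`, likewise the forget and output
#' gates; candidate `g = tanh(W_cx x + W_ca a + b_c)`;
#' `c_t = f * c_prev + i * g`; `a_t = o * tanh(c_t)`. This is the slow,
#' loop-level oracle against which the vectorized training engine is
#' checked.
#'
#' @param w An [lstm_cell_weights()].
#' @param x_t Input vector of length `input_dim`.
#' @param a_prev,c_prev Previous activation and memory vectors (`units`).
#' @return `list(a = a_t, c = c_t)`.
#' @export
lstm_cell_step <- function(w, x_t, a_prev, c_prev) {
  stopifnot(inherits(w, "lstm_cell_weights"))
  if (length(x_t) != w$input_dim)
    gm_stop(sprintf("x_t has length %d, expected %d", length(x_t),
                    w$input_dim), "contract")
  if (length(a_prev) != w$units || length(c_prev) != w$units)
    gm_stop("a_prev/c_prev length must equal the unit count", "contract")
  i <- sigmoid(drop(w$W_ix %*% x_t + w$W_ia %*% a_prev) + w$b_i)
  f <- sigmoid(drop(w$W_fx %*% x_t + w$W_fa %*% a_prev) + w$b_f)
  o <- sigmoid(drop(w$W_ox %*% x_t + w$W_oa %*% a_prev) + w$b_o)
  g <- tanh(drop(w$W_cx %*% x_t + w$W_ca %*% a_prev) + w$b_c)
  c_t <- f * c_prev + i * g
  a_t <- o * tanh(c_t)
  list(a = a_t, c = c_t)
}

#' GRU memory update
#'
#' The single-gate convex-combination memory update that distinguishes a GRU
#' from the three-gate LSTM cell: `c_t = (1 - i_t) * c_prev + i_t * a_prev`,
#' elementwise. Provided as a reference; the network itself uses LSTM cells.
#'
#' @param i_t Gate vector with entries in `[0, 1]`.
#' @param c_prev,a_prev Memory and activation vectors of the same length.
#' @return The updated memory vector.
#' @export
gru_memory_update <- function(i_t, c_prev, a_prev) {
  if (length(i_t) != length(c_prev) || length(i_t) != length(a_prev))
    gm_stop("'i_t', 'c_prev' and 'a_prev' must have equal lengths",
            "contract")
  if (any(i_t < 0 | i_t > 1))
    gm_stop("gate values must lie in [0, 1]", "contract")
  (1 - i_t) * c_prev + i_t * a_prev
}

#' LSTM layer forward pass (reference implementation)
#'
#' Iterates [lstm_cell_step()] over the rows of `X` with zero initial state.
#' Stacked layers consume the full activation sequence; the last LSTM layer
#' feeds only its final activation to the MLP sub-network.
#'
#' @param w An [lstm_cell_weights()].
#' @param X `T x input_dim` matrix (one row per frame).
#' @param return_sequence If `TRUE` return the `T x units` activation
#'   sequence, else the final activation vector.
#' @return Matrix or vector of activations, entries in `(-1, 1)`.
#' @export
lstm_layer_forward <- function(w, X, return_sequence = TRUE) {
  stopifnot(inherits(w, "lstm_cell_weights"))
  if (!is.matrix(X) || ncol(X) != w$input_dim)
    gm_stop(sprintf("X must be a T x %d matrix", w$input_dim), "contract")
  a <- rep(0, w$units); cc <- rep(0, w$units)
  out <- matrix(0, nrow(X), w$units)
  for (t in seq_len(nrow(X))) {
    st <- lstm_cell_step(w, X[t, ], a, cc)
    a <- st$a; cc <- st$c
    out[t, ] <- a
  }
  if (return_sequence) out else a
}

# Convert a packed engine layer (Wx d x 4u [i|f|c|o], Wa u x 4u, b 4u) to
# the per-gate reference representation, and back.
unpack_lstm_weights <- function(layer) {
  u <- layer$units
  g <- function(k) ((k - 1L) * u + 1L):(k * u)
  lstm_cell_weights(
    W_ix = t(layer$Wx[, g(1), drop = FALSE]),
    W_fx = t(layer$Wx[, g(2), drop = FALSE]),
    W_cx = t(layer$Wx[, g(3), drop = FALSE]),
    W_ox = t(layer$Wx[, g(4), drop = FALSE]),
    W_ia = t(layer$Wa[, g(1), drop = FALSE]),
    W_fa = t(layer$Wa[, g(2), drop = FALSE]),
    W_ca = t(layer$Wa[, g(3), drop = FALSE]),
    W_oa = t(layer$Wa[, g(4), drop = FALSE]),
    b_i = layer$b[g(1)], b_f = layer$b[g(2)],
    b_c = layer$b[g(3)], b_o = layer$b[g(4)])
}

pack_lstm_weights <- function(w) {
  list(type = "lstm", units = w$units,
       Wx = cbind(t(w$W_ix), t(w$W_fx), t(w$W_cx), t(w$W_ox)),
       Wa = cbind(t(w$W_ia), t(w$W_fa), t(w$W_ca), t(w$W_oa)),
       b = c(w$b_i, w$b_f, w$b_c, w$b_o))
}
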