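# Vectorized batch engine: forward and backward passes over a mini-batch.
#
# A batch of n sequences of T frames is held sequence-major: one
# (n*T) x D matrix whose row (i-1)*T + t is frame t of sequence i, so the
# input-to-gate products of a whole LSTM layer collapse into a single
# matrix multiplication. The per-timestep recurrent part loops over t.
# This is the "framework" path; R/model.R carries the naive per-gate
# reference path the engine is tested against.

t_rows <- function(t, n, Tlen) ((seq_len(n) - 1L) * Tlen) + t

gate_cols <- function(k, u) ((k - 1L) * u + 1L):(k * u)

lstm_forward_batch <- function(layer, Xbig, n, Tlen, keep_cache = FALSE) {
  u <- layer$units
  P <- Xbig %*% layer$Wx
  P <- P + rep(layer$b, each = nrow(P))
  a <- matrix(0, n, u); cc <- matrix(0, n, u)
  Aseq <- matrix(0, n * Tlen, u)
  steps <- if (keep_cache) vector("list", Tlen) else NULL
  for (t in seq_len(Tlen)) {
    rows <- t_rows(t, n, Tlen)
    Z <- P[rows, , drop = FALSE] + a %*% layer$Wa
    I <- sigmoid(Z[, gate_cols(1, u), drop = FALSE])
    Fg <- sigmoid(Z[, gate_cols(2, u), drop = FALSE])
    G <- tanh(Z[, gate_cols(3, u), drop = FALSE])
    O <- sigmoid(Z[, gate_cols(4, u), drop = FALSE])
    cprev <- cc
    cc <- Fg * cprev + I * G
    tc <- tanh(cc)
    if (keep_cache)
      steps[[t]] <- list(I = I, Fg = Fg, G = G, O = O, cprev = cprev,
                         tc = tc, aprev = a)
    a <- O * tc
    Aseq[rows, ] <- a
  }
  list(Aseq = Aseq, last = a, steps = steps)
}

# dA: either a full (n*T) x u matrix of upstream gradients (sequence
# output) or an n x u matrix applied at the final timestep only.
lstm_backward_batch <- function(layer, Xbig, fwd, dA, n, Tlen,
                                last_only = FALSE) {
  u <- layer$units
  Wa_t <- t(layer$Wa)
  Gbig <- matrix(0, n * Tlen, 4L * u)
  dWa <- matrix(0, u, 4L * u)
  da_next <- matrix(0, n, u)
  dc_next <- matrix(0, n, u)
  for (t in rev(seq_len(Tlen))) {
    st <- fwd$steps[[t]]
    rows <- t_rows(t, n, Tlen)
    da_above <- if (last_only) {
      if (t == Tlen) dA else matrix(0, n, u)
    } else dA[rows, , drop = FALSE]
    da <- da_above + da_next
    dpre_o <- (da * st$tc) * st$O * (1 - st$O)
    dc <- dc_next + da * st$O * (1 - st$tc^2)
    dpre_f <- (dc * st$cprev) * st$Fg * (1 - st$Fg)
    dpre_i <- (dc * st$G) * st$I * (1 - st$I)
    dpre_g <- (dc * st$I) * (1 - st$G^2)
    dc_next <- dc * st$Fg
    dpre <- cbind(dpre_i, dpre_f, dpre_g, dpre_o)
    Gbig[rows, ] <- dpre
    dWa <- dWa + crossprod(st$aprev, dpre)
    da_next <- dpre %*% Wa_t
  }
  list(dX = Gbig %*% t(layer$Wx),
       grads = list(Wx = crossprod(Xbig, Gbig), Wa = dWa,
                    b = colSums(Gbig)))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Full network forward. Returns probs, the per-layer cache (when training),
# and the model (whose batch-norm running statistics are updated when
# training). Dropout draws from the current RNG stream.
engine_forward <- function(model, Xbig, n, Tlen, training = FALSE) {
  layers <- model$layers
  lstm_idx <- which(vapply(layers, function(l) l$type == "lstm",
                           logical(1)))
  last_lstm <- max(lstm_idx)
  caches <- vector("list", length(layers))
  cur <- Xbig
  for (L in seq_along(layers)) {
    layer <- layers[[L]]
    if (layer$type == "lstm") {
      fwd <- lstm_forward_batch(layer, cur, n, Tlen, keep_cache = training)
      if (training) caches[[L]] <- list(X = cur, fwd = fwd)
      cur <- if (L == last_lstm) fwd$last else fwd$Aseq
    } else if (layer$type == "dense") {
      H <- cur
      Z <- H %*% layer$W + rep(layer$b, each = nrow(H))
      out <- switch(layer$activation,
                    tanh = tanh(Z),
                    softmax = softmax_rows(Z),
                    identity = Z)
      if (training) caches[[L]] <- list(H = H, out = out)
      cur <- out
    } else if (layer$type == "batchnorm") {
      Z <- cur
      if (training) {
        mu <- colMeans(Z)
        zc <- Z - rep(mu, each = nrow(Z))
        va <- colMeans(zc^2)
        istd <- 1 / sqrt(va + layer$eps)
        zhat <- zc * rep(istd, each = nrow(Z))
        mom <- layer$momentum
        layer$run_mean <- mom * layer$run_mean + (1 - mom) * mu
        layer$run_var <- mom * layer$run_var + (1 - mom) * va
        model$layers[[L]] <- layer
        caches[[L]] <- list(zhat = zhat, istd = istd)
      } else {
        istd <- 1 / sqrt(layer$run_var + layer$eps)
        zhat <- (Z - rep(layer$run_mean, each = nrow(Z))) *
          rep(istd, each = nrow(Z))
      }
      cur <- zhat * rep(layer$gamma, each = nrow(Z)) +
        rep(layer$beta, each = nrow(Z))
    } else if (layer$type == "dropout") {
      if (training && layer$rate > 0) {
        keep <- 1 - layer$rate
        mask <- matrix(stats::rbinom(length(cur), 1L, keep) / keep,
                       nrow(cur), ncol(cur))
        caches[[L]] <- list(mask = mask)
        cur <- cur * mask
      }
    } else gm_stop(paste("unknown layer type", layer$type), "contract")
  }
  list(probs = cur, caches = caches, model = model)
}

# Backward pass from softmax + categorical cross-entropy. Y is the n x K
# one-hot matrix. Returns a list of per-layer gradient lists.
engine_backward <- function(model, fwd, Y, n, Tlen) {
  layers <- model$layers
  caches <- fwd$caches
  lstm_idx <- which(vapply(layers, function(l) l$type == "lstm",
                           logical(1)))
  last_lstm <- max(lstm_idx)
  grads <- vector("list", length(layers))
  dcur <- NULL
  for (L in rev(seq_along(layers))) {
    layer <- layers[[L]]
    if (layer$type == "dense") {
      cache <- caches[[L]]
      dZ <- if (layer$activation == "softmax") {
        (cache$out - Y) / n          # loss gradient folded into the output
      } else {
        dcur * (1 - cache$out^2)     # tanh'
      }
      grads[[L]] <- list(W = crossprod(cache$H, dZ), b = colSums(dZ))
      dcur <- dZ %*% t(layer$W)
    } else if (layer$type == "batchnorm") {
      cache <- caches[[L]]
      zhat <- cache$zhat; istd <- cache$istd
      m <- nrow(zhat)
      dzhat <- dcur * rep(layer$gamma, each = m)
      grads[[L]] <- list(gamma = colSums(dcur * zhat),
                         beta = colSums(dcur))
      s1 <- colSums(dzhat)
      s2 <- colSums(dzhat * zhat)
      dcur <- (dzhat - rep(s1 / m, each = m) -
                 zhat * rep(s2 / m, each = m)) * rep(istd, each = m)
    } else if (layer$type == "dropout") {
      if (!is.null(caches[[L]])) dcur <- dcur * caches[[L]]$mask
    } else if (layer$type == "lstm") {
      cache <- caches[[L]]
      bk <- lstm_backward_batch(layer, cache$X, cache$fwd, dcur, n, Tlen,
                                last_only = (L == last_lstm))
      grads[[L]] <- bk$grads
      dcur <- bk$dX
    }
  }
  grads
}

# ---- user-facing forward / predict ----------------------------------------

as_feature_batch <- function(features, config) {
  if (is.matrix(features)) features <- list(features)
  if (!is.list(features) || !length(features))
    gm_stop("'features' must be a T x D matrix or a list of them",
            "contract")
  for (f in features) {
    if (!is.matrix(f))
      gm_stop("each element of 'features' must be a T x D matrix",
              "contract")
    if (ncol(f) != config$input_dim)
      gm_stop(sprintf("feature width %d does not match the model input_dim %d",
                      ncol(f), config$input_dim), "contract")
    if (nrow(f) != config$sequence_length)
      gm_stop(sprintf("sequence length %d does not match the model (%d frames)",
                      nrow(f), config$sequence_length), "contract")
  }
  features
}

#' Forward pass: class probabilities
#'
#' Runs the network in inference mode (batch normalization uses its running
#' statistics, dropout is disabled) and returns softmax probabilities.
#'
#' @param model A `gait_model` from [init_network()] or [train_model()].
#' @param features A `T x D` feature matrix (see [assemble_input()]) or a
#'   list of them (a batch).
#' @return An `n x n_classes` matrix of probabilities; every row sums to 1.
#' @export
forward <- function(model, features) {
  stopifnot(inherits(model, "gait_model"))
  xs <- as_feature_batch(features, model$config)
  n <- length(xs); Tlen <- model$config$sequence_length
  Xbig <- do.call(rbind, lapply(xs, unclass))
  probs <- engine_forward(model, Xbig, n, Tlen, training = FALSE)$probs
  if (!is.null(model$class_names)) colnames(probs) <- model$class_names
  probs
}

#' Predict emotion labels
#'
#' Argmax of [forward()]; exact probability ties are broken by the lowest
#' class index (deterministic).
#'
#' @param object A `gait_model`.
#' @param features As in [forward()].
#' @param type `"label"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Character labels (or class indices if the model carries no class
#'   names); for `type = "prob"`, the probability matrix.
#' @export
predict.gait_model <- function(object, features, type = c("label", "prob"),
                               ...) {
  type <- match.arg(type)
  probs <- forward(object, features)
  if (type == "prob") return(probs)
  idx <- apply(probs, 1L, which.max)   # which.max: first max wins ties
  if (!is.null(object$class_names)) object$class_names[idx] else idx
}
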