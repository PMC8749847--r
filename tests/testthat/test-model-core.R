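test_that("lstm_cell_step: zero weights, saturated forget, scalar oracle", {
  u <- 3L; d <- 2L
  zero <- lstm_cell_weights(
    W_ix = matrix(0, u, d), W_fx = matrix(0, u, d), W_cx = matrix(0, u, d),
    W_ox = matrix(0, u, d), W_ia = matrix(0, u, u), W_fa = matrix(0, u, u),
    W_ca = matrix(0, u, u), W_oa = matrix(0, u, u),
    b_i = rep(0, u), b_f = rep(0, u), b_c = rep(0, u), b_o = rep(0, u))
  st <- lstm_cell_step(zero, c(1, -2), rep(0.5, u), rep(0, u))
  expect_equal(st$a, rep(0, u))   # candidate tanh(0) = 0 kills the update
  expect_equal(st$c, rep(0, u))

  # large forget bias preserves the stored memory
  sat <- lstm_cell_weights(
    W_ix = matrix(0, 1, 1), W_fx = matrix(0, 1, 1), W_cx = matrix(0, 1, 1),
    W_ox = matrix(0, 1, 1), W_ia = matrix(0, 1, 1), W_fa = matrix(0, 1, 1),
    W_ca = matrix(0, 1, 1), W_oa = matrix(0, 1, 1),
    b_i = 0, b_f = 60, b_c = 0, b_o = 0)
  st <- lstm_cell_step(sat, 0.3, 0.1, 3)
  expect_equal(st$c, 3, tolerance = 1e-12)

  # random scalar cell against a literal transcription of the equations
  for (sd in 1:10) {
    w <- rand_cell_weights(1L, 1L, seed = sd)
    x <- 0.7; a0 <- -0.2; c0 <- 0.4
    sig <- function(z) 1 / (1 + exp(-z))
    i <- sig(w$W_ix[1, 1] * x + w$W_ia[1, 1] * a0 + w$b_i)
    f <- sig(w$W_fx[1, 1] * x + w$W_fa[1, 1] * a0 + w$b_f)
    o <- sig(w$W_ox[1, 1] * x + w$W_oa[1, 1] * a0 + w$b_o)
    g <- tanh(w$W_cx[1, 1] * x + w$W_ca[1, 1] * a0 + w$b_c)
    cc <- f * c0 + i * g
    st <- lstm_cell_step(w, x, a0, c0)
    expect_equal(st$c, cc, tolerance = 1e-12)
    expect_equal(st$a, o * tanh(cc), tolerance = 1e-12)
  }
  expect_error(lstm_cell_step(zero, c(1, 2, 3), rep(0, u), rep(0, u)),
               class = "gaitmood_contract_error")
})

test_that("gru_memory_update is the elementwise convex combination", {
  expect_equal(gru_memory_update(c(0, 0), c(2, -1), c(5, 5)), c(2, -1))
  expect_equal(gru_memory_update(c(1, 1), c(2, -1), c(5, 5)), c(5, 5))
  expect_equal(gru_memory_update(0.5, 2, 4), 3)
  expect_error(gru_memory_update(1.2, 1, 1), class = "gaitmood_contract_error")
  expect_error(gru_memory_update(c(0.5), c(1, 2), c(1, 2)),
               class = "gaitmood_contract_error")
})

test_that("lstm_layer_forward: base case, zero case, last-step mode", {
  w <- rand_cell_weights(3L, 2L, seed = 4)
  X <- matrix(c(0.3, -0.6), 1, 2)
  one <- lstm_layer_forward(w, X)
  st <- lstm_cell_step(w, X[1, ], rep(0, 3), rep(0, 3))
  expect_equal(as.numeric(one), st$a)
  Xz <- matrix(0, 5, 2)
  wz <- rand_cell_weights(3L, 2L, seed = 5, scale = 0)
  expect_true(all(lstm_layer_forward(wz, Xz) == 0))
  X5 <- matrix(stats::rnorm(10), 5, 2)
  full <- lstm_layer_forward(w, X5, return_sequence = TRUE)
  expect_equal(lstm_layer_forward(w, X5, return_sequence = FALSE),
               full[5, ])
  expect_true(all(abs(full) < 1))
})

test_that("vectorized engine layer matches the reference cell path", {
  for (sd in 1:20) {
    withr::with_seed(sd, {
      u <- sample(2:8, 1); d <- sample(2:6, 1); Tn <- sample(2:10, 1)
      n <- sample(1:3, 1)
    })
    w <- rand_cell_weights(u, d, seed = 100 + sd)
    layer <- gaitmood:::pack_lstm_weights(w)
    xs <- lapply(1:n, function(i)
      withr::with_seed(sd * 37 + i, matrix(stats::rnorm(Tn * d), Tn, d)))
    Xbig <- do.call(rbind, xs)
    eng <- gaitmood:::lstm_forward_batch(layer, Xbig, n, Tn)
    for (i in 1:n) {
      ref <- lstm_layer_forward(w, xs[[i]], return_sequence = TRUE)
      rows <- (i - 1L) * Tn + seq_len(Tn)
      expect_lt(max(abs(eng$Aseq[rows, , drop = FALSE] - ref)), 1e-10)
    }
    # pack/unpack is an exact involution
    w2 <- gaitmood:::unpack_lstm_weights(layer)
    expect_equal(w2$W_cx, w$W_cx)
    expect_equal(w2$b_o, w$b_o)
  }
})

test_that("count_parameters closed form equals the allocated weight count", {
  # reference architecture variants
  expect_identical(count_parameters(network_config(273, 240)), 295684L)
  expect_identical(
    count_parameters(network_config(273, 240,
                                    batchnorm_after_first_mlp = TRUE)),
    295940L)
  expect_identical(count_parameters(network_config(48, 240)), 180484L)
  # fuzz: closed form == sum over actually allocated arrays
  for (sd in 1:50) {
    cfg <- withr::with_seed(sd, {
      nl <- sample(1:3, 1); nm <- sample(1:3, 1)
      network_config(
        input_dim = sample(2:40, 1), sequence_length = sample(2:8, 1),
        lstm_units = sort(sample(1:12, nl, replace = TRUE),
                          decreasing = TRUE),
        mlp_units = sort(sample(1:12, nm, replace = TRUE),
                         decreasing = TRUE),
        n_classes = sample(2:5, 1),
        batchnorm_after_first_mlp = sample(c(TRUE, FALSE), 1),
        dropout_position = sample(0:nm, 1))
    })
    m <- init_network(cfg, seed = sd)
    expect_identical(count_parameters(m), count_parameters(cfg))
    expect_identical(sum(m$spec$trainable + m$spec$auxiliary),
                     as.numeric(count_parameters(cfg)))
  }
})

test_that("build_network descriptors match the declared architecture", {
  spec <- build_network(network_config(273, 240))
  expect_equal(sum(spec$kind %in% c("lstm", "dense")), 7L)
  expect_equal(spec$fan_out[spec$kind %in% c("lstm", "dense")],
               c(128, 64, 64, 64, 32, 32, 4))
  expect_equal(spec$activation[nrow(spec)], "softmax")
  bn <- build_network(network_config(273, 240,
                                     batchnorm_after_first_mlp = TRUE))
  expect_true("batchnorm" %in% bn$kind)
  row <- bn[bn$kind == "batchnorm", ]
  expect_equal(row$trainable + row$auxiliary, 4 * 64)
  expect_equal(sum(bn$trainable + bn$auxiliary) -
                 sum(spec$trainable + spec$auxiliary), 256)
  two <- build_network(network_config(10, 5, lstm_units = c(4, 2),
                                      mlp_units = c(2), n_classes = 2,
                                      dropout_position = 0))
  expect_equal(two$fan_out[nrow(two)], 2)
})

test_that("tapered invariant is enforced with an override", {
  expect_error(network_config(10, 5, lstm_units = c(8, 16, 16)),
               class = "gaitmood_config_error")
  expect_error(network_config(10, 5, mlp_units = c(8, 16)),
               class = "gaitmood_config_error")
  cfg <- network_config(10, 5, lstm_units = c(8, 16, 16),
                        allow_non_tapered = TRUE)
  expect_s3_class(cfg, "network_config")
  expect_error(network_config(10, 5, dropout_rate = 1),
               class = "gaitmood_config_error")
  expect_error(network_config(10, 5, n_classes = 1),
               class = "gaitmood_config_error")
})

test_that("forward emits normalized probabilities; predict takes argmax", {
  cfg <- network_config(6, 4, lstm_units = c(4, 3, 3),
                        mlp_units = c(3, 2, 2), dropout_position = 0)
  m <- init_network(cfg, seed = 3, final_layer_init = "glorot")
  xs <- lapply(1:5, function(i)
    withr::with_seed(i, matrix(stats::rnorm(24), 4, 6)))
  p <- forward(m, xs)
  expect_equal(dim(p), c(5L, 4L))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-12)
  expect_true(all(p >= 0))
  # zeroed output layer -> exactly uniform probabilities
  mz <- init_network(cfg, seed = 3, final_layer_init = "zeros")
  expect_equal(as.numeric(forward(mz, xs[[1]])), rep(0.25, 4))
  # batch permutation equivariance
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(forward(m, xs[perm]), p[perm, ])
  # width mismatch names expected and actual
  expect_error(forward(m, matrix(0, 4, 5)), "5.*6|6.*5",
               class = "gaitmood_contract_error")
  # predict = argmax(forward); exact ties resolve to the lowest index
  m$class_names <- emotion_classes()
  lab <- predict(m, xs)
  expect_equal(lab, emotion_classes()[apply(forward(m, xs), 1, which.max)])
  mz$class_names <- emotion_classes()
  expect_equal(predict(mz, xs[[1]]), "angry")
})

test_that("hidden LSTM activations stay inside (-1, 1)", {
  cfg <- network_config(5, 6, lstm_units = c(4, 3, 3),
                        mlp_units = c(3, 3, 3))
  m <- init_network(cfg, seed = 11)
  X <- withr::with_seed(1, matrix(stats::rnorm(6 * 5, sd = 4), 6, 5))
  fwd <- gaitmood:::engine_forward(m, X, 1L, 6L, training = TRUE)
  for (L in 1:3) {
    a <- fwd$caches[[L]]$fwd$Aseq
    expect_true(all(abs(a) < 1))
  }
})
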