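# Shared fixture builders. Everything is generated in code; no data files.

tiny_topology <- function(V = 4L, C = 3L, rj = 1L, fps = 30) {
  skeleton_topology(sprintf("j%02d", seq_len(V) - 1L), n_coords = C,
                    relative_joint = rj, fps = fps)
}

random_sequence <- function(Tn = 6L, topology = tiny_topology(),
                            seed = 1L, label = NA_character_,
                            id = "rseq") {
  withr::with_seed(seed, {
    gait_sequence(array(stats::rnorm(Tn * topology$n_joints *
                                       topology$n_coords),
                        dim = c(Tn, topology$n_joints,
                                topology$n_coords)),
                  label = label, sequence_id = id, topology = topology)
  })
}

# A labeled dataset of pure-noise sequences (for split/IO plumbing tests).
noise_dataset <- function(class_counts, Tn = 4L,
                          topology = tiny_topology(), seed = 1L) {
  seqs <- list(); k <- 0L
  for (cls in names(class_counts)) {
    for (i in seq_len(class_counts[[cls]])) {
      k <- k + 1L
      seqs[[k]] <- random_sequence(Tn, topology, seed = seed + k,
                                   label = cls,
                                   id = sprintf("%s_%03d", cls, i))
    }
  }
  gait_dataset(seqs, topology, class_names = names(class_counts))
}

balanced_gc <- function(n_per_class = 10L, Tn = 20L, seed = 1L) {
  generator_config(class_counts = c(angry = n_per_class,
                                    happy = n_per_class,
                                    sad = n_per_class,
                                    neutral = n_per_class),
                   n_frames = Tn, seed = seed)
}

# Random per-gate reference cell weights.
rand_cell_weights <- function(u, d, seed = 1L, scale = 0.5) {
  withr::with_seed(seed, {
    m <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = scale), nr, nc)
    lstm_cell_weights(
      W_ix = m(u, d), W_fx = m(u, d), W_cx = m(u, d), W_ox = m(u, d),
      W_ia = m(u, u), W_fa = m(u, u), W_ca = m(u, u), W_oa = m(u, u),
      b_i = stats::rnorm(u, sd = scale), b_f = stats::rnorm(u, sd = scale),
      b_c = stats::rnorm(u, sd = scale), b_o = stats::rnorm(u, sd = scale))
  })
}

dataset_labels_for_test <- function(ds) {
  vapply(ds$sequences, function(s) s$label, character(1))
}

dataset_ids_of <- function(ds) {
  vapply(ds$sequences, function(s) s$sequence_id, character(1))
}

seq_by_id <- function(ds, id) {
  ds$sequences[[which(dataset_ids_of(ds) == id)[1]]]
}

# Assembled features of the train-split sequence with the given id, using
# the run's own stored feature configuration.
feature_of <- function(run, id) {
  ds <- run$split$train
  ids <- vapply(ds$sequences, function(s) s$sequence_id, character(1))
  fc <- do.call(feature_config,
                run$manifest$feature_config[
                  c("use_jra", "use_jrd", "relative_joint", "center")])
  unclass(assemble_input(ds$sequences[[which(ids == id)[1]]],
                         ds$topology, fc))
}

# A 3-d rotation matrix (uniform via QR, det +1).
rand_rotation <- function(seed = 1L) {
  withr::with_seed(seed, {
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
  })
}

# Hand-constructed perfectly separable 2-class world + a model wired by
# hand to classify it: class "lo" has all coordinates 0, class "hi" all
# coordinates 10. The model pushes the first coordinate through saturated
# 1-unit LSTM layers and an amplifying 1-unit MLP to a +/- readout.
separator_world <- function(n_per_class = 5L, Tn = 5L) {
  topo <- tiny_topology(V = 2L, C = 2L, rj = 1L)
  mk <- function(v, cls, i) gait_sequence(
    array(v, dim = c(Tn, 2L, 2L)), label = cls,
    sequence_id = sprintf("%s_%d", cls, i), topology = topo)
  seqs <- c(lapply(seq_len(n_per_class), function(i) mk(0, "lo", i)),
            lapply(seq_len(n_per_class), function(i) mk(10, "hi", i)))
  dataset <- gait_dataset(seqs, topo, class_names = c("lo", "hi"))

  cfg <- network_config(input_dim = 4L, sequence_length = Tn,
                        lstm_units = c(1L, 1L, 1L), mlp_units = c(1L, 1L, 1L),
                        n_classes = 2L, dropout_position = 0L)
  model <- init_network(cfg, seed = 1L)
  big <- 25
  wire_lstm <- function(w_in) {
    # gates [i|f|c|o]: i ~ 1, f ~ 0, o ~ 1; candidate reads the input
    list(type = "lstm", units = 1L,
         Wx = matrix(c(0, 0, w_in, 0), 1, 4),
         Wa = matrix(0, 1, 4),
         b = c(big, -big, 0, big))
  }
  model$layers[[1]] <- wire_lstm(c(1))          # reads input coord 1
  model$layers[[1]]$Wx <- rbind(c(0, 0, 1, 0), matrix(0, 3, 4))
  model$layers[[2]] <- wire_lstm(3)
  model$layers[[3]] <- wire_lstm(3)
  for (k in 4:6) model$layers[[k]] <- list(type = "dense", units = 1L,
                                           activation = "tanh",
                                           W = matrix(3, 1, 1), b = 0)
  model$layers[[7]] <- list(type = "dense", units = 2L,
                            activation = "softmax",
                            W = matrix(c(-5, 5), 1, 2), b = c(0, 0))
  model$class_names <- c("lo", "hi")
  list(dataset = dataset, model = model,
       feature_config = feature_config(use_jra = FALSE, use_jrd = FALSE))
}

# Desk-scale architecture used by the learning criteria: the default
# tapered bi-modular shape at reduced width so a 20-epoch run fits a
# single-CPU budget.
desk_network <- function(D, Tn = 60L) {
  network_config(input_dim = D, sequence_length = Tn,
                 lstm_units = c(16L, 8L, 8L), mlp_units = c(16L, 8L, 8L))
}
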