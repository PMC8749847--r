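test_that("topology validation rejects bad inputs", {
  expect_error(skeleton_topology(c("a"), 3, 1), class = "gaitmood_config_error")
  expect_error(skeleton_topology(c("a", "a"), 3, 1),
               class = "gaitmood_config_error")
  expect_error(skeleton_topology(c("a", "b"), 4, 1),
               class = "gaitmood_config_error")
  expect_error(skeleton_topology(c("a", "b"), 3, 3),
               class = "gaitmood_config_error")
  topo <- default_topology()
  expect_equal(topo$n_joints, 16L)
  expect_equal(topo$n_coords, 3L)
  expect_equal(topo$joint_names[topo$relative_joint], "spine")
})

test_that("gait_sequence and gait_dataset enforce their invariants", {
  topo <- tiny_topology()
  expect_error(gait_sequence(matrix(0, 2, 2)), class = "gaitmood_contract_error")
  bad <- array(0, c(2, 4, 3)); bad[1, 1, 1] <- NaN
  expect_error(gait_sequence(bad), class = "gaitmood_contract_error")
  expect_error(gait_sequence(array(0, c(2, 3, 3)), topology = topo),
               class = "gaitmood_contract_error")
  s1 <- random_sequence(4, topo, 1, label = "angry", id = "a")
  s2 <- random_sequence(5, topo, 2, label = "happy", id = "b")
  expect_error(gait_dataset(list(s1, s2), topo), class = "gaitmood_format_error")
  s3 <- random_sequence(4, topo, 3, label = "bogus", id = "c")
  expect_error(gait_dataset(list(s1, s3), topo), class = "gaitmood_format_error")
})

test_that("zero-case CSV reads to an all-zero array of the right shape", {
  topo <- tiny_topology(V = 2L, C = 3L)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("j00_x,j00_y,j00_z,j01_x,j01_y,j01_z",
               "0,0,0,0,0,0", "0,0,0,0,0,0"), path)
  s <- read_gait_csv(path, topo)
  expect_equal(dim(s$coords), c(2L, 2L, 3L))
  expect_true(all(s$coords == 0))
})

test_that("CSV round-trip preserves coords within 1e-9 and metadata exactly", {
  topo <- default_topology()
  s <- random_sequence(240, topo, seed = 7, label = "sad", id = "rt01")
  path <- withr::local_tempfile(fileext = ".csv")
  write_gait_csv(s, path, topo)
  back <- read_gait_csv(path, topo)
  expect_lt(max(abs(back$coords - s$coords)), 1e-9)
  expect_identical(back$label, "sad")
  expect_identical(back$sequence_id, "rt01")
  # shape of the reference corpus: 240 frames x 48 coordinate columns
  expect_equal(dim(back$coords), c(240L, 16L, 3L))
  # unlabeled sequence: sidecar stores null, reads back as NA
  s2 <- random_sequence(3, topo, seed = 8, id = "u1")
  write_gait_csv(s2, path, topo)
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", path))
  expect_null(meta$label)
  expect_true(is.na(read_gait_csv(path, topo)$label))
})

test_that("CSV format errors name the offending column / row", {
  topo <- tiny_topology(V = 2L, C = 2L)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("j00_x,j00_y,j01_x", "0,0,0"), path)
  expect_error(read_gait_csv(path, topo), "j01_y",
               class = "gaitmood_format_error")
  writeLines(c("j00_x,j00_y,j01_x,j01_y,extra", "0,0,0,0,0"), path)
  expect_error(read_gait_csv(path, topo), "extra",
               class = "gaitmood_format_error")
  writeLines(c("j00_x,j00_y,j01_x,j01_y", "0,0,0,0", "0,oops,0,0"), path)
  expect_error(read_gait_csv(path, topo), "row 2",
               class = "gaitmood_format_error")
})

test_that("dataset manifest round-trips through a directory", {
  topo <- tiny_topology()
  ds <- noise_dataset(c(angry = 3, happy = 2), Tn = 5, topology = topo)
  dir <- withr::local_tempdir()
  mp <- write_gait_dataset(ds, dir)
  back <- read_gait_dataset(mp)
  expect_equal(length(back), 5L)
  expect_equal(sort(dataset_labels_for_test(back)),
               sort(dataset_labels_for_test(ds)))
  expect_lt(max(abs(back$sequences[[1]]$coords - ds$sequences[[1]]$coords)),
            1e-9)
})

test_that("flatten_frames orders axes fastest and inverts exactly", {
  topo <- tiny_topology(V = 2L, C = 3L)
  s <- gait_sequence(array(c(1, 4, 2, 5, 3, 6), dim = c(1, 2, 3)),
                     topology = topo)
  expect_equal(as.numeric(flatten_frames(s)), c(1, 2, 3, 4, 5, 6))
  big <- random_sequence(240, default_topology(), seed = 3)
  m <- flatten_frames(big, default_topology())
  expect_equal(dim(m), c(240L, 48L))
  back <- unflatten_frames(m, default_topology())
  expect_identical(back$coords, big$coords)
})

test_that("stratified split: exact division gives 8/1/1 per class", {
  ds <- noise_dataset(c(angry = 10, happy = 10, sad = 10, neutral = 10))
  sp <- stratified_split(ds, c(0.8, 0.1, 0.1), seed = 5)
  want <- c(train = 8L, validation = 1L, test = 1L)
  for (part in names(want)) {
    tab <- table(dataset_labels_for_test(sp[[part]]))
    expect_true(all(tab == want[[part]]))
    expect_equal(length(sp[[part]]), 4L * want[[part]])
  }
})

# Independent largest-remainder oracle: floors, then distribute leftovers
# by descending remainder, ties to test then validation.
lr_oracle <- function(n, fr) {
  base <- floor(n * fr); rem <- n * fr - base
  left <- n - sum(base)
  while (left > 0) {
    cand <- which(rem == max(rem))
    pick <- cand[length(cand)]        # later split wins a tie
    base[pick] <- base[pick] + 1; rem[pick] <- -1; left <- left - 1
  }
  base
}

test_that("split allocation matches the largest-remainder oracle per class", {
  counts <- c(angry = 1048, happy = 454, sad = 254, neutral = 79)
  fr <- c(0.8, 0.1, 0.1)
  # oracle expectations (enumerated independently above)
  expected <- vapply(counts, lr_oracle, numeric(3), fr = fr)
  ds <- noise_dataset(c(angry = 20, happy = 13, sad = 7, neutral = 9),
                      Tn = 2, topology = tiny_topology(V = 2L, C = 2L))
  sp <- stratified_split(ds, fr, seed = 1)
  small <- c(angry = 20, happy = 13, sad = 7, neutral = 9)
  got <- sapply(c("train", "validation", "test"), function(p)
    table(factor(dataset_labels_for_test(sp[[p]]), levels = names(small))))
  for (cls in names(small))
    expect_equal(unname(got[cls, ]), unname(lr_oracle(small[[cls]], fr)))
  # per-class totals are preserved for the reference class profile
  expect_equal(unname(colSums(expected)), unname(counts))
  # stratification bound: every split within 1 sample of its quota
  for (cls in names(small))
    expect_true(all(abs(got[cls, ] - small[[cls]] * fr) < 1))
})

test_that("split is a seeded deterministic partition", {
  ds <- noise_dataset(c(angry = 9, happy = 5, sad = 4, neutral = 3),
                      Tn = 2, topology = tiny_topology(V = 2L, C = 2L))
  a <- stratified_split(ds, c(0.8, 0.1, 0.1), seed = 42)
  b <- stratified_split(ds, c(0.8, 0.1, 0.1), seed = 42)
  expect_identical(lapply(a$indices, sort), lapply(b$indices, sort))
  expect_identical(a$indices, b$indices)
})

test_that("split partition + stratification properties hold over many seeds", {
  topo <- tiny_topology(V = 2L, C = 2L)
  fr_sets <- list(c(0.8, 0.1, 0.1), c(0.6, 0.2, 0.2), c(0.5, 0.3, 0.2))
  withr::with_seed(99, {
    profiles <- replicate(20, {
      n <- sample(3:25, 4, replace = TRUE)
      names(n) <- emotion_classes()
      n
    }, simplify = FALSE)
  })
  for (p in seq_along(profiles)) {
    ds <- noise_dataset(profiles[[p]], Tn = 2, topology = topo)
    for (s in 1:10) {
      fr <- fr_sets[[1 + (s %% length(fr_sets))]]
      sp <- stratified_split(ds, fr, seed = s)
      idx <- sp$indices
      expect_equal(sort(unname(unlist(idx))), seq_len(length(ds)))
      expect_equal(length(intersect(idx$train, idx$test)), 0L)
      expect_equal(length(intersect(idx$train, idx$validation)), 0L)
      labs <- dataset_labels_for_test(ds)
      for (cls in names(profiles[[p]])) {
        nc <- profiles[[p]][[cls]]
        for (k in 1:3)
          expect_lt(abs(sum(labs[idx[[k]]] == cls) - nc * fr[k]), 1)
      }
    }
  }
})

test_that("split errors: empty class, bad fractions, unlabeled data", {
  ds <- noise_dataset(c(angry = 4, happy = 4, sad = 4, neutral = 4),
                      Tn = 2, topology = tiny_topology(V = 2L, C = 2L))
  expect_error(stratified_split(ds, c(0.8, 0.1, 0.2), seed = 1),
               class = "gaitmood_config_error")
  expect_error(stratified_split(ds, c(0.9, 0.1, 0), seed = 1),
               class = "gaitmood_config_error")
  ds$class_names <- c(ds$class_names, "bored")
  expect_error(stratified_split(ds, c(0.8, 0.1, 0.1), seed = 1),
               class = "gaitmood_stratification_error")
  topo <- tiny_topology(V = 2L, C = 2L)
  s_na <- random_sequence(2, topo, 1, id = "u")
  ds2 <- gait_dataset(list(s_na), topo)
  expect_error(stratified_split(ds2, c(0.8, 0.1, 0.1), seed = 1),
               class = "gaitmood_stratification_error")
})
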