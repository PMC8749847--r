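# Gait CSV + JSON sidecar interchange format.
#
# A gait sequence is stored as a plain UTF-8 CSV with one header line
# ("<joint>_<axis>" columns in topology order, axes fastest) and one row per
# frame, '.' as decimal separator. Metadata lives in a JSON sidecar with the
# same stem: {label, sequence_id, fps, joint_names, relative_joint}. A
# dataset is a manifest JSON listing member CSVs plus the topology.

sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".json")

#' Write a gait sequence to CSV (+ JSON sidecar)
#'
#' @param seq A [gait_sequence()].
#' @param path Output CSV path; the sidecar is written next to it with a
#'   `.json` extension. An unlabeled sequence gets `"label": null`.
#' @param topology The owning [skeleton_topology()] (provides headers and
#'   sidecar fields).
#' @return Invisibly, `path`.
#' @seealso [read_gait_csv()]
#' @export
write_gait_csv <- function(seq, path, topology) {
  m <- flatten_frames(seq, topology)
  ok <- tryCatch({
    data.table::fwrite(data.table::as.data.table(m), path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    gm_stop(sprintf("cannot write '%s': %s", path,
                    conditionMessage(ok)), "io")
  meta <- list(label = if (is.na(seq$label)) NULL else seq$label,
               sequence_id = seq$sequence_id,
               fps = topology$fps,
               joint_names = topology$joint_names,
               relative_joint = topology$relative_joint)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Read a gait sequence from CSV (+ JSON sidecar)
#'
#' Validates the header against the topology (missing or extra columns are
#' reported by name) and that every cell is numeric (parse failures are
#' reported with their row index). Round-trips losslessly with
#' [write_gait_csv()] to within text precision (`1e-9`).
#'
#' @param path CSV path; if `<stem>.json` exists its label/id are attached.
#' @param topology The expected [skeleton_topology()].
#' @return A [gait_sequence()].
#' @export
read_gait_csv <- function(path, topology) {
  if (!file.exists(path))
    gm_stop(sprintf("file not found: '%s'", path), "io")
  dt <- data.table::fread(path, colClasses = "character", header = TRUE)
  want <- coord_headers(topology)
  have <- names(dt)
  missing <- setdiff(want, have)
  extra <- setdiff(have, want)
  if (length(missing) || length(extra))
    gm_stop(sprintf(
      "column mismatch in '%s': missing [%s], unexpected [%s]", path,
      paste(missing, collapse = ", "), paste(extra, collapse = ", ")),
      "format")
  m <- suppressWarnings(
    vapply(want, function(cn) as.numeric(dt[[cn]]), numeric(nrow(dt))))
  if (nrow(dt) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, want))
  if (anyNA(m)) {
    bad_row <- which(apply(is.na(m), 1L, any))[1]
    gm_stop(sprintf("non-numeric value in '%s' at data row %d", path,
                    bad_row), "format")
  }
  label <- NA_character_
  sequence_id <- sub("\\.csv$", "", basename(path))
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    meta <- jsonlite::read_json(sp)
    label <- meta$label %||% NA_character_
    sequence_id <- meta$sequence_id %||% sequence_id
  }
  unflatten_frames(m, topology, label = label, sequence_id = sequence_id)
}

#' Write a gait dataset to a directory
#'
#' Writes one CSV (+ sidecar) per sequence and a `manifest.json` recording
#' the topology, class names and member files.
#'
#' @param dataset A [gait_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_gait_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(dataset$sequences))
  for (k in seq_along(dataset$sequences)) {
    s <- dataset$sequences[[k]]
    files[k] <- paste0(gsub("[^A-Za-z0-9_.-]", "_", s$sequence_id), ".csv")
    write_gait_csv(s, file.path(dir, files[k]), dataset$topology)
  }
  manifest <- list(format = "gaitmood-dataset/1",
                   topology = topology_to_list(dataset$topology),
                   class_names = dataset$class_names,
                   sequences = files)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Read a gait dataset from a manifest
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [write_gait_dataset()]. Member CSVs are resolved relative to it. The
#'   loader enforces a uniform sequence length.
#' @return A [gait_dataset()].
#' @export
read_gait_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path))
    gm_stop(sprintf("manifest not found: '%s'", manifest_path), "io")
  man <- tryCatch(jsonlite::read_json(manifest_path), error = function(e)
    gm_stop(sprintf("cannot parse manifest '%s': %s", manifest_path,
                    conditionMessage(e)), "format"))
  if (is.null(man$topology))
    gm_stop(sprintf("'%s' is not a dataset manifest (no topology block)",
                    manifest_path), "format")
  topology <- topology_from_list(man$topology)
  dir <- dirname(manifest_path)
  seqs <- lapply(unlist(man$sequences), function(f)
    read_gait_csv(file.path(dir, f), topology))
  gait_dataset(seqs, topology,
               class_names = unlist(man$class_names) %||% emotion_classes())
}

#' Stratified train/validation/test split
#'
#' Splits a labeled dataset so that every split preserves the per-class
#' proportions of the whole dataset (stratified shuffling). Within each
#' class the samples are shuffled with the given seed and allocated to the
#' splits by largest-remainder rounding of `class_count * fraction`;
#' remainder ties favour the test split, then validation. The three splits
#' partition the dataset exactly.
#'
#' @param dataset A fully labeled [gait_dataset()].
#' @param fractions Positive train/validation/test fractions summing to 1.
#' @param seed Integer seed controlling the within-class shuffle.
#' @return An object of class `gait_split`: a list with `gait_dataset`
#'   elements `train`, `validation`, `test`.
#' @examples
#' gc <- generator_config(scale = 40 / 1835, n_frames = 10, seed = 7)
#' ds <- generate_dataset(gc)
#' sp <- stratified_split(ds, c(0.8, 0.1, 0.1), seed = 1)
#' length(sp$train) + length(sp$validation) + length(sp$test) == length(ds)
#' @export
stratified_split <- function(dataset, fractions = c(0.8, 0.1, 0.1),
                             seed = 1L) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(!is.finite(fractions)) ||
      any(fractions <= 0))
    gm_stop("'fractions' must be three positive numbers", "config")
  if (abs(sum(fractions) - 1) > 1e-9)
    gm_stop(sprintf("'fractions' must sum to 1 (got %.12g)",
                    sum(fractions)), "config")
  labs <- dataset_labels(dataset)
  if (anyNA(labs))
    gm_stop("cannot stratify: dataset contains unlabeled sequences",
            "stratification")
  counts <- table(factor(labs, levels = dataset$class_names))
  if (any(counts == 0))
    gm_stop(sprintf("class(es) with zero samples: %s",
                    paste(names(counts)[counts == 0], collapse = ", ")),
            "stratification")
  parts <- list(train = integer(0), validation = integer(0),
                test = integer(0))
  withr::with_seed(derive_seed(seed), {
    for (cls in dataset$class_names) {
      idx <- which(labs == cls)
      idx <- idx[sample.int(length(idx))]
      alloc <- largest_remainder(length(idx), fractions)
      cuts <- cumsum(c(0L, alloc))
      for (k in 1:3)
        parts[[k]] <- c(parts[[k]], idx[seq2(cuts[k] + 1L, cuts[k + 1L])])
    }
  })
  structure(
    list(train = subset_dataset(dataset, parts$train),
         validation = subset_dataset(dataset, parts$validation),
         test = subset_dataset(dataset, parts$test),
         indices = parts,
         fractions = fractions,
         seed = as.integer(seed)),
    class = "gait_split")
}

# seq() that yields integer(0) when from > to.
seq2 <- function(from, to) if (from > to) integer(0) else seq.int(from, to)

#' Random (non-stratified) split
#'
#' Shuffles the whole dataset with the given seed and cuts it into three
#' parts by largest-remainder rounding, ignoring class labels. Provided as
#' the baseline the stratified procedure is compared against.
#'
#' @inheritParams stratified_split
#' @return A `gait_split` list as for [stratified_split()].
#' @export
random_split <- function(dataset, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    gm_stop("'fractions' must be three positive numbers summing to 1",
            "config")
  n <- length(dataset$sequences)
  idx <- withr::with_seed(derive_seed(seed), sample.int(n))
  alloc <- largest_remainder(n, fractions)
  cuts <- cumsum(c(0L, alloc))
  parts <- list(train = idx[seq2(cuts[1] + 1L, cuts[2])],
                validation = idx[seq2(cuts[2] + 1L, cuts[3])],
                test = idx[seq2(cuts[3] + 1L, cuts[4])])
  structure(
    list(train = subset_dataset(dataset, parts$train),
         validation = subset_dataset(dataset, parts$validation),
         test = subset_dataset(dataset, parts$test),
         indices = parts, fractions = fractions, seed = as.integer(seed)),
    class = "gait_split")
}

#' @export
print.gait_split <- function(x, ...) {
  cat(sprintf("<gait_split> train=%d validation=%d test=%d (seed %d)\n",
              length(x$train), length(x$validation), length(x$test),
              x$seed))
  invisible(x)
}
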