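#' Emotion classes
#'
#' The four perceived-emotion categories used throughout the package, in
#' canonical order.
#' @return Character vector `c("angry", "happy", "sad", "neutral")`.
#' @export
emotion_classes <- function() c("angry", "happy", "sad", "neutral")

#' Gait sequence
#'
#' A single motion-capture gait recording: a `T x V x C` array of joint
#' coordinates over time, an optional emotion label and an identifier.
#'
#' @param coords Numeric array of dimension `T x V x C` (frames x joints x
#'   coordinates). All values must be finite.
#' @param label Emotion label, or `NA` for an unlabeled sequence.
#' @param sequence_id Identifier string.
#' @param topology Optional [skeleton_topology()]; if supplied, `V` and `C`
#'   are validated against it.
#' @return An object of class `gait_sequence`.
#' @export
gait_sequence <- function(coords, label = NA_character_,
                          sequence_id = "seq", topology = NULL) {
  if (!is.array(coords) || length(dim(coords)) != 3L)
    gm_stop("'coords' must be a 3-d array of shape T x V x C", "contract")
  if (dim(coords)[1] < 1L)
    gm_stop("a gait sequence needs at least one frame (T >= 1)", "contract")
  if (!all(is.finite(coords)))
    gm_stop("'coords' contains non-finite values", "contract")
  if (!is.null(topology)) {
    if (dim(coords)[2] != topology$n_joints ||
        dim(coords)[3] != topology$n_coords)
      gm_stop(sprintf(
        "coords shape (%d joints x %d coords) does not match topology (%d x %d)",
        dim(coords)[2], dim(coords)[3],
        topology$n_joints, topology$n_coords), "contract")
  }
  if (length(label) != 1L) gm_stop("'label' must be length 1", "contract")
  structure(
    list(coords = coords,
         label = if (is.na(label)) NA_character_ else as.character(label),
         sequence_id = as.character(sequence_id)),
    class = "gait_sequence")
}

#' @export
print.gait_sequence <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<gait_sequence> '%s': %d frames x %d joints x %d coords, label=%s\n",
              x$sequence_id, d[1], d[2], d[3],
              if (is.na(x$label)) "<none>" else x$label))
  invisible(x)
}

n_frames <- function(seq) dim(seq$coords)[1]

#' Labeled gait dataset
#'
#' A collection of [gait_sequence()] objects sharing one topology and one
#' uniform sequence length. Ragged collections are rejected: the classifier
#' consumes fixed-length `[T, D]` inputs.
#'
#' @param sequences List of [gait_sequence()] objects.
#' @param topology The shared [skeleton_topology()].
#' @param class_names Ordered emotion class labels.
#' @return An object of class `gait_dataset`.
#' @export
gait_dataset <- function(sequences, topology,
                         class_names = emotion_classes()) {
  if (!length(sequences)) gm_stop("empty dataset", "format")
  for (s in sequences) {
    if (!inherits(s, "gait_sequence"))
      gm_stop("all elements of 'sequences' must be gait_sequence objects",
              "contract")
    if (dim(s$coords)[2] != topology$n_joints ||
        dim(s$coords)[3] != topology$n_coords)
      gm_stop(sprintf("sequence '%s' does not match the topology",
                      s$sequence_id), "format")
  }
  lens <- vapply(sequences, n_frames, integer(1))
  if (length(unique(lens)) != 1L)
    gm_stop(sprintf(
      "ragged dataset: sequence lengths %s differ; uniform T required",
      paste(sort(unique(lens)), collapse = ", ")), "format")
  labs <- vapply(sequences, function(s) s$label, character(1))
  bad <- !is.na(labs) & !(labs %in% class_names)
  if (any(bad))
    gm_stop(sprintf("labels outside class set: %s",
                    paste(unique(labs[bad]), collapse = ", ")), "format")
  structure(
    list(topology = topology,
         sequences = sequences,
         class_names = class_names),
    class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  labs <- dataset_labels(x)
  cat(sprintf("<gait_dataset> %d sequences, T=%d, %d joints\n",
              length(x$sequences), n_frames(x$sequences[[1]]),
              x$topology$n_joints))
  print(table(factor(labs, levels = x$class_names), useNA = "ifany"))
  invisible(x)
}

#' @export
length.gait_dataset <- function(x) length(x$sequences)

dataset_labels <- function(dataset) {
  vapply(dataset$sequences, function(s) s$label, character(1))
}

dataset_ids <- function(dataset) {
  vapply(dataset$sequences, function(s) s$sequence_id, character(1))
}

subset_dataset <- function(dataset, idx) {
  gait_dataset(dataset$sequences[idx], dataset$topology,
               dataset$class_names)
}

#' Flatten a gait sequence to a frame matrix
#'
#' Reshapes the `T x V x C` coordinate array to a `T x (V*C)` matrix; row `t`
#' concatenates the joints in topology order with axes fastest-varying, i.e.
#' column `(v-1)*C + c` holds joint `v`, axis `c`. For a 16-joint, 3-coordinate
#' skeleton each row has the 48 raw values the network consumes when no
#' handcrafted features are enabled. Inverse: [unflatten_frames()].
#'
#' @param seq A [gait_sequence()].
#' @param topology Optional topology used only to name the columns.
#' @return A `T x (V*C)` numeric matrix.
#' @export
flatten_frames <- function(seq, topology = NULL) {
  d <- dim(seq$coords)
  m <- matrix(aperm(seq$coords, c(1L, 3L, 2L)), nrow = d[1],
              ncol = d[2] * d[3])
  if (!is.null(topology)) colnames(m) <- coord_headers(topology)
  m
}

#' Rebuild a gait sequence from a flattened frame matrix
#'
#' @param mat `T x (V*C)` matrix as produced by [flatten_frames()].
#' @param topology The [skeleton_topology()] giving `V` and `C`.
#' @param label,sequence_id Passed to [gait_sequence()].
#' @return A [gait_sequence()].
#' @export
unflatten_frames <- function(mat, topology, label = NA_character_,
                             sequence_id = "seq") {
  V <- topology$n_joints; C <- topology$n_coords
  if (ncol(mat) != V * C)
    gm_stop(sprintf("matrix has %d columns; topology requires V*C = %d",
                    ncol(mat), V * C), "contract")
  arr <- aperm(array(as.numeric(mat), dim = c(nrow(mat), C, V)),
               c(1L, 3L, 2L))
  gait_sequence(arr, label = label, sequence_id = sequence_id,
                topology = topology)
}
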