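# Handcrafted joint-relative geometric features.
#
# JRA: for every unordered pair {A, B} of non-mid-spine joints, the angle at
# the mid-spine S between vectors SA and SB -> choose(V-1, 2) columns/frame.
# JRD: Euclidean distance for every unordered joint pair -> choose(V, 2).
# Both are computed per frame and concatenated after the raw flattened
# coordinates to form the network input of width (V*C) + F.

#' Feature configuration
#'
#' Selects which handcrafted feature blocks are appended to the raw
#' coordinates. Joint relative triangle areas and cosine dissimilarities are
#' recognised extension points but not implemented here.
#'
#' @param use_jra Include the joint-relative-angle block
#'   (`choose(V-1, 2)` columns)?
#' @param use_jrd Include the joint-relative-distance block
#'   (`choose(V, 2)` columns)?
#' @param relative_joint Optional override of the topology's mid-spine index.
#' @param center Subtract the relative joint's position from every joint,
#'   per frame, before flattening the raw block? Off by default: the
#'   network consumes raw gait sequences. Centering never changes the JRA
#'   or JRD blocks (both are translation-invariant).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(use_jra = TRUE, use_jrd = TRUE,
                           relative_joint = NULL, center = FALSE) {
  if (!is_flag(use_jra) || !is_flag(use_jrd) || !is_flag(center))
    gm_stop("'use_jra', 'use_jrd' and 'center' must be single logicals",
            "config")
  if (!is.null(relative_joint) && !is_count(relative_joint))
    gm_stop("'relative_joint' must be a positive index", "config")
  structure(list(use_jra = use_jra, use_jrd = use_jrd,
                 relative_joint = if (is.null(relative_joint)) NULL
                                  else as.integer(relative_joint),
                 center = center),
            class = "feature_config")
}

resolve_relative_joint <- function(config, topology) {
  rj <- config$relative_joint %||% topology$relative_joint
  if (rj > topology$n_joints)
    gm_stop(sprintf("relative joint #%d outside topology (V=%d)", rj,
                    topology$n_joints), "config")
  rj
}

# Unordered index pairs in lexicographic (min, max) order, as a 2-column
# matrix. 'exclude' drops one joint before enumeration.
joint_pairs <- function(V, exclude = NULL) {
  idx <- setdiff(seq_len(V), exclude)
  if (length(idx) < 2L) return(matrix(integer(0), ncol = 2L))
  t(utils::combn(idx, 2L))
}

#' Angle at the mid-spine between two joints (single frame)
#'
#' Computes `acos((SA . SB) / (|SA| |SB|))` where `S` is the relative
#' (mid-spine) joint; the cosine is clamped to `[-1, 1]` before `acos` to
#' absorb floating-point drift. If either vector has zero length (a joint
#' coincides with the mid-spine) the angle is defined as 0 and a
#' `gaitmood_degenerate_geometry` warning is raised.
#'
#' @param frame `V x C` coordinate matrix for one frame.
#' @param relative_joint Index of the mid-spine joint `S`.
#' @param a,b Distinct joint indices, neither equal to `relative_joint`.
#' @return Angle in radians, in `[0, pi]`; symmetric in `(a, b)`.
#' @export
joint_relative_angle <- function(frame, relative_joint, a, b) {
  if (a == b || a == relative_joint || b == relative_joint)
    gm_stop("'a' and 'b' must be distinct joints different from the relative joint",
            "contract")
  s <- frame[relative_joint, ]
  va <- frame[a, ] - s
  vb <- frame[b, ] - s
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) {
    gm_warn("degenerate geometry: joint coincides with the mid-spine; angle set to 0",
            "degenerate_geometry")
    return(0)
  }
  acos(clamp(sum(va * vb) / (na * nb), -1, 1))
}

#' Euclidean distance between two joints (single frame)
#'
#' @param frame `V x C` coordinate matrix for one frame.
#' @param a,b Distinct joint indices.
#' @return Non-negative distance; symmetric in `(a, b)`.
#' @export
joint_relative_distance <- function(frame, a, b) {
  if (a == b) gm_stop("'a' and 'b' must be distinct joints", "contract")
  sqrt(sum((frame[b, ] - frame[a, ])^2))
}

#' Joint-relative-angle feature block
#'
#' One column per unordered pair of non-mid-spine joints, in lexicographic
#' order of `(min index, max index)`, computed per frame. Degenerate frames
#' (a joint on the mid-spine) yield angle 0 for the affected pairs; the
#' number of degenerate pair-frames is attached as attribute
#' `"n_degenerate"`.
#'
#' @param seq A [gait_sequence()].
#' @param topology The owning [skeleton_topology()].
#' @param relative_joint Mid-spine index (defaults to the topology's).
#' @return `T x choose(V-1, 2)` matrix with values in `[0, pi]`.
#' @export
jra_features <- function(seq, topology,
                         relative_joint = topology$relative_joint) {
  V <- topology$n_joints
  if (V < 3L)
    gm_stop("JRA requires at least 3 joints (no vector pairs exist)",
            "geometry")
  coords <- seq$coords
  Tn <- dim(coords)[1]
  rel <- coords - coords[, rep(relative_joint, V), , drop = FALSE]
  # squared norms of SA per frame/joint: T x V
  nrm2 <- apply(rel^2, c(1, 2), sum)
  if (Tn == 1L) nrm2 <- matrix(nrm2, nrow = 1L)
  pairs <- joint_pairs(V, exclude = relative_joint)
  out <- matrix(0, Tn, nrow(pairs))
  n_degenerate <- 0L
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    dot <- rowSums(rel[, a, , drop = FALSE] * rel[, b, , drop = FALSE],
                   dims = 1)
    denom2 <- nrm2[, a] * nrm2[, b]
    deg <- denom2 == 0
    n_degenerate <- n_degenerate + sum(deg)
    cosv <- ifelse(deg, 1, dot / sqrt(pmax(denom2, .Machine$double.xmin)))
    out[, k] <- acos(clamp(cosv, -1, 1))
  }
  if (n_degenerate > 0L)
    gm_warn(sprintf("%d degenerate pair-frame(s): joint on mid-spine, angle set to 0",
                    n_degenerate), "degenerate_geometry")
  colnames(out) <- sprintf("jra_%s_%s", topology$joint_names[pairs[, 1]],
                           topology$joint_names[pairs[, 2]])
  attr(out, "n_degenerate") <- n_degenerate
  out
}

#' Joint-relative-distance feature block
#'
#' One column per unordered joint pair in lexicographic order, computed per
#' frame.
#'
#' @inheritParams jra_features
#' @return `T x choose(V, 2)` non-negative matrix.
#' @export
jrd_features <- function(seq, topology) {
  V <- topology$n_joints
  if (V < 2L) gm_stop("JRD requires at least 2 joints", "geometry")
  coords <- seq$coords
  Tn <- dim(coords)[1]
  pairs <- joint_pairs(V)
  out <- matrix(0, Tn, nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]; b <- pairs[k, 2]
    d2 <- rowSums((coords[, b, , drop = FALSE] -
                   coords[, a, , drop = FALSE])^2, dims = 1)
    out[, k] <- sqrt(d2)
  }
  colnames(out) <- sprintf("jrd_%s_%s", topology$joint_names[pairs[, 1]],
                           topology$joint_names[pairs[, 2]])
  out
}

#' Width of the assembled network input
#'
#' Closed form: `V*C + use_jra * choose(V-1, 2) + use_jrd * choose(V, 2)`.
#' For the default 16-joint, 3-coordinate skeleton with both blocks on this
#' is `48 + 105 + 120 = 273`.
#'
#' @param topology A [skeleton_topology()].
#' @param config A [feature_config()].
#' @return Integer input width `D`.
#' @export
feature_dim <- function(topology, config = feature_config()) {
  V <- topology$n_joints; C <- topology$n_coords
  as.integer(V * C +
    (if (config$use_jra) choose(V - 1, 2) else 0) +
    (if (config$use_jrd) choose(V, 2) else 0))
}

#' Assemble the per-frame network input
#'
#' Concatenates, per frame: the flattened raw coordinates (width `V*C`),
#' then the JRA block (if enabled), then the JRD block (if enabled). Column
#' labels record the provenance of every column.
#'
#' @param seq A [gait_sequence()].
#' @param topology The owning [skeleton_topology()].
#' @param config A [feature_config()].
#' @return A `feature_matrix`: a `T x D` numeric matrix with attributes
#'   `blocks` (named block widths) and `n_degenerate`.
#' @examples
#' topo <- default_topology()
#' seq <- gait_sequence(array(rnorm(10 * 16 * 3), c(10, 16, 3)))
#' fm <- assemble_input(seq, topo, feature_config())
#' ncol(fm)  # 273
#' @export
assemble_input <- function(seq, topology, config = feature_config()) {
  rj <- resolve_relative_joint(config, topology)
  raw_seq <- seq
  if (isTRUE(config$center)) {
    V <- topology$n_joints
    centered <- seq$coords - seq$coords[, rep(rj, V), , drop = FALSE]
    raw_seq <- gait_sequence(centered, label = seq$label,
                             sequence_id = seq$sequence_id)
  }
  blocks <- list(raw = flatten_frames(raw_seq, topology))
  n_degenerate <- 0L
  if (config$use_jra) {
    jra <- withCallingHandlers(
      jra_features(seq, topology, relative_joint = rj),
      gaitmood_degenerate_geometry = function(w) invokeRestart("muffleWarning"))
    n_degenerate <- attr(jra, "n_degenerate") %||% 0L
    attr(jra, "n_degenerate") <- NULL
    blocks$jra <- jra
  }
  if (config$use_jrd) blocks$jrd <- jrd_features(seq, topology)
  out <- do.call(cbind, blocks)
  colnames(out) <- unlist(lapply(blocks, colnames), use.names = FALSE)
  structure(out,
            blocks = vapply(blocks, ncol, integer(1)),
            n_degenerate = n_degenerate,
            class = c("feature_matrix", class(out)))
}

#' Write a feature matrix to CSV
#'
#' @param fm A feature matrix from [assemble_input()].
#' @param path Output CSV path; column labels become the header.
#' @return Invisibly, `path`.
#' @export
write_feature_csv <- function(fm, path) {
  data.table::fwrite(data.table::as.data.table(unclass(fm)), path)
  invisible(path)
}
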