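#' Skeleton topology
#'
#' Describes the joint layout of a motion-capture skeleton: the ordered joint
#' names, the coordinate dimensionality, the index of the designated
#' *relative joint* (the mid-spine, from which joint-relative angles are
#' measured), and the capture frame rate.
#'
#' @param joint_names Character vector of unique joint names, in the column
#'   order used by gait CSV files.
#' @param n_coords Coordinate dimensionality per joint; 2 or 3.
#' @param relative_joint 1-based index of the mid-spine (reference) joint.
#' @param fps Capture frame rate in Hz.
#'
#' @return An object of class `skeleton_topology` with fields `joint_names`,
#'   `n_joints`, `n_coords`, `relative_joint`, `fps`.
#' @examples
#' topo <- default_topology()
#' topo$n_joints            # 16
#' topo$joint_names[topo$relative_joint]  # "spine"
#' @export
skeleton_topology <- function(joint_names, n_coords = 3L, relative_joint,
                              fps = 60) {
  if (!is.character(joint_names) || length(joint_names) < 2L)
    gm_stop("'joint_names' must be a character vector with at least 2 joints",
            "config")
  if (anyDuplicated(joint_names))
    gm_stop("joint names must be unique", "config")
  if (!is_count(n_coords) || !(n_coords %in% c(2L, 3L)))
    gm_stop("'n_coords' must be 2 or 3", "config")
  if (!is_count(relative_joint) || relative_joint > length(joint_names))
    gm_stop(sprintf("'relative_joint' must be an index in 1..%d",
                    length(joint_names)), "config")
  if (!is_number(fps) || fps <= 0)
    gm_stop("'fps' must be a positive number", "config")
  structure(
    list(joint_names = joint_names,
         n_joints = length(joint_names),
         n_coords = as.integer(n_coords),
         relative_joint = as.integer(relative_joint),
         fps = fps),
    class = "skeleton_topology")
}

#' Default 16-joint, 3-coordinate walking skeleton
#'
#' A full-body skeleton with 16 named joints sampled at 60 Hz, matching the
#' joint/coordinate budget of common locomotion mocap corpora (16 joints x 3
#' coordinates = 48 values per frame). The mid-spine joint (`"spine"`, index
#' 2) is the relative joint for the geometric features.
#'
#' @return A [skeleton_topology()].
#' @export
default_topology <- function() {
  skeleton_topology(
    joint_names = c("pelvis", "spine", "neck", "head",
                    "shoulder_l", "elbow_l", "hand_l",
                    "shoulder_r", "elbow_r", "hand_r",
                    "hip_l", "knee_l", "foot_l",
                    "hip_r", "knee_r", "foot_r"),
    n_coords = 3L,
    relative_joint = 2L,
    fps = 60)
}

axis_names <- function(n_coords) c("x", "y", "z")[seq_len(n_coords)]

# Column headers of a gait CSV: joint-major, axis fastest ("pelvis_x", ...).
coord_headers <- function(topology) {
  as.vector(t(outer(topology$joint_names, axis_names(topology$n_coords),
                    paste, sep = "_")))
}

#' @export
print.skeleton_topology <- function(x, ...) {
  cat(sprintf("<skeleton_topology> %d joints x %d coords @ %g Hz\n",
              x$n_joints, x$n_coords, x$fps))
  cat("  relative joint:", x$joint_names[x$relative_joint],
      sprintf("(#%d)\n", x$relative_joint))
  invisible(x)
}

topology_to_list <- function(topology) {
  list(joint_names = topology$joint_names,
       n_coords = topology$n_coords,
       relative_joint = topology$relative_joint,
       fps = topology$fps)
}

topology_from_list <- function(x) {
  skeleton_topology(joint_names = unlist(x$joint_names),
                    n_coords = x$n_coords,
                    relative_joint = x$relative_joint,
                    fps = x$fps)
}
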