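# Kinematic synthetic gait generator.
#
# The generator is kinematic, not biomechanical: a root that advances at a
# constant speed, limb joints oscillating sinusoidally at the stride
# frequency with antiphase left/right coordination, a static torso pitch,
# and additive Gaussian jitter. Classes differ in exactly the cue families
# the handcrafted features encode -- cadence, swing amplitudes and posture
# -- which makes the four emotions separable by geometry without any claim
# of biomechanical realism.

#' Emotion movement profile
#'
#' Class-conditional kinematic parameters of the generator.
#'
#' @param emotion Class label.
#' @param stride_frequency Stride cycles per second (Hz).
#' @param arm_swing_amplitude Peak hand displacement along the walking
#'   axis (length units; elbows swing at half amplitude).
#' @param step_amplitude Peak foot displacement along the walking axis
#'   (knees at half amplitude).
#' @param torso_lean Static forward pitch of the torso (radians; positive
#'   = slumped forward).
#' @param speed Root advance per frame (length units / frame).
#' @param noise_sd Standard deviation of the additive Gaussian jitter on
#'   every coordinate.
#' @return An object of class `emotion_profile`.
#' @export
emotion_profile <- function(emotion, stride_frequency, arm_swing_amplitude,
                            step_amplitude, torso_lean, speed, noise_sd) {
  if (!is_number(stride_frequency) || stride_frequency <= 0)
    gm_stop("'stride_frequency' must be > 0", "config")
  for (v in c(arm_swing_amplitude, step_amplitude, speed, noise_sd))
    if (!is_number(v) || v < 0)
      gm_stop("profile magnitudes must be non-negative numbers", "config")
  if (!is_number(torso_lean)) gm_stop("'torso_lean' must be a number",
                                      "config")
  structure(list(emotion = as.character(emotion),
                 stride_frequency = stride_frequency,
                 arm_swing_amplitude = arm_swing_amplitude,
                 step_amplitude = step_amplitude,
                 torso_lean = torso_lean, speed = speed,
                 noise_sd = noise_sd),
            class = "emotion_profile")
}

#' Default emotion profiles
#'
#' Fixed constants following the direction of the gait literature: angry
#' and happy walks have higher cadence, longer/stronger swing and faster
#' progression; sad walks are slow, small-amplitude and slumped; neutral
#' sits in between. These are generator constants of this package, not
#' measured values.
#'
#' @return Named list of [emotion_profile()]s for angry/happy/sad/neutral.
#' @export
default_profiles <- function() {
  list(
    angry = emotion_profile("angry", stride_frequency = 1.4,
                            arm_swing_amplitude = 0.35,
                            step_amplitude = 0.45, torso_lean = 0.15,
                            speed = 0.025, noise_sd = 0.02),
    happy = emotion_profile("happy", stride_frequency = 1.15,
                            arm_swing_amplitude = 0.30,
                            step_amplitude = 0.40, torso_lean = -0.05,
                            speed = 0.020, noise_sd = 0.02),
    sad = emotion_profile("sad", stride_frequency = 0.7,
                          arm_swing_amplitude = 0.10,
                          step_amplitude = 0.20, torso_lean = 0.35,
                          speed = 0.008, noise_sd = 0.02),
    neutral = emotion_profile("neutral", stride_frequency = 0.95,
                              arm_swing_amplitude = 0.20,
                              step_amplitude = 0.30, torso_lean = 0,
                              speed = 0.015, noise_sd = 0.02))
}

#' Generator configuration
#'
#' @param topology Skeleton to generate for (default: the 16-joint,
#'   3-coordinate skeleton).
#' @param n_frames Frames per sequence (default 240, i.e. 4 s at 60 Hz).
#' @param class_counts Named per-class sequence counts; the default is the
#'   1048/454/254/79 angry/happy/sad/neutral imbalance.
#' @param scale Optional factor applied to `class_counts` via
#'   [scale_class_counts()].
#' @param profiles Named list of [emotion_profile()]s covering every class
#'   in `class_counts`.
#' @param seed Master seed; sequence `k` of the dataset uses `seed + k`.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(topology = default_topology(),
                             n_frames = 240L,
                             class_counts = c(angry = 1048L, happy = 454L,
                                              sad = 254L, neutral = 79L),
                             scale = 1,
                             profiles = default_profiles(),
                             seed = 1L) {
  if (!is_count(n_frames, min = 2L))
    gm_stop("'n_frames' must be >= 2", "config")
  if (is.null(names(class_counts)) || any(class_counts < 0))
    gm_stop("'class_counts' must be named non-negative counts", "config")
  if (!is_number(scale) || scale <= 0)
    gm_stop("'scale' must be > 0", "config")
  if (scale != 1) class_counts <- scale_class_counts(class_counts, scale)
  miss <- setdiff(names(class_counts), names(profiles))
  if (length(miss))
    gm_stop(sprintf("no profile for class(es): %s",
                    paste(miss, collapse = ", ")), "config")
  structure(list(topology = topology, n_frames = as.integer(n_frames),
                 fps = topology$fps, class_counts = class_counts,
                 profiles = profiles, seed = as.integer(seed)),
            class = "generator_config")
}

#' Scale class counts preserving the total by largest remainder
#'
#' Multiplies each count by `scale`, floors, then distributes the remaining
#' units (up to `floor(scale * sum)`) to the classes with the largest
#' fractional remainders (earlier class wins a tie). E.g. counts
#' 1048/454/254/79 at scale 0.1 give 105/45/25/8 (total 183).
#'
#' @param counts Named integer vector.
#' @param scale Positive factor.
#' @return Named integer vector.
#' @export
scale_class_counts <- function(counts, scale) {
  exact <- counts * scale
  base <- floor(exact + 1e-12)
  target <- floor(sum(counts) * scale + 1e-12)
  leftover <- round(target - sum(base))
  if (leftover > 0) {
    ord <- order(-(exact - base), seq_along(counts))
    take <- ord[seq_len(leftover)]
    base[take] <- base[take] + 1
  }
  stats::setNames(as.integer(base), names(counts))
}

# Neutral standing pose for the default 16-joint skeleton (z up, walking
# along +y), pelvis at the origin. For other topologies a generic pose is
# spread on a circle (good enough to exercise the pipeline).
base_pose <- function(topology) {
  if (identical(topology$joint_names, default_topology()$joint_names)) {
    m <- rbind(
      pelvis     = c(0.00, 0, 1.00),
      spine      = c(0.00, 0, 1.25),
      neck       = c(0.00, 0, 1.50),
      head       = c(0.00, 0, 1.65),
      shoulder_l = c(-0.20, 0, 1.45),
      elbow_l    = c(-0.25, 0, 1.20),
      hand_l     = c(-0.28, 0, 0.95),
      shoulder_r = c(0.20, 0, 1.45),
      elbow_r    = c(0.25, 0, 1.20),
      hand_r     = c(0.28, 0, 0.95),
      hip_l      = c(-0.10, 0, 0.95),
      knee_l     = c(-0.10, 0, 0.50),
      foot_l     = c(-0.10, 0, 0.05),
      hip_r      = c(0.10, 0, 0.95),
      knee_r     = c(0.10, 0, 0.50),
      foot_r     = c(0.10, 0, 0.05))
    return(m[, seq_len(topology$n_coords), drop = FALSE][, , drop = FALSE])
  }
  V <- topology$n_joints
  ang <- 2 * pi * (seq_len(V) - 1) / V
  m <- cbind(0.3 * cos(ang), 0.3 * sin(ang), 1 + 0.1 * seq_len(V) / V)
  m[, seq_len(topology$n_coords), drop = FALSE]
}

# Oscillator weights per joint: how strongly each joint follows the arm /
# leg oscillators (along the walking axis) for the default skeleton.
swing_weights <- function(joint_names) {
  arm <- stats::setNames(numeric(length(joint_names)), joint_names)
  leg <- arm
  arm[c("hand_l", "elbow_l")] <- c(1, 0.5)
  arm[c("hand_r", "elbow_r")] <- c(-1, -0.5)
  leg[c("foot_l", "knee_l")] <- c(-1, -0.5)   # left leg with right arm
  leg[c("foot_r", "knee_r")] <- c(1, 0.5)
  list(arm = arm, leg = leg)
}

torso_joints <- function(joint_names) {
  intersect(c("spine", "neck", "head", "shoulder_l", "shoulder_r",
              "elbow_l", "elbow_r", "hand_l", "hand_r"), joint_names)
}

#' Generate one synthetic gait sequence
#'
#' Builds the deterministic kinematic skeleton (root advance, sinusoidal
#' antiphase limb swing at the stride frequency, double-frequency vertical
#' bob, static torso pitch about the pelvis), then adds Gaussian coordinate
#' noise — the sole stochastic element, so within-class variation is
#' entirely noise-driven. All sequences start at stride phase zero; see the
#' methods vignette for what this deliberately does not emulate (random
#' gait phase, speed drift, per-subject style). Deterministic per seed.
#'
#' @param profile An [emotion_profile()].
#' @param gc A [generator_config()].
#' @param seed Integer seed for this sequence.
#' @param sequence_id Identifier for the result.
#' @return A labeled [gait_sequence()].
#' @export
generate_sequence <- function(profile, gc, seed = 1L,
                              sequence_id = profile$emotion) {
  topo <- gc$topology
  Tn <- gc$n_frames; V <- topo$n_joints; C <- topo$n_coords
  withr::with_seed(derive_seed(seed), {
    freq <- profile$stride_frequency
    arm_amp <- profile$arm_swing_amplitude
    step_amp <- profile$step_amplitude
    speed <- profile$speed
    tt <- (seq_len(Tn) - 1) / gc$fps
    phase <- 2 * pi * freq * tt

    pose <- base_pose(topo)
    # static torso pitch about the pelvis, in the (walk axis, up) plane
    if (C == 3L && "pelvis" %in% topo$joint_names) {
      tj <- match(torso_joints(topo$joint_names), topo$joint_names)
      piv <- pose[match("pelvis", topo$joint_names), ]
      th <- profile$torso_lean
      rel_y <- pose[tj, 2] - piv[2]; rel_z <- pose[tj, 3] - piv[3]
      pose[tj, 2] <- piv[2] + cos(th) * rel_y + sin(th) * rel_z
      pose[tj, 3] <- piv[3] - sin(th) * rel_y + cos(th) * rel_z
    }

    coords <- array(rep(pose, each = Tn), dim = c(Tn, V, C))
    walk_axis <- min(2L, C)
    # root advance shared by every joint
    adv <- speed * (seq_len(Tn) - 1)
    coords[, , walk_axis] <- coords[, , walk_axis] + adv
    sw <- swing_weights(topo$joint_names)
    osc_arm <- arm_amp * sin(phase)
    osc_leg <- step_amp * sin(phase)
    for (v in seq_len(V)) {
      coords[, v, walk_axis] <- coords[, v, walk_axis] +
        sw$arm[v] * osc_arm + sw$leg[v] * osc_leg
    }
    if (C == 3L) {
      # double-frequency vertical bob of the upper body; small foot lift
      bob <- 0.05 * step_amp * sin(2 * phase)
      tj <- match(torso_joints(topo$joint_names), topo$joint_names)
      tj <- tj[!is.na(tj)]
      for (v in tj) coords[, v, 3] <- coords[, v, 3] + bob
      for (side in c("l", "r")) {
        fj <- match(paste0("foot_", side), topo$joint_names)
        if (!is.na(fj)) {
          ph <- phase + if (side == "l") pi else 0
          coords[, fj, 3] <- coords[, fj, 3] +
            0.1 * step_amp * pmax(sin(ph), 0)
        }
      }
    }
    if (profile$noise_sd > 0)
      coords <- coords + array(stats::rnorm(Tn * V * C, 0,
                                            profile$noise_sd),
                               dim = c(Tn, V, C))
    gait_sequence(coords, label = profile$emotion,
                  sequence_id = sequence_id, topology = topo)
  })
}

#' Generate a class-conditioned synthetic gait dataset
#'
#' Produces `class_counts[k]` sequences per class; the j-th sequence of the
#' dataset (counting across classes in `class_counts` order) uses seed
#' `gc$seed + j`, so datasets are reproducible and extensible.
#'
#' @param gc A [generator_config()].
#' @return A labeled [gait_dataset()].
#' @examples
#' ds <- generate_dataset(generator_config(
#'   class_counts = c(angry = 10, happy = 10, sad = 10, neutral = 10),
#'   n_frames = 30, seed = 42))
#' length(ds)  # 40
#' @export
generate_dataset <- function(gc) {
  stopifnot(inherits(gc, "generator_config"))
  if (sum(gc$class_counts) == 0)
    gm_stop("all class counts are zero: empty dataset", "config")
  seqs <- list()
  counter <- 0L
  for (cls in names(gc$class_counts)) {
    prof <- gc$profiles[[cls]]
    for (k in seq_len(gc$class_counts[[cls]])) {
      counter <- counter + 1L
      seqs[[counter]] <- generate_sequence(
        prof, gc, seed = derive_seed(gc$seed, counter),
        sequence_id = sprintf("%s_%04d", cls, k))
    }
  }
  cls_names <- if (setequal(names(gc$class_counts), emotion_classes()))
    emotion_classes() else names(gc$class_counts)
  gait_dataset(seqs, gc$topology, class_names = cls_names)
}
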