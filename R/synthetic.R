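# Planar gait simulator: forward kinematics from the angle templates, a
# double-bump vertical GRF, and a keypoint corruption model (pixel noise +
# occlusion dropout of the limb opposite the camera).
#
# Coordinate frame: x = direction of progression, y = up, origin at the
# walkway start; pixel coordinates are meters * pixel_scale.

.rot <- function(vx, vy, theta) {
  list(x = vx * cos(theta) - vy * sin(theta),
       y = vx * sin(theta) + vy * cos(theta))
}

# Landmark trajectories for one limb given its three signed angle waveforms
# (degrees) and the pelvis trajectory. Returns pixel coordinates.
.limb_points <- function(hip_deg, knee_deg, ankle_deg, hip_x, hip_y,
                         seg, px) {
  d2r <- pi / 180
  phi <- hip_deg * d2r
  kap <- knee_deg * d2r
  alp <- ankle_deg * d2r
  # thigh axis: downward vertical rotated CCW by hip flexion
  vx <- sin(phi)
  vy <- -cos(phi)
  # shank axis: thigh rotated CW by knee flexion
  w <- .rot(vx, vy, -kap)
  # foot axis: shank rotated CCW by (ankle + 90 deg)
  f <- .rot(w$x, w$y, alp + pi / 2)
  knee_x <- hip_x + seg[["thigh"]] * px * vx
  knee_y <- hip_y + seg[["thigh"]] * px * vy
  ank_x <- knee_x + seg[["shank"]] * px * w$x
  ank_y <- knee_y + seg[["shank"]] * px * w$y
  # heel sits behind/below the ankle along the foot axis
  heel_x <- ank_x - 0.25 * seg[["foot"]] * px * f$x + 0.05 * px * f$y
  heel_y <- ank_y - 0.25 * seg[["foot"]] * px * f$y - 0.05 * px * f$x
  toe_x <- heel_x + seg[["foot"]] * px * f$x
  toe_y <- heel_y + seg[["foot"]] * px * f$y
  list(knee_x = knee_x, knee_y = knee_y, ankle_x = ank_x, ankle_y = ank_y,
       heel_x = heel_x, heel_y = heel_y, toe_x = toe_x, toe_y = toe_y)
}

#' Simulate one planar gait trial with known ground truth
#'
#' Builds reference joint-center trajectories by forward kinematics from the
#' profile's angle templates, a pose-keypoint stream (the reference
#' trajectories corrupted by pixel noise and occlusion dropout according to
#' the profile), per-limb vertical ground reaction forces, the true signed
#' joint-angle waveforms, and the true initial-contact frames.
#'
#' With `noise_sd = 0` and `dropout_prob_crossing = 0` the pose coordinates
#' equal the reference coordinates exactly, and recomputing angles with
#' [joint_angles()] reproduces `true_angles` to numerical precision.
#'
#' @param profile A [gait_profile()].
#' @return An object of class `gait_trial`: list with elements `profile`,
#'   `reference` and `pose` (landmark sequences), `grf` (list of two
#'   `force_series`), `true_angles` (per side, per joint, degrees per frame)
#'   and `true_events` (0-based initial-contact video frames per side).
#' @examples
#' trial <- simulate_trial(gait_profile(n_cycles = 2))
#' trial$true_events$right
#' @export
simulate_trial <- function(profile) {
  stopifnot(inherits(profile, "gait_profile"))
  cf <- profile$cycle_frames
  nfr <- profile$n_cycles * cf + 1L
  rate <- profile$sample_rate_video
  t <- (0:(nfr - 1L)) / rate
  cyc <- profile$cycle_duration
  funs <- .angle_template_funs(profile)

  phase_r <- (t / cyc) %% 1
  phase_l <- (t / cyc - 0.5) %% 1
  truth <- list(
    right = list(hip = funs$hip(phase_r), knee = funs$knee(phase_r),
                 ankle = funs$ankle(phase_r)),
    left = list(hip = funs$hip(phase_l), knee = funs$knee(phase_l),
                ankle = funs$ankle(phase_l))
  )

  px <- profile$pixel_scale
  seg <- profile$segment_lengths
  hip_h <- (seg[["thigh"]] + seg[["shank"]] + 0.05) * px
  midhip_x <- profile$speed * t * px
  midhip_y <- rep(hip_h, nfr)
  neck_x <- midhip_x
  neck_y <- midhip_y + seg[["trunk"]] * px

  r <- .limb_points(truth$right$hip, truth$right$knee, truth$right$ankle,
                    midhip_x, midhip_y, seg, px)
  l <- .limb_points(truth$left$hip, truth$left$knee, truth$left$ankle,
                    midhip_x, midhip_y, seg, px)

  x <- cbind(neck_x, midhip_x,
             midhip_x, r$knee_x, r$ankle_x, r$toe_x, r$heel_x,
             midhip_x, l$knee_x, l$ankle_x, l$toe_x, l$heel_x)
  y <- cbind(neck_y, midhip_y,
             midhip_y, r$knee_y, r$ankle_y, r$toe_y, r$heel_y,
             midhip_y, l$knee_y, l$ankle_y, l$toe_y, l$heel_y)
  colnames(x) <- colnames(y) <- GAIT_KEYPOINTS

  reference <- new_landmark_sequence(t, x, y, source = "reference",
                                     rate = rate)
  pose <- new_landmark_sequence(t, x, y, source = "ai", rate = rate)
  pose <- corrupt_pose(pose, noise_sd = profile$noise_sd,
                       dropout_prob_crossing = profile$dropout_prob_crossing,
                       seed = profile$seed)

  grf <- synth_grf(profile)
  true_events <- list(
    right = as.integer((0:profile$n_cycles) * cf),
    left = as.integer((0:(profile$n_cycles - 1L)) * cf + cf / 2L)
  )

  trial <- list(profile = profile, reference = reference, pose = pose,
                grf = grf, true_angles = truth, true_events = true_events)
  class(trial) <- "gait_trial"
  trial
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> %d frames, %d cycles, noise %g px, dropout %g\n",
              n_frames(x$reference), x$profile$n_cycles,
              x$profile$noise_sd, x$profile$dropout_prob_crossing))
  invisible(x)
}

#' Synthesize per-limb vertical ground reaction forces
#'
#' Each stance phase carries the classic double-bump vertical force: a
#' two-peaked envelope (peaks near body weight, mid-stance valley around
#' 0.73 body weight) with a square-root onset/offset so the trace rises
#' through the 20 N contact threshold within a sample or two of the true
#' initial contact, and is exactly 0 N throughout swing. The left trace is
#' the right trace offset by half a cycle (including the tail of the
#' left stance that precedes the first full left cycle).
#'
#' @param profile A [gait_profile()].
#' @return List with `force_series` elements `right` and `left`.
#' @export
synth_grf <- function(profile) {
  stopifnot(inherits(profile, "gait_profile"))
  fr <- profile$sample_rate_force
  cyc <- profile$cycle_duration
  sf <- profile$stance_fraction
  dur <- (profile$n_cycles + sf) * cyc
  m <- as.integer(round(dur * fr)) + 1L
  tf <- (0:(m - 1L)) / fr
  bw_n <- profile$body_mass * 9.80665

  one_trace <- function(ic_times) {
    fz <- numeric(m)
    s_dur <- sf * cyc
    for (t0 in ic_times) {
      ph <- (tf - t0) / s_dur
      in_st <- ph > 0 & ph < 1
      # steep loading/unloading edges (sin^1/4) keep the 20 N crossing
      # within one force sample of the true contact boundaries
      fz[in_st] <- fz[in_st] +
        bw_n * sin(pi * ph[in_st])^0.25 *
        (0.95 - 0.22 * cos(4 * pi * ph[in_st]))
    }
    fz
  }
  right_ics <- (0:profile$n_cycles) * cyc
  left_ics <- ((0:profile$n_cycles) - 0.5) * cyc  # includes pre-trial stance tail
  list(
    right = new_force_series(tf, one_trace(right_ics), side = "right",
                             rate = fr),
    left = new_force_series(tf, one_trace(left_ics), side = "left",
                            rate = fr)
  )
}

#' Corrupt a pose sequence with pixel noise and occlusion dropout
#'
#' Adds i.i.d. Gaussian noise (standard deviation `noise_sd` pixels) to every
#' visible keypoint coordinate, and, during frames where the two limbs cross
#' (right and left knee or ankle keypoints closer than
#' `crossing_threshold_px`), drops all left-limb keypoints with probability
#' `dropout_prob_crossing` by setting their confidence to 0. The right limb
#' (camera side) is never dropped; the left limb is the one intermittently
#' hidden from a single right-side camera.
#'
#' With `noise_sd = 0` and `dropout_prob_crossing = 0` the input is returned
#' unchanged.
#'
#' @param pose A pose `landmark_sequence`.
#' @param noise_sd Gaussian noise standard deviation in pixels (>= 0).
#' @param dropout_prob_crossing Per-frame dropout probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @param crossing_threshold_px Knee/ankle proximity (pixels) that defines a
#'   limb-crossing frame.
#' @return The corrupted `landmark_sequence`.
#' @export
corrupt_pose <- function(pose, noise_sd = 0, dropout_prob_crossing = 0,
                         seed = NULL, crossing_threshold_px = 15) {
  stopifnot(inherits(pose, "landmark_sequence"))
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  if (dropout_prob_crossing < 0 || dropout_prob_crossing > 1) {
    stop("dropout_prob_crossing must lie in [0, 1]")
  }
  if (noise_sd == 0 && dropout_prob_crossing == 0) return(pose)
  if (!is.null(seed)) set.seed(seed)

  nfr <- n_frames(pose)
  nk <- ncol(pose$x)

  # crossing windows from the clean input coordinates
  dknee <- sqrt((pose$x[, "RKnee"] - pose$x[, "LKnee"])^2 +
                  (pose$y[, "RKnee"] - pose$y[, "LKnee"])^2)
  dankle <- sqrt((pose$x[, "RAnkle"] - pose$x[, "LAnkle"])^2 +
                   (pose$y[, "RAnkle"] - pose$y[, "LAnkle"])^2)
  crossing <- (dknee < crossing_threshold_px) |
    (dankle < crossing_threshold_px)
  crossing[is.na(crossing)] <- FALSE

  if (noise_sd > 0) {
    vis <- pose$conf > 0
    nx <- matrix(stats::rnorm(nfr * nk, sd = noise_sd), nfr, nk)
    ny <- matrix(stats::rnorm(nfr * nk, sd = noise_sd), nfr, nk)
    pose$x[vis] <- pose$x[vis] + nx[vis]
    pose$y[vis] <- pose$y[vis] + ny[vis]
  }
  if (dropout_prob_crossing > 0 && any(crossing)) {
    drop_frame <- crossing & (stats::runif(nfr) < dropout_prob_crossing)
    if (any(drop_frame)) {
      lcols <- .side_keypoints("left")
      pose$conf[drop_frame, lcols] <- 0
      pose$x[drop_frame, lcols] <- NA_real_
      pose$y[drop_frame, lcols] <- NA_real_
    }
  }
  attr(pose, "crossing_frames") <- which(crossing) - 1L
  pose
}
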