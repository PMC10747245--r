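# Sagittal joint angles from 2D landmark trajectories.
#
# Segment axes (proximal -> distal): trunk = Neck->MidHip, thigh =
# Hip->Knee, shank = Knee->Ankle, foot = Heel->BigToe. Hip flexion is the
# signed trunk/thigh angle, knee flexion the signed thigh/shank angle, and
# ankle dorsiflexion the signed shank/foot angle minus the 90 degree neutral
# offset (foot roughly perpendicular to the shank in neutral standing).
# Flexion and dorsiflexion are positive regardless of walking direction or
# image orientation: the in-plane orientation sign is resolved from the
# anatomy itself (trunk-down vs. foot-forward cross product), which makes
# the angles invariant to rotation, translation, scaling and mirroring of
# the coordinate frame.

#' Unit segment axis between two landmarks
#'
#' @param p_from,p_to Numeric length-2 points (proximal, distal).
#' @return Unit vector from `p_from` to `p_to`, or `c(NA, NA)` when the
#'   points coincide (degenerate frame).
#' @examples
#' segment_axis(c(0, 0), c(3, 4))  # 0.6 0.8
#' @export
segment_axis <- function(p_from, p_to) {
  d <- c(p_to[1] - p_from[1], p_to[2] - p_from[2])
  nrm <- sqrt(sum(d^2))
  if (!is.finite(nrm) || nrm == 0) return(c(NA_real_, NA_real_))
  d / nrm
}

#' Angle between two unit vectors, degrees
#'
#' The unsigned form lies in `[0, 180]`; the signed form in `(-180, 180]`
#' with the sign of the planar cross product `u_x v_y - u_y v_x`
#' (counter-clockwise positive).
#'
#' @param u,v Numeric length-2 unit vectors.
#' @param signed Return the signed angle?
#' @return Angle in degrees.
#' @examples
#' angle_between(c(1, 0), c(0, 1))                 # 90
#' angle_between(c(1, 0), c(0, -1), signed = TRUE) # -90
#' @export
angle_between <- function(u, v, signed = FALSE) {
  cr <- u[1] * v[2] - u[2] * v[1]
  dt <- u[1] * v[1] + u[2] * v[2]
  ang <- atan2(cr, dt) * 180 / pi
  if (!signed) ang <- abs(ang)
  ang
}

# Vectorized signed angle over frame series.
.signed_angle <- function(ux, uy, vx, vy) {
  atan2(ux * vy - uy * vx, ux * vx + uy * vy) * 180 / pi
}

# Vectorized unit axes with validity flag.
.axes <- function(x1, y1, x2, y2) {
  dx <- x2 - x1
  dy <- y2 - y1
  nrm <- sqrt(dx^2 + dy^2)
  bad <- !is.finite(nrm) | nrm == 0
  nrm[bad] <- NA_real_
  list(x = dx / nrm, y = dy / nrm, bad = bad)
}

#' Bilateral sagittal hip, knee and ankle angles from landmarks
#'
#' Computes the six signed joint-angle waveforms (3 joints x 2 sides,
#' degrees; flexion/dorsiflexion positive) from a pose or joint-center
#' landmark sequence. Frames where a needed landmark is missing (confidence
#' at or below `confidence_gate`, non-finite coordinates) or where a segment
#' degenerates to a point are flagged and carry `NA` angles.
#'
#' @param seq A `landmark_sequence` (pose keypoints or reference joint
#'   centers).
#' @param confidence_gate Landmarks with confidence `<=` this value are
#'   treated as missing (default 0: only dropped points are excluded).
#' @return An object of class `angle_set`: list with `time`, `rate`,
#'   `source`, `angles$<side>$<joint>` numeric vectors, matching logical
#'   `flagged` structure, and the resolved progression sign `dir`.
#' @examples
#' trial <- simulate_trial(gait_profile(n_cycles = 1))
#' ang <- joint_angles(trial$reference)
#' range(ang$angles$right$knee)
#' @export
joint_angles <- function(seq, confidence_gate = 0) {
  stopifnot(inherits(seq, "landmark_sequence"))
  ok <- seq$conf > confidence_gate & is.finite(seq$x) & is.finite(seq$y)
  gx <- seq$x
  gy <- seq$y
  gx[!ok] <- NA_real_
  gy[!ok] <- NA_real_

  trunk <- .axes(gx[, "Neck"], gy[, "Neck"], gx[, "MidHip"], gy[, "MidHip"])

  # In-plane orientation: cross(trunk-down, foot-forward) > 0 when the
  # subject progresses toward +x in a y-up frame; mirrored or rotated data
  # resolve consistently because both axes transform together.
  foot_cross <- function(side) {
    kp <- .side_keypoints(side)
    f <- .axes(gx[, kp[5]], gy[, kp[5]], gx[, kp[4]], gy[, kp[4]])
    trunk$x * f$y - trunk$y * f$x
  }
  cr <- c(foot_cross("right"), foot_cross("left"))
  dir_mean <- mean(cr, na.rm = TRUE)
  dir <- if (is.finite(dir_mean) && dir_mean < 0) -1 else 1

  one_side <- function(side) {
    kp <- .side_keypoints(side)  # Hip, Knee, Ankle, BigToe, Heel
    thigh <- .axes(gx[, kp[1]], gy[, kp[1]], gx[, kp[2]], gy[, kp[2]])
    shank <- .axes(gx[, kp[2]], gy[, kp[2]], gx[, kp[3]], gy[, kp[3]])
    foot <- .axes(gx[, kp[5]], gy[, kp[5]], gx[, kp[4]], gy[, kp[4]])
    hip <- dir * .signed_angle(trunk$x, trunk$y, thigh$x, thigh$y)
    knee <- -dir * .signed_angle(thigh$x, thigh$y, shank$x, shank$y)
    ankle <- dir * .signed_angle(shank$x, shank$y, foot$x, foot$y) - 90
    list(
      angles = list(hip = hip, knee = knee, ankle = ankle),
      flagged = list(hip = trunk$bad | thigh$bad | is.na(hip),
                     knee = thigh$bad | shank$bad | is.na(knee),
                     ankle = shank$bad | foot$bad | is.na(ankle))
    )
  }
  r <- one_side("right")
  l <- one_side("left")
  out <- list(
    time = seq$time,
    rate = seq$rate,
    source = seq$source,
    dir = dir,
    angles = list(right = r$angles, left = l$angles),
    flagged = list(right = r$flagged, left = l$flagged),
    unusable_sides = seq$unusable_sides
  )
  class(out) <- "angle_set"
  out
}

#' @export
print.angle_set <- function(x, ...) {
  nf <- length(x$time)
  nflag <- sum(unlist(x$flagged))
  cat(sprintf("<angle_set source=%s> %d frames, %d flagged joint-frames\n",
              x$source, nf, nflag))
  invisible(x)
}

#' Tidy data frame of an angle set
#'
#' @param angle_set An [joint_angles()] result.
#' @return data.frame with columns side, joint, frame (0-based), time_s,
#'   angle_deg, flagged.
#' @export
as_angle_df <- function(angle_set) {
  stopifnot(inherits(angle_set, "angle_set"))
  nf <- length(angle_set$time)
  rows <- list()
  for (side in c("right", "left")) {
    for (joint in c("hip", "knee", "ankle")) {
      rows[[paste(side, joint)]] <- data.frame(
        side = side, joint = joint,
        frame = 0:(nf - 1L), time_s = angle_set$time,
        angle_deg = angle_set$angles[[side]][[joint]],
        flagged = angle_set$flagged[[side]][[joint]]
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
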