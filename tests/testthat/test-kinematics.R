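# Segment axes, signed angles, and the joint-angle definitions.

test_that("segment_axis normalizes and flags degenerate pairs", {
  expect_equal(segment_axis(c(0, 0), c(0, -2)), c(0, -1))
  expect_equal(segment_axis(c(0, 0), c(3, 4)), c(0.6, 0.8))
  expect_true(all(is.na(segment_axis(c(1, 1), c(1, 1)))))
})

test_that("angle_between matches hand values in both forms", {
  expect_equal(angle_between(c(1, 0), c(1, 0)), 0)
  expect_equal(angle_between(c(0, -1), c(0.5, -0.8660254)), 30,
               tolerance = 1e-6)
  expect_equal(angle_between(c(1, 0), c(-1, 0)), 180)
  expect_equal(angle_between(c(1, 0), c(0, 1), signed = TRUE), 90)
  expect_equal(angle_between(c(1, 0), c(0, -1), signed = TRUE), -90)
})

# Hand-built single-frame sequence: duplicate one frame so timestamps
# stay strictly increasing and direction detection has data.
frame_seq <- function(pts) {
  x <- rbind(pts[, 1], pts[, 1])
  y <- rbind(pts[, 2], pts[, 2])
  colnames(x) <- colnames(y) <- GAIT_KEYPOINTS
  new_landmark_sequence(c(0, 1 / 120), x, y, source = "reference")
}

neutral_pts <- function() {
  # upright neutral stance: straight legs, feet flat pointing +x
  pts <- rbind(
    Neck = c(0, 1.5), MidHip = c(0, 1.0),
    RHip = c(0, 1.0), RKnee = c(0, 0.55), RAnkle = c(0, 0.1),
    RBigToe = c(0.19, 0.02), RHeel = c(-0.06, 0.02),
    LHip = c(0, 1.0), LKnee = c(0, 0.55), LAnkle = c(0, 0.1),
    LBigToe = c(0.19, 0.02), LHeel = c(-0.06, 0.02)
  )
  pts[GAIT_KEYPOINTS, ]
}

test_that("neutral standing gives zero hip, knee and ankle angles", {
  ang <- joint_angles(frame_seq(neutral_pts()))
  for (side in c("right", "left")) {
    expect_equal(ang$angles[[side]]$hip[1], 0, tolerance = 1e-9)
    expect_equal(ang$angles[[side]]$knee[1], 0, tolerance = 1e-9)
    expect_equal(ang$angles[[side]]$ankle[1], 0, tolerance = 1e-9)
  }
})

test_that("a horizontal foot under a vertical shank is ankle-neutral", {
  pts <- neutral_pts()
  pts["RKnee", ] <- c(0, 0)
  pts["RAnkle", ] <- c(0, -1)
  pts["RHeel", ] <- c(-0.05, -1.05)
  pts["RBigToe", ] <- c(0.2, -1.05)
  ang <- joint_angles(frame_seq(pts))
  expect_equal(ang$angles$right$ankle[1], 0, tolerance = 1e-9)
})

test_that("known flexions are recovered with the documented signs", {
  pts <- neutral_pts()
  # right thigh flexed 30 deg forward; shank continues straight
  d2r <- pi / 180
  hipp <- pts["RHip", ]
  kx <- hipp[1] + 0.45 * sin(30 * d2r)
  ky <- hipp[2] - 0.45 * cos(30 * d2r)
  pts["RKnee", ] <- c(kx, ky)
  # knee flexed 20 deg: shank rotated backward relative to the thigh
  sh <- c(sin((30 - 20) * d2r), -cos((30 - 20) * d2r))
  pts["RAnkle", ] <- pts["RKnee", ] + 0.45 * sh
  # keep the foot perpendicular to the shank (neutral ankle)
  fx <- c(-sh[2], sh[1])
  pts["RHeel", ] <- pts["RAnkle", ] - 0.06 * fx
  pts["RBigToe", ] <- pts["RAnkle", ] + 0.19 * fx
  ang <- joint_angles(frame_seq(pts))
  expect_equal(ang$angles$right$hip[1], 30, tolerance = 1e-9)
  expect_equal(ang$angles$right$knee[1], 20, tolerance = 1e-9)
  expect_equal(ang$angles$right$ankle[1], 0, tolerance = 1e-9)
})

test_that("angles are invariant to rotation, translation and scaling", {
  tr <- simulate_trial(quick_profile())
  base <- joint_angles(tr$reference)
  for (theta in c(0.3, 1.2, pi / 2)) {
    m <- tr$reference
    xr <- cos(theta) * m$x - sin(theta) * m$y + 500
    yr <- sin(theta) * m$x + cos(theta) * m$y - 120
    rot <- new_landmark_sequence(m$time, 2.5 * xr, 2.5 * yr,
                                 source = "reference", rate = m$rate)
    got <- joint_angles(rot)
    for (side in c("right", "left")) {
      for (joint in c("hip", "knee", "ankle")) {
        expect_lt(max(abs(got$angles[[side]][[joint]] -
                            base$angles[[side]][[joint]])), 1e-9)
      }
    }
  }
})

test_that("mirroring x and swapping sides reproduces contralateral angles", {
  tr <- simulate_trial(quick_profile())
  base <- joint_angles(tr$reference)
  m <- tr$reference
  swap <- GAIT_KEYPOINTS
  swap <- ifelse(startsWith(swap, "R"), sub("^R", "L", swap),
                 ifelse(startsWith(swap, "L"), sub("^L", "R", swap), swap))
  xm <- -m$x[, swap]
  ym <- m$y[, swap]
  colnames(xm) <- colnames(ym) <- GAIT_KEYPOINTS
  mir <- new_landmark_sequence(m$time, xm, ym, source = "reference",
                               rate = m$rate)
  got <- joint_angles(mir)
  other <- c(right = "left", left = "right")
  for (side in c("right", "left")) {
    for (joint in c("hip", "knee", "ankle")) {
      expect_lt(max(abs(got$angles[[side]][[joint]] -
                          base$angles[[other[[side]]]][[joint]])), 1e-9)
    }
  }
})

test_that("missing landmarks flag the affected joints only", {
  tr <- simulate_trial(quick_profile())
  pose <- tr$pose
  pose$conf[30, "LKnee"] <- 0
  pose$x[30, "LKnee"] <- NA
  pose$y[30, "LKnee"] <- NA
  ang <- joint_angles(pose)
  # the knee landmark feeds the thigh and shank axes: hip, knee and ankle
  # of that side all lose the frame
  expect_true(ang$flagged$left$hip[30])
  expect_true(ang$flagged$left$knee[30])
  expect_true(ang$flagged$left$ankle[30])
  expect_false(any(ang$flagged$right$knee))
  expect_true(is.na(ang$angles$left$knee[30]))
  # the heel only feeds the foot axis: ankle alone is flagged
  pose2 <- tr$pose
  pose2$conf[40, "LHeel"] <- 0
  pose2$x[40, "LHeel"] <- NA
  pose2$y[40, "LHeel"] <- NA
  ang2 <- joint_angles(pose2)
  expect_false(ang2$flagged$left$hip[40])
  expect_false(ang2$flagged$left$knee[40])
  expect_true(ang2$flagged$left$ankle[40])
})

test_that("the tidy export carries all six waveforms", {
  tr <- simulate_trial(quick_profile())
  df <- as_angle_df(joint_angles(tr$reference))
  expect_equal(nrow(df), 6 * length(tr$reference$time))
  expect_setequal(unique(df$joint), c("hip", "knee", "ankle"))
  expect_setequal(unique(df$side), c("right", "left"))
  expect_equal(min(df$frame), 0)
})
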