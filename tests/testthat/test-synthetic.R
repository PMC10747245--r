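# Synthetic gait generator: templates, forward kinematics, GRF, corruption.

test_that("angle templates hit the profile's peak fields and are periodic", {
  p <- gait_profile(knee_swing_peak_flex = 60)
  tg <- seq(0, 1, length.out = 5001)
  tpl <- angle_templates(p, tg)

  expect_equal(max(tpl$knee), 60, tolerance = 0.1 / 60)
  # loading-response local knee peak (within early stance)
  expect_equal(max(tpl$knee[tg <= 0.3]), p$knee_stance_peak_flex,
               tolerance = 0.1 / 15)
  expect_equal(max(tpl$hip), p$hip_peak_flex, tolerance = 1e-6)
  expect_equal(min(tpl$hip), -p$hip_peak_ext, tolerance = 1e-6)
  expect_equal(max(tpl$ankle), p$ankle_peak_dorsi, tolerance = 1e-6)
  expect_equal(min(tpl$ankle), -p$ankle_peak_plantar, tolerance = 1e-6)

  # cyclic boundary: t = 0 and t = 1 coincide
  ends <- angle_templates(p, c(0, 1))
  expect_equal(ends[1, -1], ends[2, -1], tolerance = 1e-12,
               ignore_attr = TRUE)

  # all-zero amplitudes give identically-zero waveforms
  p0 <- gait_profile(hip_peak_flex = 0, hip_peak_ext = 0,
                     knee_stance_peak_flex = 0, knee_swing_peak_flex = 0,
                     ankle_peak_dorsi = 0, ankle_peak_plantar = 0)
  tpl0 <- angle_templates(p0, tg)
  expect_true(all(abs(as.matrix(tpl0[, c("hip", "knee", "ankle")])) < 1e-12))

  expect_error(gait_profile(hip_peak_flex = NaN), "finite")
  expect_error(angle_templates(p, c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("noiseless forward kinematics round-trips through joint_angles", {
  p <- quick_profile()
  tr <- simulate_trial(p)
  expect_identical(tr$pose$x, tr$reference$x)  # no corruption by default
  ang <- joint_angles(tr$pose)
  for (side in c("right", "left")) {
    for (joint in c("hip", "knee", "ankle")) {
      expect_lt(max(abs(ang$angles[[side]][[joint]] -
                          tr$true_angles[[side]][[joint]])), 1e-9)
    }
  }
})

test_that("zero-amplitude profile yields collinear hip-knee-ankle", {
  p0 <- quick_profile(hip_peak_flex = 0, hip_peak_ext = 0,
                      knee_stance_peak_flex = 0, knee_swing_peak_flex = 0,
                      ankle_peak_dorsi = 0, ankle_peak_plantar = 0)
  tr <- simulate_trial(p0)
  x <- tr$reference$x
  y <- tr$reference$y
  # straight leg: cross product of hip->knee and knee->ankle is 0
  cr <- (x[, "RKnee"] - x[, "RHip"]) * (y[, "RAnkle"] - y[, "RKnee"]) -
    (y[, "RKnee"] - y[, "RHip"]) * (x[, "RAnkle"] - x[, "RKnee"])
  expect_lt(max(abs(cr)), 1e-6)
})

test_that("left waveforms equal right waveforms shifted by half a cycle", {
  p <- quick_profile()
  tr <- simulate_trial(p)
  half <- p$cycle_frames / 2
  n <- length(tr$true_angles$right$hip)
  idx <- 1:(n - half)
  for (joint in c("hip", "knee", "ankle")) {
    expect_lt(max(abs(tr$true_angles$left[[joint]][idx + half] -
                        tr$true_angles$right[[joint]][idx])), 1e-9)
  }
})

test_that("identical seeds reproduce a corrupted trial exactly", {
  p <- quick_profile(noise_sd = 2, dropout_prob_crossing = 0.5, seed = 99)
  t1 <- simulate_trial(p)
  t2 <- simulate_trial(p)
  expect_identical(t1$pose$x, t2$pose$x)
  expect_identical(t1$pose$conf, t2$pose$conf)
  expect_identical(t1$grf$right$fz, t2$grf$right$fz)
})

test_that("synthetic GRF is zero in swing, double-bump in stance, linear in mass", {
  p <- quick_profile()
  g <- synth_grf(p)
  fz <- g$right$fz
  # swing of the first cycle: strictly after stance end, before next IC
  s_end <- p$stance_fraction * p$cycle_duration
  swing <- g$right$time > s_end & g$right$time < p$cycle_duration
  expect_true(all(fz[swing] == 0))
  # peaks near body weight
  bw <- p$body_mass * 9.80665
  expect_gt(max(fz), 0.85 * bw)
  expect_lt(max(fz), 1.25 * bw)
  # two local maxima separated by a valley within one stance
  st <- fz[g$right$time > 0 & g$right$time < s_end]
  peak1 <- max(st[seq_len(floor(length(st) / 2))])
  peak2 <- max(st[(floor(length(st) / 2) + 1):length(st)])
  valley <- min(st[st > 0.4 * bw])
  expect_lt(valley, 0.85 * peak1)
  expect_lt(valley, 0.85 * peak2)
  # doubling body mass doubles the trace
  p2 <- quick_profile(body_mass = 2 * p$body_mass)
  expect_equal(synth_grf(p2)$right$fz, 2 * fz, tolerance = 1e-12)
})

test_that("GRF rises through 20 N within two force samples of the true IC", {
  p <- quick_profile()
  g <- synth_grf(p)
  ic_samples <- p$cycle_frames * 10 * (0:p$n_cycles)  # 0-based
  for (s in ic_samples) {
    above <- which(g$right$fz > 20) - 1L
    first_after <- min(above[above >= s])
    expect_lte(first_after - s, 2L)
  }
})

test_that("corrupt_pose is identity at zero noise and dropout", {
  tr <- simulate_trial(quick_profile())
  out <- corrupt_pose(tr$pose, noise_sd = 0, dropout_prob_crossing = 0)
  expect_identical(out, tr$pose)
  expect_error(corrupt_pose(tr$pose, noise_sd = -1), ">= 0")
})

test_that("corrupt_pose noise has the stated RMS magnitude", {
  # long trial for a tight Monte-Carlo estimate (>= 1e4 point-frames)
  p <- gait_profile(n_cycles = 8)
  tr <- simulate_trial(p)
  noisy <- corrupt_pose(tr$pose, noise_sd = 2, seed = 42)
  dev <- c(noisy$x - tr$reference$x, noisy$y - tr$reference$y)
  expect_gt(length(dev), 2e4)
  expect_equal(sqrt(mean(dev^2)), 2, tolerance = 0.1)
})

test_that("full dropout blanks every left keypoint in crossing windows", {
  p <- quick_profile()
  tr <- simulate_trial(p)
  out <- corrupt_pose(tr$pose, dropout_prob_crossing = 1, seed = 1)
  crossing <- attr(out, "crossing_frames") + 1L
  expect_gt(length(crossing), 0)
  left <- c("LHip", "LKnee", "LAnkle", "LBigToe", "LHeel")
  expect_true(all(out$conf[crossing, left] == 0))
  right <- c("RHip", "RKnee", "RAnkle", "RBigToe", "RHeel")
  expect_true(all(out$conf[, right] == 1))
})

test_that("profile validation rejects degenerate geometry", {
  expect_error(gait_profile(segment_lengths = c(trunk = 0.5, thigh = -0.4,
                                                shank = 0.4, foot = 0.25)),
               "positive")
  expect_error(gait_profile(stance_fraction = 1.2), "stance_fraction")
  expect_error(gait_profile(dropout_prob_crossing = 2), "dropout")
})
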