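# Agreement statistics vs. independent brute-force oracles, plus the
# interpretation bands.

test_that("mae matches hand sums and the constant-offset property", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(1, 2, 3), c(2, 2, 5)), 1)
  set.seed(1)
  w <- rnorm(101)
  for (c0 in c(-3.2, 0.5, 7)) expect_equal(mae(w + c0, w), abs(c0))
  expect_error(mae(1:3, 1:4), "length")
})

test_that("mae_ci reproduces the t-interval, including the n=2 case", {
  ci <- mae_ci(c(2, 4))
  expect_equal(unname(ci["mean"]), 3)
  expect_equal(unname(ci["ci_low"]), 3 - qt(0.975, 1) * sd(c(2, 4)) / sqrt(2),
               tolerance = 1e-12)
  expect_equal(unname(ci["ci_high"]), 15.70621, tolerance = 1e-5)
  ci0 <- mae_ci(rep(4.4, 5))
  expect_equal(unname(ci0), c(4.4, 4.4, 4.4))
  expect_error(mae_ci(3), "two")
  set.seed(2)
  for (i in 1:100) {
    v <- rnorm(sample(2:30, 1), sd = runif(1, 0.1, 5))
    expect_equal(unname(mae_ci(v)), mae_ci_oracle(v), tolerance = 1e-12)
  }
})

test_that("cmc agrees with a literal double-loop transcription", {
  w <- sin(seq(0, 2 * pi, length.out = 101))
  expect_equal(cmc(rbind(w, w)), 1)
  # the F=2, T=2 antisymmetric case: within-time dispersion exceeds the
  # total dispersion (ratio 1.5 > 1), so the CMC is undefined
  y <- rbind(c(0, 2), c(2, 0))
  expect_true(is.na(cmc(y)))
  expect_true(is.na(cmc_oracle(y)))
  expect_true(is.na(cmc(rbind(rep(1, 5), rep(1, 5)))))  # zero variance
  set.seed(3)
  n_def <- 0
  for (i in 1:150) {
    f <- sample(2:4, 1)
    tt <- sample(2:40, 1)
    y <- matrix(rnorm(f * tt), f, tt)
    # correlated pairs so defined values are well represented
    if (i %% 2 == 0) y <- y[1, ][col(y)] + 0.2 * y
    got <- cmc(y)
    want <- cmc_oracle(y)
    if (is.na(want)) {
      expect_true(is.na(got))
    } else {
      n_def <- n_def + 1
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
  expect_gte(n_def, 50)
  expect_error(cmc(matrix(1, 1, 5)), "protocols")
})

test_that("icc_1_3 matches the ANOVA mean-squares oracle", {
  perfect <- cbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  res <- icc_1_3(perfect)
  expect_equal(res$icc, 1)
  expect_equal(res$ci_low, 1)
  set.seed(4)
  for (i in 1:120) {
    n <- sample(4:20, 1)
    k <- sample(2:5, 1)
    x <- matrix(rnorm(n * k), n, k) + rnorm(n)[row(matrix(0, n, k))]
    res <- icc_1_3(x)
    expect_equal(res$icc, icc_oracle(x), tolerance = 1e-10)
    # CI is ordered and contains the point estimate
    expect_lte(res$ci_low, res$icc)
    expect_gte(res$ci_high, res$icc)
  }
  expect_error(icc_1_3(matrix(1, 2, 3)), "n >= 3")
})

test_that("icc_1_3 increases with between-subject variance at fixed noise", {
  set.seed(5)
  mean_icc <- sapply(c(0.5, 2, 8), function(sdb) {
    mean(replicate(200, {
      subj <- rnorm(12, sd = sdb)
      icc_1_3(matrix(subj, 12, 3) + matrix(rnorm(36), 12, 3))$icc
    }))
  })
  expect_true(all(diff(mean_icc) > 0))
})

test_that("pearson_r and paired_t match textbook formulas and conventions", {
  x <- c(1.2, 2.1, 3.3, 4.0, 5.5)
  expect_equal(unname(pearson_r(x, 2 * x + 1)["r"]), 1)
  tt <- paired_t(x, x)
  expect_equal(unname(tt["t"]), 0)
  expect_equal(unname(tt["p"]), 1)
  # constant nonzero difference: infinite t, zero p
  tc <- paired_t(x + 2, x)
  expect_equal(unname(tc["t"]), Inf)
  expect_equal(unname(tc["p"]), 0)
  set.seed(6)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    a <- rnorm(n)
    b <- 0.5 * a + rnorm(n)
    pr <- pearson_r(a, b)
    po <- pearson_oracle(a, b)
    expect_equal(unname(pr["r"]), unname(po["r"]), tolerance = 1e-12)
    expect_equal(unname(pr["p"]), unname(po["p"]), tolerance = 1e-12)
    pt_ <- paired_t(a, b)
    pto <- paired_t_oracle(a, b)
    expect_equal(unname(pt_["t"]), unname(pto["t"]), tolerance = 1e-12)
    expect_equal(unname(pt_["p"]), unname(pto["p"]), tolerance = 1e-12)
  }
})

test_that("the MAE triangle-type bound holds on random waveforms", {
  set.seed(7)
  for (i in 1:50) {
    a <- rnorm(101)
    b <- rnorm(101)
    c0 <- rnorm(101)
    expect_lte(mae(a, c0), mae(a, b) + mae(b, c0) + 1e-12)
  }
})

test_that("cmc degrades with phase shift until it becomes undefined", {
  p <- gait_profile()
  tg <- seq(0, 1, length.out = 101)
  knee <- angle_templates(p, tg)$knee
  shift_wave <- function(s) angle_templates(p, (tg + s) %% 1)$knee
  vals <- sapply(seq(0.01, 0.25, by = 0.02), function(s)
    cmc(rbind(knee, shift_wave(s))))
  def <- which(!is.na(vals))
  expect_gte(length(def), 5)
  expect_true(all(diff(vals[def]) < 0))
  # undefined values form a suffix: once lost, similarity never returns
  if (anyNA(vals)) {
    expect_true(all(is.na(vals[min(which(is.na(vals))):length(vals)])))
  }
})

test_that("interpretation bands map the documented boundaries exactly", {
  expect_equal(interpret_band("AE", c(1.9, 2, 3.1, 5, 5.01, 10, 10.5)),
               c("good accuracy", "good accuracy", "acceptable accuracy",
                 "acceptable accuracy", "tolerable accuracy",
                 "tolerable accuracy", "unacceptable accuracy"))
  expect_equal(interpret_band("ICC", c(0.75, 0.749, 0.4, 0.39)),
               c("excellent", "fair to good", "fair to good", "poor"))
  expect_equal(interpret_band("CMC", c(0.936, 0.95, 0.949, 0.85, 0.75,
                                       0.65, 0.64)),
               c("very good", "excellent", "very good", "very good", "good",
                 "moderate", "poor"))
  expect_equal(interpret_band("CMC", NA_real_), "undefined")
})
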