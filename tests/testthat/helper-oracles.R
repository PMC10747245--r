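# Independent brute-force transcriptions of the agreement statistics,
# written as literal double loops over their defining formulas. These stay
# independent of the package implementations they check.

cmc_oracle <- function(y) {
  f <- nrow(y)
  tt <- ncol(y)
  ybar_t <- numeric(tt)
  for (j in seq_len(tt)) ybar_t[j] <- mean(y[, j])
  ybar <- mean(y)
  num <- 0
  den <- 0
  for (i in seq_len(f)) {
    for (j in seq_len(tt)) {
      num <- num + (y[i, j] - ybar_t[j])^2
      den <- den + (y[i, j] - ybar)^2
    }
  }
  num <- num / (tt * (f - 1))
  den <- den / (f * tt - 1)
  if (den == 0) return(NA_real_)
  ratio <- num / den
  if (ratio > 1) return(NA_real_)
  sqrt(1 - ratio)
}

icc_oracle <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  grand <- mean(x)
  ss_b <- 0
  ss_w <- 0
  for (i in seq_len(n)) {
    mi <- mean(x[i, ])
    ss_b <- ss_b + k * (mi - grand)^2
    for (j in seq_len(k)) ss_w <- ss_w + (x[i, j] - mi)^2
  }
  bms <- ss_b / (n - 1)
  wms <- ss_w / (n * (k - 1))
  (bms - wms) / bms
}

mae_oracle <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + abs(a[i] - b[i])
  s / length(a)
}

mae_ci_oracle <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  s <- sqrt(sum((v - m)^2) / (n - 1))
  half <- qt(0.975, n - 1) * s / sqrt(n)
  c(m, m - half, m + half)
}

pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- mean(x)
  my <- mean(y)
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * pt(-abs(tstat), n - 2))
}

paired_t_oracle <- function(x, y) {
  d <- x - y
  n <- length(d)
  tstat <- mean(d) / (sd(d) / sqrt(n))
  c(t = tstat, p = 2 * pt(-abs(tstat), n - 1))
}

# Magnitude response of the package's zero-lag filter (digital design,
# applied forward and backward) computed directly from the designed
# coefficients: |B(z)/A(z)|^2 at z = exp(i 2 pi f / rate).
butter_response_sq <- function(f, rate, cutoff_hz = 6, design_order = 2) {
  bf <- signal::butter(design_order, cutoff_hz / (rate / 2))
  z <- exp(-1i * 2 * pi * f / rate)
  h <- sum(bf$b * z^(seq_along(bf$b) - 1)) /
    sum(bf$a * z^(seq_along(bf$a) - 1))
  Mod(h)^2
}

# Small default profile for fast tests.
quick_profile <- function(...) {
  gait_profile(n_cycles = 2, ...)
}
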