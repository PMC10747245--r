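# Agreement statistics: MAE with parametric CI, coefficient of multiple
# correlation (CMC), ICC(1,k), Pearson r, paired t-tests, and the clinical
# interpretation bands.

#' Mean absolute error between two paired waveforms
#'
#' @param ai,ref Equal-length numeric vectors (e.g. 101-point normalized
#'   waveforms), no missing values.
#' @return Mean of `|ai - ref|`.
#' @examples
#' mae(c(1, 2, 3), c(2, 2, 5))  # 1
#' @export
mae <- function(ai, ref) {
  if (length(ai) != length(ref)) stop("waveforms must have equal length")
  if (anyNA(ai) || anyNA(ref)) stop("waveforms must be complete")
  mean(abs(ai - ref))
}

#' Mean and parametric 95% confidence interval of per-participant MAEs
#'
#' `mean +/- t(0.975, n-1) * sd / sqrt(n)` across participants.
#'
#' @param values Numeric vector of per-participant MAEs (n >= 2).
#' @param conf Confidence level (default 0.95).
#' @return Named numeric: `mean`, `ci_low`, `ci_high`.
#' @export
mae_ci <- function(values, conf = 0.95) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("need at least two values for a confidence interval")
  m <- mean(values)
  half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) *
    stats::sd(values) / sqrt(n)
  c(mean = m, ci_low = m - half, ci_high = m + half)
}

#' Coefficient of multiple correlation across measurement protocols
#'
#' For an `F x T` matrix of `F` protocol waveforms over the same `T`
#' within-cycle time points,
#' `CMC = sqrt(1 - [sum_ft (Y_ft - Ybar_t)^2 / (T (F - 1))] /
#' [sum_ft (Y_ft - Ybar)^2 / (F T - 1)])`,
#' with `Ybar_t` the across-protocol mean at time `t` and `Ybar` the grand
#' mean. When the within-time dispersion exceeds the total dispersion the
#' radicand is negative and the CMC is undefined: `NA` is returned, never a
#' clamped value. All-constant input (zero total variance) is likewise
#' undefined.
#'
#' @param waveforms Numeric `F x T` matrix, `F >= 2`, `T >= 2`.
#' @return The CMC (unitless, at most 1), or `NA_real_` when undefined.
#' @examples
#' w <- sin(seq(0, 2 * pi, length.out = 101))
#' cmc(rbind(w, w))  # identical waveforms: 1
#' @export
cmc <- function(waveforms) {
  y <- as.matrix(waveforms)
  f <- nrow(y)
  tt <- ncol(y)
  if (f < 2 || tt < 2) stop("need at least 2 protocols and 2 time points")
  if (anyNA(y)) stop("waveforms must be complete")
  ybar_t <- colMeans(y)
  ybar <- mean(y)
  num <- sum(sweep(y, 2, ybar_t)^2) / (tt * (f - 1))
  den <- sum((y - ybar)^2) / (f * tt - 1)
  if (den == 0) return(NA_real_)
  ratio <- num / den
  if (ratio > 1) return(NA_real_)
  sqrt(1 - ratio)
}

#' One-way random-effects, average-measures intraclass correlation ICC(1,k)
#'
#' From the one-way ANOVA decomposition of an `n x k`
#' (subjects x repeated trials) matrix: `ICC(1,k) = (BMS - WMS) / BMS`,
#' where `BMS` and `WMS` are the between- and within-subject mean squares.
#' The confidence interval follows the F-distribution bounds on `BMS/WMS`
#' (Shrout & Fleiss): with `Fobs = BMS/WMS`,
#' `lower = 1 - 1/(Fobs / F(1-a/2; n-1, n(k-1)))` and
#' `upper = 1 - 1/(Fobs * F(1-a/2; n(k-1), n-1))`.
#' Degenerate data (zero between-subject variance) yield an ICC at or below
#' 0, reported as computed rather than floored.
#'
#' @param data Complete numeric `n x k` matrix, `n >= 3`, `k >= 2`.
#' @param conf Confidence level (default 0.95).
#' @return List with `icc`, `ci_low`, `ci_high`, `f_value`, `p_value`,
#'   `n`, `k`.
#' @examples
#' icc_1_3(cbind(1:5, 1:5 + 0.1, 1:5 - 0.1))$icc
#' @export
icc_1_3 <- function(data, conf = 0.95) {
  x <- as.matrix(data)
  n <- nrow(x)
  k <- ncol(x)
  if (n < 3 || k < 2) stop("need n >= 3 subjects and k >= 2 trials")
  if (anyNA(x)) stop("matrix must be complete")
  row_m <- rowMeans(x)
  grand <- mean(x)
  bms <- k * sum((row_m - grand)^2) / (n - 1)
  wms <- sum((x - row_m)^2) / (n * (k - 1))
  icc <- if (bms == 0) NA_real_ else (bms - wms) / bms
  if (wms == 0) {
    # zero within-subject variance: perfect reproducibility
    return(list(icc = icc, ci_low = if (is.na(icc)) NA_real_ else icc,
                ci_high = if (is.na(icc)) NA_real_ else icc,
                f_value = Inf, p_value = 0, n = n, k = k))
  }
  fobs <- bms / wms
  alpha <- 1 - conf
  fl <- fobs / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
  fu <- fobs * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
  list(
    icc = icc,
    ci_low = 1 - 1 / fl,
    ci_high = 1 - 1 / fu,
    f_value = fobs,
    p_value = stats::pf(fobs, n - 1, n * (k - 1), lower.tail = FALSE),
    n = n, k = k
  )
}

#' Pearson correlation with its two-sided p-value
#'
#' Thin wrapper over [stats::cor.test()] (t distribution, n - 2 df).
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`.
#' @return Named numeric: `r`, `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need n >= 3")
  ct <- stats::cor.test(x, y, method = "pearson")
  c(r = unname(ct$estimate), p = ct$p.value)
}

#' Paired t-test with a zero-difference convention
#'
#' [stats::t.test()] on paired data (n - 1 df), with the degenerate
#' constant-difference case resolved explicitly: identical pairs give
#' `t = 0, p = 1`; a constant non-zero difference gives `t = +/-Inf,
#' p = 0`.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`.
#' @return Named numeric: `t`, `p`, `df`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  d <- x - y
  # mirror t.test's own degeneracy guard so constant differences resolve
  # to the documented convention instead of an error
  if (stats::sd(d) <= 10 * .Machine$double.eps * max(abs(mean(d)), 1e-300)) {
    md <- mean(d)
    if (abs(md) <= 10 * .Machine$double.eps * max(abs(x), 1)) {
      return(c(t = 0, p = 1, df = n - 1, mean_diff = 0))
    }
    return(c(t = sign(md) * Inf, p = 0, df = n - 1, mean_diff = md))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  c(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
    mean_diff = unname(tt$estimate))
}

#' Clinical interpretation bands for AE, ICC and CMC
#'
#' Absolute error (degrees): `<= 2` good, `(2, 5]` acceptable, `(5, 10]`
#' tolerable, `> 10` unacceptable accuracy. ICC: `>= 0.75` excellent,
#' `[0.4, 0.75)` fair to good, `< 0.4` poor. CMC: `[0.65, 0.75)` moderate,
#' `[0.75, 0.85)` good, `[0.85, 0.95)` very good, `[0.95, 1]` excellent;
#' values below 0.65 are labelled poor. `NA` input returns `"undefined"`.
#'
#' @param metric One of `"AE"`, `"ICC"`, `"CMC"`.
#' @param value Numeric vector to classify.
#' @return Character vector of labels.
#' @examples
#' interpret_band("AE", 3.1)    # acceptable accuracy
#' interpret_band("CMC", 0.936) # very good
#' @export
interpret_band <- function(metric = c("AE", "ICC", "CMC"), value) {
  metric <- match.arg(metric)
  one <- function(v) {
    if (is.na(v)) return("undefined")
    switch(metric,
      AE = if (v <= 2) "good accuracy" else if (v <= 5) "acceptable accuracy"
        else if (v <= 10) "tolerable accuracy" else "unacceptable accuracy",
      ICC = if (v >= 0.75) "excellent" else if (v >= 0.4) "fair to good"
        else "poor",
      CMC = if (v >= 0.95) "excellent" else if (v >= 0.85) "very good"
        else if (v >= 0.75) "good" else if (v >= 0.65) "moderate"
        else "poor"
    )
  }
  vapply(value, one, character(1))
}
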