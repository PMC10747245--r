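# Gap handling and zero-lag Butterworth low-pass filtering of landmark
# trajectories. Filtering is applied to coordinates, never to angles.

#' Interpolate short confidence gaps in a pose sequence
#'
#' Interior runs of missing frames (confidence 0 or non-finite coordinates)
#' of length at most `max_gap` are filled per keypoint by linear
#' interpolation between the flanking valid frames; filled point-frames get
#' confidence 1 and are marked in the sequence's `imputed` matrix so they
#' stay reportable. Leading and trailing gaps are never extrapolated (their
#' frames remain missing). Any gap longer than `max_gap` marks the affected
#' side (both sides for Neck/MidHip) as unusable in `unusable_sides`.
#'
#' @param seq A `landmark_sequence`.
#' @param max_gap Longest interior gap (frames) that may be interpolated.
#' @return The gap-filled `landmark_sequence`.
#' @export
fill_gaps <- function(seq, max_gap = 10) {
  stopifnot(inherits(seq, "landmark_sequence"))
  if (!is.finite(max_gap) || max_gap < 0) stop("max_gap must be >= 0")
  nfr <- n_frames(seq)
  unusable <- seq$unusable_sides
  kp_side <- function(kp) {
    if (startsWith(kp, "L")) "left" else if (startsWith(kp, "R")) "right"
    else c("right", "left")
  }
  for (kp in colnames(seq$x)) {
    valid <- seq$conf[, kp] > 0 & is.finite(seq$x[, kp]) &
      is.finite(seq$y[, kp])
    if (all(valid)) next
    r <- rle(valid)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$lengths)) {
      if (r$values[i]) next
      len <- r$lengths[i]
      interior <- i > 1L && i < length(r$lengths)
      if (len > max_gap) {
        unusable <- union(unusable, kp_side(kp))
        next
      }
      if (!interior) next  # edge gap: flagged, never extrapolated
      lo <- starts[i] - 1L
      hi <- ends[i] + 1L
      w <- (starts[i]:ends[i] - lo) / (hi - lo)
      seq$x[starts[i]:ends[i], kp] <-
        seq$x[lo, kp] + w * (seq$x[hi, kp] - seq$x[lo, kp])
      seq$y[starts[i]:ends[i], kp] <-
        seq$y[lo, kp] + w * (seq$y[hi, kp] - seq$y[lo, kp])
      seq$conf[starts[i]:ends[i], kp] <- 1
      seq$imputed[starts[i]:ends[i], kp] <- TRUE
    }
  }
  seq$unusable_sides <- unusable
  seq
}

# Steady-state past samples make a constant pass through the filter exactly
# (DC gain 1 to machine precision); odd reflection padding suppresses edge
# transients of non-constant inputs.
.filter_pass <- function(b, a, x, padlen) {
  n <- length(x)
  padlen <- min(padlen, n - 1L)
  pre <- 2 * x[1] - x[seq(padlen + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - padlen)]
  xe <- c(pre, x, post)
  k <- length(a) - 1L
  y <- signal::filter(b, a, xe, init.x = rep(xe[1], k),
                      init.y = rep(xe[1], k))
  y[seq(padlen + 1L, padlen + n)]
}

#' Zero-lag Butterworth low-pass filter for one series
#'
#' Implements the biomechanics-standard "fourth-order zero-lag Butterworth"
#' as a half-order design applied forward then backward
#' (`convention = "effective"`, the default: a 2nd-order design run twice
#' gives an effective 4th-order, zero-phase response with -6.02 dB at the
#' cutoff). `convention = "design"` instead runs the full-order design
#' forward-backward (effective order doubled). Edge transients are
#' controlled by odd-reflection padding with steady-state initial
#' conditions, so the DC gain is exactly 1.
#'
#' @param x Numeric series (no `NA`).
#' @param rate Sampling rate, Hz.
#' @param cutoff_hz Low-pass cutoff, Hz (default 6); must be below `rate/2`.
#' @param order Effective filter order (default 4; even for the
#'   `"effective"` convention).
#' @param convention `"effective"` or `"design"` (see Details).
#' @return Filtered series, same length.
#' @export
zero_lag_butter <- function(x, rate, cutoff_hz = 6, order = 4,
                            convention = c("effective", "design")) {
  convention <- match.arg(convention)
  if (anyNA(x)) stop("x must not contain NA; fill or split gaps first")
  if (cutoff_hz <= 0 || rate <= 2 * cutoff_hz) {
    stop("need rate > 2 * cutoff_hz")
  }
  design_order <- if (convention == "effective") {
    if (order %% 2 != 0) stop("order must be even for convention 'effective'")
    order / 2
  } else {
    order
  }
  min_len <- 3L * (design_order + 1L) + 1L
  if (length(x) < min_len) {
    stop(sprintf("series too short to filter: need at least %d samples",
                 min_len))
  }
  bf <- signal::butter(design_order, cutoff_hz / (rate / 2))
  pole <- max(Mod(polyroot(rev(bf$a))))
  padlen <- ceiling(log(1e-13) / log(max(min(pole, 0.999), 1e-6)))
  padlen <- max(3L * (design_order + 1L), min(padlen, 2000L))
  y <- .filter_pass(bf$b, bf$a, x, padlen)
  rev(.filter_pass(bf$b, bf$a, rev(y), padlen))
}

#' Low-pass filter all trajectories of a landmark sequence
#'
#' Applies [zero_lag_butter()] to the x and y series of every keypoint.
#' Frames left missing after gap handling split a trajectory into finite
#' runs; each run long enough for the filter is smoothed independently and
#' shorter runs pass through unfiltered, so missing frames never bleed into
#' valid ones. Imputed frames are filtered like real ones and stay flagged.
#'
#' @param seq A `landmark_sequence`.
#' @inheritParams zero_lag_butter
#' @return The filtered `landmark_sequence`.
#' @export
lowpass <- function(seq, cutoff_hz = 6, order = 4,
                    convention = c("effective", "design")) {
  stopifnot(inherits(seq, "landmark_sequence"))
  convention <- match.arg(convention)
  design_order <- if (convention == "effective") order / 2 else order
  min_len <- 3L * (design_order + 1L) + 1L
  smooth_col <- function(v, valid) {
    r <- rle(valid)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$lengths)) {
      if (!r$values[i] || r$lengths[i] < min_len) next
      idx <- starts[i]:ends[i]
      v[idx] <- zero_lag_butter(v[idx], rate = seq$rate,
                                cutoff_hz = cutoff_hz, order = order,
                                convention = convention)
    }
    v
  }
  for (kp in colnames(seq$x)) {
    valid <- seq$conf[, kp] > 0 & is.finite(seq$x[, kp]) &
      is.finite(seq$y[, kp])
    seq$x[, kp] <- smooth_col(seq$x[, kp], valid)
    seq$y[, kp] <- smooth_col(seq$y[, kp], valid)
  }
  seq
}
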