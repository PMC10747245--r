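# Gait-event detection from vertical GRF and cycle time-normalization.
#
# Sample/frame indices are 0-based throughout (timestamp = index / rate).

#' Detect initial contacts and toe-offs from vertical GRF
#'
#' Ground contact is the force exceeding `threshold_n` (strictly). An
#' initial contact is the first sample of a contact run that is preceded by
#' at least `quiet_s` below the threshold (a below-threshold run touching
#' the start of the recording counts as quiet, since pre-trial quiet is
#' unobservable); contact runs shorter than `min_contact_s` are discarded as
#' artifacts. A toe-off is the first sample after a contact run, provided
#' the force then stays at or below the threshold for at least `quiet_s`.
#'
#' @param grf A `force_series`.
#' @param threshold_n Contact threshold in newtons (default 20).
#' @param min_contact_s Minimum contact-run duration in seconds.
#' @param quiet_s Minimum below-threshold duration that validates an initial
#'   contact (before) or a toe-off (after), seconds.
#' @return List with integer vectors `ic` and `toe_off` (0-based force-sample
#'   indices), plus `rate` and `threshold_n`. Empty vectors when no crossing
#'   is found.
#' @examples
#' p <- gait_profile(n_cycles = 2)
#' ev <- detect_events(synth_grf(p)$right)
#' ev$ic
#' @export
detect_events <- function(grf, threshold_n = 20, min_contact_s = 0.1,
                          quiet_s = 0.05) {
  stopifnot(inherits(grf, "force_series"))
  if (!is.finite(threshold_n) || threshold_n <= 0) {
    stop("threshold_n must be positive")
  }
  fz <- grf$fz
  rate <- grf$rate
  min_contact <- as.integer(round(min_contact_s * rate))
  quiet <- as.integer(round(quiet_s * rate))

  above <- fz > threshold_n
  if (!any(above)) {
    return(list(ic = integer(0), toe_off = integer(0), rate = rate,
                threshold_n = threshold_n))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L  # 1-based

  ics <- integer(0)
  toes <- integer(0)
  nrun <- length(r$lengths)
  for (i in seq_len(nrun)) {
    if (!r$values[i]) next
    if (r$lengths[i] < min_contact) next  # artifact run
    # initial contact: needs qualifying quiet before the run
    if (i > 1L) {
      quiet_ok <- r$lengths[i - 1L] >= quiet || starts[i - 1L] == 1L
      if (quiet_ok) ics <- c(ics, starts[i] - 1L)  # 0-based
    }
    # toe-off: needs qualifying quiet after the run
    if (i < nrun) {
      after_ok <- r$lengths[i + 1L] >= quiet || ends[i + 1L] == length(fz)
      if (after_ok) toes <- c(toes, ends[i])  # 0-based first sample after run
    }
  }
  list(ic = as.integer(ics), toe_off = as.integer(toes), rate = rate,
       threshold_n = threshold_n)
}

#' Convert force-sample indices to video-frame indices
#'
#' `floor(sample * video_rate / force_rate)` on 0-based indices; the force
#' rate must be a positive integer multiple of the video rate.
#'
#' @param sample_idx Integer vector of 0-based force-sample indices.
#' @param force_rate,video_rate Sampling rates in Hz.
#' @return Integer vector of 0-based video-frame indices.
#' @examples
#' to_video_frames(40, 1200, 120)  # 4
#' @export
to_video_frames <- function(sample_idx, force_rate, video_rate) {
  if (video_rate <= 0 || force_rate %% video_rate != 0) {
    stop("force_rate must be a positive integer multiple of video_rate")
  }
  as.integer(floor(sample_idx * video_rate / force_rate))
}

#' Build per-side gait cycles from detected events
#'
#' Pairs consecutive initial contacts (video frames) and assigns the unique
#' toe-off falling strictly between them. Cycles shorter than
#' `min_cycle_frames`, or without exactly one interior toe-off, are dropped
#' with a logged reason.
#'
#' @param ic_frames Integer vector of 0-based initial-contact video frames.
#' @param toe_off_frames Numeric vector of 0-based toe-off video frames;
#'   fractional values (force-sample events converted at force resolution,
#'   `sample * video_rate / force_rate` without flooring) are accepted and
#'   keep the stance share at force-plate precision.
#' @param n_frames Total video frames available.
#' @param min_cycle_frames Minimum cycle length in frames (default 20).
#' @return List with a data.frame `cycles` (columns `ic`, `toe_off`,
#'   `next_ic`, `stance_pct`) and a character vector `excluded`.
#' @export
build_cycles <- function(ic_frames, toe_off_frames, n_frames,
                         min_cycle_frames = 20) {
  cycles <- list()
  excluded <- character(0)
  ic_frames <- sort(unique(as.integer(ic_frames)))
  if (length(ic_frames) >= 2) {
    for (i in seq_len(length(ic_frames) - 1L)) {
      ic <- ic_frames[i]
      nic <- ic_frames[i + 1L]
      if (nic > n_frames - 1L) {
        excluded <- c(excluded, sprintf(
          "cycle at frame %d extends beyond the recording", ic))
        next
      }
      if (nic - ic < min_cycle_frames) {
        excluded <- c(excluded, sprintf(
          "cycle at frame %d spans %d frames (< %d)", ic, nic - ic,
          min_cycle_frames))
        next
      }
      to <- as.numeric(toe_off_frames[toe_off_frames > ic &
                                        toe_off_frames < nic])
      if (length(to) != 1L) {
        excluded <- c(excluded, sprintf(
          "cycle at frame %d has %d interior toe-offs", ic, length(to)))
        next
      }
      cycles[[length(cycles) + 1L]] <- data.frame(
        ic = ic, toe_off = to, next_ic = nic,
        stance_pct = 100 * (to - ic) / (nic - ic))
    }
  }
  cyc <- if (length(cycles)) do.call(rbind, cycles) else
    data.frame(ic = integer(0), toe_off = numeric(0), next_ic = integer(0),
               stance_pct = numeric(0))
  list(cycles = cyc, excluded = excluded)
}

#' Time-normalize a waveform over one gait cycle
#'
#' Linearly interpolates the angle samples between two initial contacts onto
#' the canonical 101-point grid (0, 1, ..., 100% of cycle; first point is
#' the value at initial contact, last the value at the next initial
#' contact). Interior `NA` (flagged) frames are bridged by linear
#' interpolation when they make up at most `max_flagged_frac` of the cycle;
#' otherwise — or when an endpoint is missing — the cycle is rejected.
#'
#' @param values Numeric per-frame waveform (degrees), `NA` where flagged.
#' @param ic_frame,next_ic_frame 0-based cycle bounds (video frames).
#' @param min_cycle_frames Minimum span in frames.
#' @param max_flagged_frac Maximum tolerated fraction of flagged frames.
#' @return Numeric vector of length 101, or `NULL` (with attribute handling
#'   left to the caller) when the cycle must be excluded.
#' @examples
#' normalize_cycle(rep(5, 50), 0, 49)[c(1, 101)]
#' @export
normalize_cycle <- function(values, ic_frame, next_ic_frame,
                            min_cycle_frames = 20, max_flagged_frac = 0.2) {
  if (next_ic_frame - ic_frame < min_cycle_frames) return(NULL)
  idx <- (ic_frame:next_ic_frame) + 1L
  if (idx[1] < 1L || idx[length(idx)] > length(values)) return(NULL)
  v <- values[idx]
  nbad <- sum(is.na(v))
  if (nbad > max_flagged_frac * length(v)) return(NULL)
  if (is.na(v[1]) || is.na(v[length(v)])) return(NULL)
  if (nbad > 0) {
    xi <- seq_along(v)
    v <- stats::approx(xi[!is.na(v)], v[!is.na(v)], xout = xi)$y
  }
  x <- seq(0, 1, length.out = length(v))
  stats::approx(x, v, xout = seq(0, 1, length.out = 101L))$y
}
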