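# Readers and writers for the external formats: OpenPose per-frame JSON,
# reference joint-center CSV, per-limb vertical GRF CSV, and a trial
# manifest. CSV dialect: comma separated, '.' decimal, mandatory header.

#' Default BODY-25 index map for the 12 feature points
#'
#' 0-based OpenPose BODY-25 slot for each of the 12 sagittal feature points.
#' Override entries (or supply a JSON file to [read_keypoint_map()]) when a
#' different pose model orders its keypoints differently.
#'
#' @return Named integer vector (names = `GAIT_KEYPOINTS`).
#' @export
body25_map <- function() {
  c(Neck = 1L, MidHip = 8L,
    RHip = 9L, RKnee = 10L, RAnkle = 11L, RBigToe = 22L, RHeel = 24L,
    LHip = 12L, LKnee = 13L, LAnkle = 14L, LBigToe = 19L, LHeel = 21L)
}

#' Read a keypoint map override from a small JSON file
#'
#' The file holds an object mapping feature-point names to 0-based model
#' indices, e.g. `{"Neck": 1, "MidHip": 8, ...}`; entries missing from the
#' file keep their [body25_map()] defaults.
#'
#' @param path JSON file path.
#' @return Named integer vector like [body25_map()].
#' @export
read_keypoint_map <- function(path) {
  m <- body25_map()
  ov <- jsonlite::fromJSON(path)
  bad <- setdiff(names(ov), names(m))
  if (length(bad)) {
    stop("unknown keypoint names in map file: ", paste(bad, collapse = ", "))
  }
  m[names(ov)] <- as.integer(unlist(ov))
  m
}

#' Write a pose sequence as an OpenPose-style JSON directory
#'
#' One file per frame (`<prefix>_<000000000000>_keypoints.json`), each with
#' `people[[1]]$pose_keypoints_2d` holding 25 `[x, y, confidence]` triplets
#' in BODY-25 order; unmapped slots and confidence-0 points are written as
#' `0, 0, 0` (the OpenPose missing-point convention).
#'
#' @param pose A pose `landmark_sequence`.
#' @param path Output directory (created if needed).
#' @param keypoint_map Named map of feature point to 0-based model index.
#' @param prefix Filename prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_openpose_dir <- function(pose, path, keypoint_map = body25_map(),
                               prefix = "frame") {
  stopifnot(inherits(pose, "landmark_sequence"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  nfr <- n_frames(pose)
  files <- character(nfr)
  for (i in seq_len(nfr)) {
    v <- numeric(75)
    for (kp in names(keypoint_map)) {
      slot <- keypoint_map[[kp]]
      if (pose$conf[i, kp] > 0) {
        v[3 * slot + 1] <- pose$x[i, kp]
        v[3 * slot + 2] <- pose$y[i, kp]
        v[3 * slot + 3] <- pose$conf[i, kp]
      }
    }
    obj <- list(version = 1.3,
                people = list(list(person_id = list(-1L),
                                   pose_keypoints_2d = v)))
    f <- file.path(path, sprintf("%s_%012d_keypoints.json", prefix, i - 1L))
    jsonlite::write_json(obj, f, digits = NA, auto_unbox = TRUE)
    files[i] <- f
  }
  invisible(files)
}

#' Read an OpenPose JSON directory into a pose sequence
#'
#' Frames are ordered by the numeric index embedded in each filename (the
#' OpenPose zero-padded suffix), so shuffled listings still yield strictly
#' increasing timestamps. Points written as `0, 0, 0` or with zero
#' confidence are carried as confidence 0 with invalid (`NA`) coordinates.
#' A frame with no detected people becomes an all-dropout frame (counted in
#' a warning); a frame with more than one person is an error naming the
#' file, since the single-subject walkway expects exactly one.
#'
#' @param path Directory of per-frame JSON files.
#' @param keypoint_map Named map of feature point to 0-based model index.
#' @param video_rate Video sampling rate, Hz (timestamps = frame / rate).
#' @return A pose `landmark_sequence`.
#' @export
read_openpose_dir <- function(path, keypoint_map = body25_map(),
                              video_rate = 120) {
  files <- list.files(path, pattern = "\\.json$", full.names = TRUE)
  if (!length(files)) stop("no JSON frame files found in ", path)
  idx <- suppressWarnings(as.numeric(sub(
    ".*?(\\d+)(_keypoints)?\\.json$", "\\1", basename(files))))
  if (anyNA(idx)) stop("cannot parse a frame index from some filenames")
  files <- files[order(idx)]
  nfr <- length(files)
  nk <- length(GAIT_KEYPOINTS)
  x <- matrix(NA_real_, nfr, nk, dimnames = list(NULL, GAIT_KEYPOINTS))
  y <- x
  conf <- matrix(0, nfr, nk, dimnames = list(NULL, GAIT_KEYPOINTS))
  empty_frames <- 0L
  for (i in seq_len(nfr)) {
    obj <- jsonlite::fromJSON(files[i], simplifyVector = TRUE)
    ppl <- obj$people
    npeople <- if (is.null(ppl)) 0L else if (is.data.frame(ppl)) nrow(ppl)
      else length(ppl)
    if (npeople == 0L) {
      empty_frames <- empty_frames + 1L
      next
    }
    if (npeople > 1L) {
      stop(sprintf("frame file '%s' contains %d people; expected one",
                   basename(files[i]), npeople))
    }
    v <- if (is.data.frame(ppl)) unlist(ppl$pose_keypoints_2d[1]) else
      unlist(ppl[[1]]$pose_keypoints_2d)
    for (kp in names(keypoint_map)) {
      slot <- keypoint_map[[kp]]
      xi <- v[3 * slot + 1]
      yi <- v[3 * slot + 2]
      ci <- v[3 * slot + 3]
      if (is.na(ci) || ci <= 0 || (xi == 0 && yi == 0 && ci == 0)) next
      x[i, kp] <- xi
      y[i, kp] <- yi
      conf[i, kp] <- ci
    }
  }
  if (empty_frames > 0L) {
    warning(sprintf("%d frame(s) contained no people; carried as all-dropout",
                    empty_frames))
  }
  seq <- new_landmark_sequence((seq_len(nfr) - 1L) / video_rate, x, y, conf,
                               source = "ai", rate = video_rate)
  attr(seq, "empty_frames") <- empty_frames
  seq
}

#' Write reference joint centers to CSV
#'
#' Columns: `frame` (0-based), `time_s`, then `<point>_x`, `<point>_y` for
#' each of the 12 feature points, in pixels.
#'
#' @param ref A reference `landmark_sequence`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_reference_csv <- function(ref, path) {
  stopifnot(inherits(ref, "landmark_sequence"))
  df <- data.frame(frame = seq_len(n_frames(ref)) - 1L, time_s = ref$time)
  for (kp in colnames(ref$x)) {
    df[[paste0(kp, "_x")]] <- ref$x[, kp]
    df[[paste0(kp, "_y")]] <- ref$y[, kp]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read reference joint centers from CSV
#'
#' Requires `time_s` plus `<point>_x`/`<point>_y` columns for all 12
#' feature points (an error names the first missing column); unrelated
#' extra columns are ignored. The time column must be strictly increasing.
#'
#' @param path CSV path.
#' @return A reference `landmark_sequence` (confidence fixed at 1).
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", paste0(rep(GAIT_KEYPOINTS, each = 2), c("_x", "_y")))
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (any(diff(df$time_s) <= 0)) {
    stop("time_s column must be strictly increasing")
  }
  x <- sapply(GAIT_KEYPOINTS, function(kp) df[[paste0(kp, "_x")]])
  y <- sapply(GAIT_KEYPOINTS, function(kp) df[[paste0(kp, "_y")]])
  new_landmark_sequence(df$time_s, x, y, source = "reference")
}

#' Write a vertical GRF series to CSV
#'
#' Columns: `sample` (0-based), `time_s`, `fz_n`.
#'
#' @param grf A `force_series`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_grf_csv <- function(grf, path) {
  stopifnot(inherits(grf, "force_series"))
  df <- data.frame(sample = seq_along(grf$fz) - 1L, time_s = grf$time,
                   fz_n = grf$fz)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a vertical GRF series from CSV
#'
#' Requires `time_s` and `fz_n` columns; negative force samples (unloading
#' artifacts) are preserved, never clipped. Fails loudly on malformed input
#' (wrong delimiter, missing columns, non-monotone time).
#'
#' @param path CSV path.
#' @param side `"right"` or `"left"`.
#' @return A `force_series`.
#' @export
read_grf_csv <- function(path, side = c("right", "left")) {
  side <- match.arg(side)
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(c("time_s", "fz_n"), names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (any(diff(df$time_s) <= 0)) {
    stop("time_s column must be strictly increasing")
  }
  if (!is.numeric(df$fz_n) || anyNA(df$fz_n)) {
    stop("fz_n column must be numeric and complete")
  }
  new_force_series(df$time_s, df$fz_n, side = side)
}

#' Write a simulated trial to disk
#'
#' Emits the pose keypoints as an OpenPose JSON directory (`pose/`), the
#' reference joint centers and the two GRF traces as CSV, and a
#' `manifest.json` recording the full profile, the seed and the true
#' initial-contact frames so the trial is reproducible from the files
#' alone.
#'
#' @param trial A [simulate_trial()] result.
#' @param path Output directory.
#' @return Invisibly, `path`.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "gait_trial"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_openpose_dir(trial$pose, file.path(path, "pose"))
  write_reference_csv(trial$reference, file.path(path, "reference.csv"))
  write_grf_csv(trial$grf$right, file.path(path, "grf_right.csv"))
  write_grf_csv(trial$grf$left, file.path(path, "grf_left.csv"))
  prof <- trial$profile
  manifest <- list(
    profile = unclass(prof)[setdiff(names(prof), "segment_lengths")],
    segment_lengths = as.list(prof$segment_lengths),
    true_events = trial$true_events
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
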