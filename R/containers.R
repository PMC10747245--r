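# Internal time-series containers shared across the pipeline.
#
# A landmark_sequence holds per-frame x/y (pixels) and confidence for the 12
# feature points; pose keypoints (source "ai") and reference joint centers
# (source "reference", confidence fixed at 1) use the same structure.

new_landmark_sequence <- function(time, x, y, conf = NULL,
                                  source = c("ai", "reference"),
                                  rate = NULL, imputed = NULL,
                                  unusable_sides = character()) {
  source <- match.arg(source)
  x <- as.matrix(x)
  y <- as.matrix(y)
  n <- nrow(x)
  if (is.null(conf)) conf <- matrix(1, n, ncol(x))
  conf <- as.matrix(conf)
  stopifnot(
    ncol(x) == length(GAIT_KEYPOINTS),
    all(dim(y) == dim(x)), all(dim(conf) == dim(x)),
    length(time) == n
  )
  if (n > 1 && any(diff(time) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  if (any(conf < 0 | conf > 1, na.rm = TRUE)) {
    stop("confidence values must lie in [0, 1]")
  }
  bad <- conf > 0 & (!is.finite(x) | !is.finite(y))
  if (any(bad)) stop("coordinates must be finite where confidence > 0")
  colnames(x) <- colnames(y) <- colnames(conf) <- GAIT_KEYPOINTS
  if (is.null(rate) && n > 1) rate <- 1 / stats::median(diff(time))
  if (is.null(imputed)) imputed <- matrix(FALSE, n, ncol(x),
                                          dimnames = dimnames(x))
  obj <- list(time = as.numeric(time), x = x, y = y, conf = conf,
              rate = rate, source = source, imputed = imputed,
              unusable_sides = unusable_sides)
  class(obj) <- "landmark_sequence"
  obj
}

#' @export
print.landmark_sequence <- function(x, ...) {
  cat(sprintf("<landmark_sequence source=%s> %d frames @ %.6g Hz, %d keypoints\n",
              x$source, nrow(x$x), x$rate, ncol(x$x)))
  nmiss <- sum(x$conf == 0)
  if (nmiss > 0) cat(sprintf("  %d point-frames at confidence 0\n", nmiss))
  if (length(x$unusable_sides)) {
    cat("  unusable sides:", paste(x$unusable_sides, collapse = ", "), "\n")
  }
  invisible(x)
}

n_frames <- function(seq) length(seq$time)

# side -> keypoint columns (core landmarks belong to both sides)
.side_keypoints <- function(side) {
  switch(side,
         right = c("RHip", "RKnee", "RAnkle", "RBigToe", "RHeel"),
         left = c("LHip", "LKnee", "LAnkle", "LBigToe", "LHeel"),
         stop("side must be 'right' or 'left'"))
}

new_force_series <- function(time, fz, side = c("right", "left"),
                             rate = NULL) {
  side <- match.arg(side)
  if (!all(is.finite(fz))) stop("fz must be finite")
  if (length(time) != length(fz)) stop("time and fz lengths differ")
  if (length(time) > 1 && any(diff(time) <= 0)) {
    stop("timestamps must be strictly increasing")
  }
  if (is.null(rate) && length(time) > 1) {
    rate <- 1 / stats::median(diff(time))
  }
  obj <- list(time = as.numeric(time), fz = as.numeric(fz), side = side,
              rate = rate)
  class(obj) <- "force_series"
  obj
}

#' @export
print.force_series <- function(x, ...) {
  cat(sprintf("<force_series side=%s> %d samples @ %.6g Hz, peak %.1f N\n",
              x$side, length(x$fz), x$rate, max(x$fz)))
  invisible(x)
}
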