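# Model input construction: frame-difference stacks for the sequence
# network, and fixed-length lock-in feature vectors for the SVM.

#' Pixel-wise frame-difference stack
#'
#' Element t of the stack is frame(t+1) - frame(t); the whole stack is then
#' min-max scaled to [0, 1] globally per video, with the scaling range
#' anchored to include 0 so that a zero difference always maps to the same
#' point of the output range (a constant video yields an all-zero stack).
#' This preprocessing exposes the temporal speckle dynamics to a
#' convolution-based sequence model.
#'
#' @param video A `speckle_video` or rows x cols x frames array, >= 2 frames.
#' @return A `difference_sequence`: list with `frames` (rows x cols x
#'   (frames - 1) array in [0, 1]) and `label` (glucose level or `NA`).
#' @export
frame_difference_stack <- function(video) {
  label <- NA_real_
  if (inherits(video, "speckle_video")) {
    label <- video$label
    frames <- video$frames
  } else {
    frames <- video
  }
  if (!is.array(frames) || length(dim(frames)) != 3) {
    stop_invalid("`video` must be a speckle_video or a 3-d array")
  }
  n <- dim(frames)[3]
  if (n < 2) stop_invalid("video must contain at least 2 frames")
  d <- frames[, , 2:n, drop = FALSE] - frames[, , 1:(n - 1), drop = FALSE]
  lo <- min(0, min(d))
  hi <- max(0, max(d))
  d <- if (hi > lo) (d - lo) / (hi - lo) else d * 0
  structure(list(frames = d, label = label), class = "difference_sequence")
}

resample_linear <- function(x, m) {
  n <- length(x)
  if (n == m) return(as.numeric(x))
  stats::approx(seq_len(n), x, xout = seq(1, n, length.out = m))$y
}

#' Build a fixed-length SVM feature row from lock-in series
#'
#' Each displacement channel (x and y), after lock-in filtering, is
#' resampled to `target_length / 2` points by uniform linear interpolation;
#' the two channels are concatenated and z-scored, giving one row of
#' `target_length` columns per recording.
#'
#' @param lockin_x,lockin_y `lockin_series` objects or numeric vectors of
#'   equal length.
#' @param target_length Even feature-vector length (default 500).
#' @return Numeric vector of length `target_length`, mean 0 and sd 1.
#' @export
build_ml_features <- function(lockin_x, lockin_y, target_length = 500) {
  if (inherits(lockin_x, "lockin_series")) lockin_x <- lockin_x$signal
  if (inherits(lockin_y, "lockin_series")) lockin_y <- lockin_y$signal
  if (length(lockin_x) != length(lockin_y)) {
    stop_invalid("channels must have equal lengths")
  }
  if (target_length %% 2 != 0 || target_length < 2) {
    stop_invalid("`target_length` must be a positive even number")
  }
  row <- c(resample_linear(lockin_x, target_length / 2),
           resample_linear(lockin_y, target_length / 2))
  normalize_series(row, "zscore")
}
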