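# Frame-pair speckle displacement tracking: normalized circular
# cross-correlation computed by FFT, integer argmax and 3-point parabolic
# subpixel refinement. Coordinate convention: rows = y, cols = x, origin
# top-left; the reported (dx, dy) is the shift of frame_b relative to
# frame_a.

center_frame <- function(frame, name) {
  if (!is.matrix(frame)) stop_invalid("`", name, "` must be a matrix")
  f0 <- frame - mean(frame)
  ss <- sum(f0^2)
  if (ss <= 0) stop_invalid("degenerate input: `", name, "` is constant")
  list(centered = f0, ss = ss)
}

# Core: normalized circular cross-correlation from pre-centered frames.
xcorr_surface <- function(a0, ss_a, b0, ss_b) {
  fa <- stats::fft(a0)
  fb <- stats::fft(b0)
  raw <- Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / length(a0)
  raw / sqrt(ss_a * ss_b)
}

#' Normalized circular cross-correlation of two frames
#'
#' Both frames are mean-subtracted and energy-normalized, so the surface
#' value at lag (0, 0) equals the Pearson correlation of the two frames and
#' every value lies in [-1, 1] (Cauchy-Schwarz). Lags are circular; element
#' `[i, j]` of the result is the correlation at lag (dy = i - 1, dx = j - 1)
#' modulo the frame size.
#'
#' @param frame_a,frame_b Equal-shape numeric matrices; neither constant.
#' @return Matrix of normalized correlations, same shape as the input.
#' @export
cross_correlate <- function(frame_a, frame_b) {
  a <- center_frame(frame_a, "frame_a")
  b <- center_frame(frame_b, "frame_b")
  if (!all(dim(frame_a) == dim(frame_b))) {
    stop_invalid("frames must have equal shapes")
  }
  xcorr_surface(a$centered, a$ss, b$centered, b$ss)
}

wrap_lag <- function(k, n) ifelse(k > n / 2, k - n, k)

# 3-point parabolic vertex offset from samples (c_minus, c0, c_plus) at
# lags (-1, 0, +1); 0 when the curvature vanishes.
parabolic_offset <- function(c_minus, c0, c_plus) {
  denom <- c_plus + c_minus - 2 * c0
  if (abs(denom) < .Machine$double.eps * 16) return(0)
  delta <- (c_minus - c_plus) / (2 * denom)
  max(min(delta, 0.5), -0.5)
}

# 3-point Gaussian vertex offset: a parabola fit through the log of the
# samples. The speckle correlation peak is near-Gaussian, so this has far
# less pixel-locking bias than the direct parabolic fit; falls back to the
# parabolic form when any sample is non-positive.
gaussian_offset <- function(c_minus, c0, c_plus) {
  if (c_minus <= 0 || c0 <= 0 || c_plus <= 0) {
    return(parabolic_offset(c_minus, c0, c_plus))
  }
  parabolic_offset(log(c_minus), log(c0), log(c_plus))
}

#' Estimate the displacement from a correlation surface
#'
#' Integer argmax of the surface (circular lags wrapped to the symmetric
#' range), optionally refined per axis by a 3-point fit through the peak
#' and its circular neighbours. The default `"gaussian"` refinement fits a
#' parabola to the log of the three samples — the appropriate model for the
#' near-Gaussian speckle correlation peak, with far less pixel-locking bias
#' than the direct `"parabolic"` fit (it falls back to parabolic when a
#' sample is non-positive). Exact ties on the maximum are broken by
#' smallest lag magnitude, then lexicographically on (dy, dx).
#'
#' @param surface Correlation surface from [cross_correlate()].
#' @param subpixel Logical; apply subpixel refinement (default `TRUE`).
#' @param method `"gaussian"` (default) or `"parabolic"` 3-point refinement.
#' @return List `(dx, dy, peak)`: the shift in px and the correlation at the
#'   integer peak.
#' @export
estimate_shift <- function(surface, subpixel = TRUE,
                           method = c("gaussian", "parabolic")) {
  method <- match.arg(method)
  refine <- if (method == "gaussian") gaussian_offset else parabolic_offset
  if (!is.matrix(surface) || any(!is.finite(surface))) {
    stop_invalid("`surface` must be a finite matrix")
  }
  nr <- nrow(surface)
  nc <- ncol(surface)
  peak_val <- max(surface)
  cand <- which(surface == peak_val, arr.ind = TRUE)
  dy_c <- wrap_lag(cand[, 1] - 1, nr)
  dx_c <- wrap_lag(cand[, 2] - 1, nc)
  ord <- order(dy_c^2 + dx_c^2, dy_c, dx_c)
  i <- unname(cand[ord[1], 1])
  j <- unname(cand[ord[1], 2])
  dy <- wrap_lag(i - 1, nr)
  dx <- wrap_lag(j - 1, nc)
  if (subpixel) {
    im <- if (i == 1) nr else i - 1
    ip <- if (i == nr) 1 else i + 1
    jm <- if (j == 1) nc else j - 1
    jp <- if (j == nc) 1 else j + 1
    dy <- dy + refine(surface[im, j], surface[i, j], surface[ip, j])
    dx <- dx + refine(surface[i, jm], surface[i, j], surface[i, jp])
  }
  list(dx = dx, dy = dy, peak = peak_val)
}

#' Track the speckle displacement through a video
#'
#' Produces the per-frame-pair displacement time series used as the
#' machine-learning front end. `sequential` mode correlates each frame with
#' the next (the series then approximates the frame-to-frame increment of
#' the pattern shift); `fixed_reference` correlates every frame with frame 1
#' (absolute shift, valid while boiling decorrelation is mild). The
#' time-averaged peak correlation is reported as a recording-quality metric.
#'
#' @param video A `speckle_video` or a rows x cols x frames array with at
#'   least 2 frames.
#' @param mode `"sequential"` or `"fixed_reference"`.
#' @param subpixel Logical; 3-point Gaussian subpixel refinement
#'   (default `TRUE`).
#' @return A `displacement_series`: list with numeric vectors `dx`, `dy`,
#'   `peak` (length frames - 1), `fps`, `mode`, and `mean_peak`.
#' @export
track_video <- function(video, mode = c("sequential", "fixed_reference"),
                        subpixel = TRUE) {
  mode <- match.arg(mode)
  fps <- NA_real_
  if (inherits(video, "speckle_video")) {
    fps <- video$protocol$fps
    frames <- video$frames
  } else {
    frames <- video
  }
  if (!is.array(frames) || length(dim(frames)) != 3) {
    stop_invalid("`video` must be a speckle_video or a 3-d array")
  }
  n <- dim(frames)[3]
  if (n < 2) stop_invalid("video must contain at least 2 frames")
  dx <- dy <- peak <- numeric(n - 1)
  ref <- center_frame(frames[, , 1], "frame")
  ref_fft <- Conj(stats::fft(ref$centered))
  npx <- length(ref$centered)
  for (i in seq_len(n - 1)) {
    cur <- center_frame(frames[, , i + 1], "frame")
    surface <- Re(stats::fft(ref_fft * stats::fft(cur$centered),
                             inverse = TRUE)) / npx / sqrt(ref$ss * cur$ss)
    est <- estimate_shift(surface, subpixel = subpixel)
    dx[i] <- est$dx
    dy[i] <- est$dy
    peak[i] <- est$peak
    if (mode == "sequential") {
      ref <- cur
      ref_fft <- Conj(stats::fft(cur$centered))
    }
  }
  structure(list(dx = dx, dy = dy, peak = peak, fps = fps, mode = mode,
                 mean_peak = mean(peak)),
            class = "displacement_series")
}

#' Write a displacement series to CSV
#'
#' Columns (t, dx, dy, peak); t in seconds when the frame rate is known,
#' otherwise the pair index.
#'
#' @param series A `displacement_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_displacement_series <- function(series, path) {
  stopifnot(inherits(series, "displacement_series"))
  n <- length(series$dx)
  t <- if (is.finite(series$fps)) seq_len(n) / series$fps else seq_len(n)
  utils::write.csv(data.frame(t = t, dx = series$dx, dy = series$dy,
                              peak = series$peak),
                   path, row.names = FALSE)
  invisible(path)
}
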