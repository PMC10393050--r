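# Synthetic speckle-video generator. Emulates the statistical structure the
# downstream analysis assumes: a fully developed speckle field whose
# transversal shift carries (i) a glucose-proportional component at the AC
# magnetic drive frequency when the field is on, (ii) a glucose-independent
# drive-frequency component attributed to diamagnetic hemoglobin oscillation,
# (iii) physiological pulse motion, (iv) slow random-walk drift, plus speckle
# boiling (gradual decorrelation) and additive sensor noise.

#' Acquisition protocol for a simulated speckle recording
#'
#' Defaults mirror the reference acquisition: 128 x 128 px frames at 500
#' frames per second for 5 s (2501 frames), under a 150 Gauss AC magnetic
#' field driven at 140 Hz.
#'
#' @param frame_size Pixels per (square) frame side.
#' @param fps Frames per second; must exceed twice the drive frequency
#'   (Nyquist).
#' @param duration Recording length in seconds.
#' @param frames_per_video Number of frames; default `fps * duration + 1`.
#' @param drive_frequency AC magnetic drive frequency in Hz.
#' @param field_strength Magnetic field strength in Gauss.
#' @param field_on Logical; whether the AC field is applied.
#' @param glucose_level Reference blood glucose label in mg/dl; must be > 0.
#' @param seed Integer seed controlling all randomness of the recording.
#' @return A `simulation_protocol` object.
#' @export
simulation_protocol <- function(frame_size = 128, fps = 500, duration = 5,
                                frames_per_video = fps * duration + 1,
                                drive_frequency = 140, field_strength = 150,
                                field_on = TRUE, glucose_level = 96,
                                seed = 1) {
  check_finite_scalar(frame_size, "frame_size")
  check_finite_scalar(fps, "fps")
  check_finite_scalar(drive_frequency, "drive_frequency")
  check_finite_scalar(glucose_level, "glucose_level")
  check_finite_scalar(frames_per_video, "frames_per_video")
  if (fps <= 2 * drive_frequency) {
    stop_invalid("Nyquist violation: fps must exceed 2 * drive_frequency")
  }
  if (frames_per_video < 2) stop_invalid("`frames_per_video` must be >= 2")
  if (glucose_level <= 0) stop_invalid("`glucose_level` must be > 0")
  if (field_strength < 0) stop_invalid("`field_strength` must be >= 0")
  structure(list(frame_size = as.integer(frame_size), fps = fps,
                 duration = duration,
                 frames_per_video = as.integer(frames_per_video),
                 drive_frequency = drive_frequency,
                 field_strength = field_strength,
                 field_on = isTRUE(field_on),
                 glucose_level = glucose_level,
                 seed = as.integer(seed)),
            class = "simulation_protocol")
}

#' Motion and noise model for the simulator
#'
#' The per-frame translational shift applied to the speckle field is the sum
#' of a glucose-proportional sinusoid at the drive frequency (the
#' polarization-rotation cue, horizontal axis), a fixed-amplitude quadrature
#' sinusoid at the same frequency (diamagnetic hemoglobin response, vertical
#' axis; present whenever the field is on and nearly independent of
#' glucose), a cardiac-pulse sinusoid with a weak glucose-dependent
#' second-harmonic distortion, and a random-walk drift. Boiling re-mixes the
#' underlying complex field each frame; sensor noise is additive on
#' intensities.
#'
#' @param glucose_gain Drive-frequency shift amplitude per unit glucose
#'   (px per mg/dl). Default puts the highest reference level (198 mg/dl) at
#'   0.5 px.
#' @param hb_amplitude Fixed drive-frequency shift amplitude of the
#'   hemoglobin response (px).
#' @param pulse_frequency Cardiac pulse frequency (Hz).
#' @param pulse_amplitude Pulse shift amplitude (px).
#' @param pulse_glucose_distortion Fraction of the drive-frequency glucose
#'   cue that reappears as a second-harmonic pulse-shape perturbation;
#'   this is the only glucose signature surviving with the field off.
#' @param drift_step Random-walk standard deviation per frame (px).
#' @param boiling_rate Per-frame fraction of the complex field replaced by a
#'   fresh independent field; in [0, 1).
#' @param noise_std Additive Gaussian intensity noise, as a fraction of the
#'   mean frame intensity.
#' @param grain_size Speckle grain (correlation length) in px.
#' @return A `motion_model` object.
#' @export
motion_model <- function(glucose_gain = 0.5 / 198, hb_amplitude = 0.25,
                         pulse_frequency = 1.2, pulse_amplitude = 0.3,
                         pulse_glucose_distortion = 0.1,
                         drift_step = 0.01, boiling_rate = 0.02,
                         noise_std = 0.02, grain_size = 4) {
  for (nm in c("glucose_gain", "hb_amplitude", "pulse_frequency",
               "pulse_amplitude", "pulse_glucose_distortion", "drift_step",
               "boiling_rate", "noise_std", "grain_size")) {
    check_finite_scalar(get(nm), nm)
    if (get(nm) < 0) stop_invalid("`", nm, "` must be >= 0")
  }
  if (boiling_rate >= 1) stop_invalid("`boiling_rate` must be in [0, 1)")
  structure(list(glucose_gain = glucose_gain, hb_amplitude = hb_amplitude,
                 pulse_frequency = pulse_frequency,
                 pulse_amplitude = pulse_amplitude,
                 pulse_glucose_distortion = pulse_glucose_distortion,
                 drift_step = drift_step, boiling_rate = boiling_rate,
                 noise_std = noise_std, grain_size = grain_size),
            class = "motion_model")
}

# Signed FFT frequency indices 0, 1, ..., floor(n/2), -(n/2-1), ..., -1.
fft_freq_index <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

# Low-pass pupil mask realizing the speckle grain size: frequencies within
# radius n / (2 * grain) of DC survive.
speckle_mask_index <- function(n, grain_size) {
  k <- fft_freq_index(n)
  kx <- matrix(k, n, n, byrow = TRUE)
  ky <- matrix(k, n, n)
  which(kx^2 + ky^2 <= (n / (2 * grain_size))^2)
}

#' Simulate a single fully developed speckle intensity frame
#'
#' Standard construction: a circular complex Gaussian field, low-pass
#' filtered to the requested grain size; the observed intensity is the
#' squared magnitude. The intensity histogram of a fully developed speckle
#' field is negative-exponential with unit contrast (sd/mean = 1).
#'
#' @param grid_size Frame side length in px.
#' @param grain_size Speckle grain (correlation length) in px; >= 1 and
#'   < `grid_size`.
#' @param seed Integer seed; the frame is deterministic given the seed.
#' @return A `grid_size` x `grid_size` matrix of non-negative intensities
#'   with mean 1.
#' @export
simulate_speckle_field <- function(grid_size, grain_size = 4, seed = 1) {
  check_finite_scalar(grid_size, "grid_size")
  check_finite_scalar(grain_size, "grain_size")
  if (grain_size < 1) stop_invalid("`grain_size` must be >= 1 px")
  if (grain_size >= grid_size) {
    stop_invalid("`grain_size` must be smaller than `grid_size`")
  }
  idx <- speckle_mask_index(grid_size, grain_size)
  fvec <- with_seed(seed, complex(real = stats::rnorm(length(idx)),
                                  imaginary = stats::rnorm(length(idx))))
  fmat <- matrix(0i, grid_size, grid_size)
  fmat[idx] <- fvec
  e <- stats::fft(fmat, inverse = TRUE) / grid_size^2
  intensity <- Mod(e)^2
  intensity / mean(intensity)
}

# Ground-truth per-frame shift (dx, dy) of the speckle pattern, px, relative
# to frame 1. Drive and Hb phases are locked to the recording start
# (drive-synchronous acquisition); pulse phase and drift are random.
ground_truth_shift <- function(protocol, motion) {
  n <- protocol$frames_per_video
  t <- (seq_len(n) - 1) / protocol$fps
  fd <- protocol$drive_frequency
  amp_g <- motion$glucose_gain * protocol$glucose_level
  phi_pulse <- stats::runif(1, 0, 2 * pi)
  pulse <- motion$pulse_amplitude * sin(2 * pi * motion$pulse_frequency * t + phi_pulse)
  distort <- motion$pulse_glucose_distortion * amp_g *
    sin(4 * pi * motion$pulse_frequency * t + phi_pulse)
  drift_x <- cumsum(stats::rnorm(n, 0, motion$drift_step))
  drift_y <- cumsum(stats::rnorm(n, 0, motion$drift_step))
  dx <- pulse / sqrt(2) + distort + drift_x
  dy <- pulse / sqrt(2) + drift_y
  if (protocol$field_on) {
    dx <- dx + amp_g * sin(2 * pi * fd * t)
    dy <- dy + motion$hb_amplitude * sin(2 * pi * fd * t + pi / 2)
  }
  data.frame(t = t, dx = dx - dx[1], dy = dy - dy[1])
}

#' Simulate a speckle video recording
#'
#' Generates a seeded complex speckle field and renders one frame per time
#' step by (a) convex re-mixing with a fresh independent field (boiling),
#' (b) subpixel translation by the ground-truth shift, applied as a Fourier
#' phase ramp, and (c) squared-magnitude detection with additive Gaussian
#' sensor noise. The injected shift sequence is stored alongside the frames
#' as ground truth.
#'
#' @param protocol A [simulation_protocol()].
#' @param motion A [motion_model()].
#' @param master_field_seed Optional seed for the underlying complex field;
#'   defaults to a stream derived from `protocol$seed`.
#' @return A `speckle_video` object: list with `frames` (array
#'   frame_size x frame_size x frames_per_video, non-negative), `protocol`,
#'   `label` (glucose level) and `truth` (data frame t, dx, dy).
#' @export
simulate_recording <- function(protocol, motion = motion_model(),
                               master_field_seed = NULL) {
  stopifnot(inherits(protocol, "simulation_protocol"),
            inherits(motion, "motion_model"))
  if (protocol$fps <= 2 * protocol$drive_frequency) {
    stop_invalid("Nyquist violation: fps must exceed 2 * drive_frequency")
  }
  n <- protocol$frames_per_video
  sz <- protocol$frame_size
  if (is.null(master_field_seed)) {
    master_field_seed <- derive_seed(protocol$seed, 1)
  }
  idx <- speckle_mask_index(sz, motion$grain_size)
  m <- length(idx)
  k <- fft_freq_index(sz)
  kx <- matrix(k, sz, sz, byrow = TRUE)[idx]
  ky <- matrix(k, sz, sz)[idx]
  fvec <- with_seed(master_field_seed,
                    complex(real = stats::rnorm(m), imaginary = stats::rnorm(m)))
  with_seed(derive_seed(protocol$seed, 2), {
    truth <- ground_truth_shift(protocol, motion)
    frames <- array(0, dim = c(sz, sz, n))
    fmat <- matrix(0i, sz, sz)
    r <- motion$boiling_rate
    scale <- NULL
    for (i in seq_len(n)) {
      if (r > 0 && i > 1) {
        fresh <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
        fvec <- sqrt(1 - r) * fvec + sqrt(r) * fresh
      }
      phase <- exp(-2i * pi * (kx * truth$dx[i] + ky * truth$dy[i]) / sz)
      fmat[idx] <- fvec * phase
      e <- stats::fft(fmat, inverse = TRUE) / sz^2
      intensity <- Mod(e)^2
      if (is.null(scale)) scale <- 1 / mean(intensity)
      intensity <- intensity * scale
      if (motion$noise_std > 0) {
        intensity <- intensity +
          stats::rnorm(sz * sz, 0, motion$noise_std * mean(intensity))
        intensity[intensity < 0] <- 0
      }
      frames[, , i] <- intensity
    }
    structure(list(frames = frames, protocol = protocol,
                   label = protocol$glucose_level, truth = truth),
              class = "speckle_video")
  })
}

#' @export
print.speckle_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("speckle_video: %d frames of %dx%d px @ %g fps, field %s, %g mg/dl\n",
              d[3], d[1], d[2], x$protocol$fps,
              if (x$protocol$field_on) "on" else "off", x$label))
  invisible(x)
}

#' Reference glucose levels
#'
#' The 13 finger-prick reference blood glucose levels used as class labels,
#' shipped as a packaged CSV.
#'
#' @return Data frame with columns `sample_no` and `glucose_level` (mg/dl).
#' @export
reference_levels <- function() {
  path <- system.file("extdata", "reference_glucose_levels.csv",
                      package = "speckleglucose")
  utils::read.csv(path)
}

#' Write a speckle video to disk
#'
#' Frames go to a multi-page 32-bit float TIFF (one page per frame, scaled
#' to [0, 1] by the global maximum); the ground-truth shift series goes to a
#' sidecar CSV `<stem>_truth.csv` with columns (t, dx, dy).
#'
#' @param video A `speckle_video`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_speckle_video <- function(video, path) {
  stopifnot(inherits(video, "speckle_video"))
  mx <- max(video$frames)
  if (mx <= 0) mx <- 1
  pages <- lapply(seq_len(dim(video$frames)[3]),
                  function(i) video$frames[, , i] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  truth_path <- sub("\\.tiff?$", "_truth.csv", path)
  utils::write.csv(video$truth, truth_path, row.names = FALSE)
  invisible(path)
}

#' Read a speckle video frame stack from a multi-page TIFF
#'
#' @param path TIFF path written by [write_speckle_video()] or any
#'   multi-page grayscale TIFF.
#' @return Array rows x cols x frames.
#' @export
read_speckle_frames <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  arr
}

#' Generate a fixture dataset of simulated recordings
#'
#' Writes one video per (glucose level, replicate) in both field-on and
#' field-off variants, emulating a session in which the speckle patterns are
#' recorded several times in a row for each reference glucose level under
#' both conditions.
#'
#' @param protocol_template A [simulation_protocol()] whose glucose level,
#'   field flag and seed are overridden per video.
#' @param reference_table Data frame with a `glucose_level` column (mg/dl).
#' @param videos_per_level Replicates per level per field condition; >= 1.
#' @param out_dir Output directory (created if missing).
#' @param motion A [motion_model()].
#' @param seed Master seed; every video seed derives from it.
#' @param dry_run If `TRUE`, return the manifest without writing files.
#' @return The manifest data frame (path, glucose_level, field_on, seed),
#'   also written to `manifest.csv` in `out_dir` unless `dry_run`.
#' @export
generate_fixture_dataset <- function(protocol_template, reference_table,
                                     videos_per_level, out_dir,
                                     motion = motion_model(), seed = 1,
                                     dry_run = FALSE) {
  stopifnot(inherits(protocol_template, "simulation_protocol"))
  if (!is.data.frame(reference_table) || nrow(reference_table) == 0 ||
      !"glucose_level" %in% names(reference_table)) {
    stop_invalid("`reference_table` must be a non-empty data frame with a glucose_level column")
  }
  if (videos_per_level < 1) stop_invalid("`videos_per_level` must be >= 1")
  levels <- reference_table$glucose_level
  grid <- expand.grid(replicate = seq_len(videos_per_level),
                      glucose_level = levels,
                      field_on = c(TRUE, FALSE))
  grid$seed <- vapply(seq_len(nrow(grid)),
                      function(i) derive_seed(seed, i), numeric(1))
  grid$path <- file.path(out_dir, sprintf(
    "speckle_g%03d_%s_rep%02d.tiff", round(grid$glucose_level),
    ifelse(grid$field_on, "fieldon", "fieldoff"), grid$replicate))
  manifest <- grid[, c("path", "glucose_level", "field_on", "seed")]
  if (dry_run) return(manifest)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir)
    }
  }
  for (i in seq_len(nrow(manifest))) {
    p <- protocol_template
    p$glucose_level <- manifest$glucose_level[i]
    p$field_on <- manifest$field_on[i]
    p$seed <- manifest$seed[i]
    video <- simulate_recording(p, motion)
    write_speckle_video(video, manifest$path[i])
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
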