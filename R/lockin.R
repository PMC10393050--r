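# Frequency-domain lock-in extraction: transform a displacement time series
# with the FFT, keep only the bins around the magnetic drive frequency
# (with their conjugate mirrors, so the output stays real), and invert. The
# retained band carries the glucose-modulated component; everything else —
# pulse, drift, broadband noise — is rejected.

# Zero-based FFT bin indices (and their conjugate mirrors) retained for a
# band of +/- `bandwidth_bins` around the bin nearest `center_frequency`.
lockin_band_bins <- function(n, fs, center_frequency, bandwidth_bins) {
  k0 <- round(center_frequency * n / fs)
  k <- (k0 - bandwidth_bins):(k0 + bandwidth_bins)
  k <- k[k >= 1 & k <= floor(n / 2)]
  if (length(k) == 0) stop_invalid("retained band is empty for this series length")
  mirrors <- (n - k) %% n
  sort(unique(c(k, mirrors[mirrors != 0])))
}

#' Lock-in filter a time series at the drive frequency
#'
#' Forward FFT, zero every bin except those within `bandwidth_bins` of the
#' bin nearest `center_frequency` (conjugate mirrors always retained
#' together), inverse FFT. The output is a real series containing variation
#' only in the retained narrow band; the filter is a linear idempotent
#' projection. DC is always excluded.
#'
#' @param series Real numeric vector, length >= 4.
#' @param fs Sampling frequency (Hz) of the series.
#' @param center_frequency Drive frequency (Hz); must lie in (0, fs / 2).
#' @param bandwidth_bins Retained bins each side of the centre bin
#'   (default 1, tolerating drive-frequency jitter of one bin).
#' @return A `lockin_series`: list with `signal` (same length as the input),
#'   `center_frequency`, `bandwidth_bins` and `band_energy_fraction` (energy
#'   retained / total AC energy).
#' @export
lockin_filter <- function(series, fs, center_frequency = 140,
                          bandwidth_bins = 1) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 4) stop_invalid("`series` must have length >= 4")
  if (any(!is.finite(series))) stop_invalid("`series` must be finite")
  check_finite_scalar(fs, "fs")
  check_finite_scalar(center_frequency, "center_frequency")
  if (center_frequency <= 0 || center_frequency >= fs / 2) {
    stop_invalid("Nyquist error: `center_frequency` must lie in (0, fs/2)")
  }
  keep <- lockin_band_bins(n, fs, center_frequency, bandwidth_bins)
  x <- stats::fft(series)
  mask <- rep(FALSE, n)
  mask[keep + 1] <- TRUE
  ac_energy <- sum(Mod(x[-1])^2)
  band_energy <- sum(Mod(x[mask])^2)
  x[!mask] <- 0
  signal <- Re(stats::fft(x, inverse = TRUE) / n)
  structure(list(signal = signal, center_frequency = center_frequency,
                 bandwidth_bins = bandwidth_bins,
                 band_energy_fraction = if (ac_energy > 0) band_energy / ac_energy else 0),
            class = "lockin_series")
}

#' Fraction of AC energy inside a frequency band
#'
#' Parseval-based diagnostic: the ratio of spectral energy within
#' `bandwidth_hz` of the centre frequency to the total AC (non-DC) energy.
#' Field-on recordings concentrate displacement energy at the drive
#' frequency; field-off recordings do not.
#'
#' @param series Real numeric vector, length >= 4, with non-zero AC energy.
#' @param fs Sampling frequency (Hz).
#' @param center_frequency Band centre (Hz), in (0, fs / 2).
#' @param bandwidth_hz Half-width of the band (Hz).
#' @return Fraction in [0, 1].
#' @export
band_energy_fraction <- function(series, fs, center_frequency = 140,
                                 bandwidth_hz = fs / length(series)) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 4) stop_invalid("`series` must have length >= 4")
  check_finite_scalar(bandwidth_hz, "bandwidth_hz")
  if (center_frequency <= 0 || center_frequency >= fs / 2) {
    stop_invalid("Nyquist error: `center_frequency` must lie in (0, fs/2)")
  }
  if (stats::sd(series) == 0) {
    stop_invalid("degenerate input: series has zero AC energy")
  }
  x <- stats::fft(series)
  k <- 1:(n - 1)
  freq <- k * fs / n
  freq <- pmin(freq, fs - freq)  # alias to [0, fs/2]
  energy <- Mod(x[k + 1])^2
  total <- sum(energy)
  sum(energy[abs(freq - center_frequency) <= bandwidth_hz]) / total
}

#' Normalize a series
#'
#' `zscore` maps to mean 0, sd 1 (sample sd); `minmax` maps to [0, 1]. A
#' constant series has no z-score and raises a degenerate-input error; under
#' `minmax` it maps to all zeros.
#'
#' @param series Numeric vector.
#' @param method `"zscore"` or `"minmax"`.
#' @return Normalized numeric vector.
#' @export
normalize_series <- function(series, method = c("zscore", "minmax")) {
  method <- match.arg(method)
  series <- as.numeric(series)
  if (any(!is.finite(series))) stop_invalid("`series` must be finite")
  if (method == "zscore") {
    s <- stats::sd(series)
    if (!is.finite(s) || s == 0) {
      stop_invalid("degenerate input: constant series has no z-score")
    }
    (series - mean(series)) / s
  } else {
    rng <- range(series)
    if (rng[2] == rng[1]) return(rep(0, length(series)))
    (series - rng[1]) / (rng[2] - rng[1])
  }
}
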