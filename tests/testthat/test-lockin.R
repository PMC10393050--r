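test_that("commensurate drive tone passes through the lock-in unchanged", {
  t <- (0:2499) / 500
  x <- sin(2 * pi * 140 * t)  # bin 700 of 2500 exactly
  out <- lockin_filter(x, 500, 140, 1)
  expect_lt(max(abs(out$signal - x)) / max(abs(x)), 1e-9)
  expect_equal(out$band_energy_fraction, 1, tolerance = 1e-9)
})

test_that("lock-in isolates the drive component from a mixture", {
  t <- (0:2499) / 500
  drive <- sin(2 * pi * 140 * t)
  x <- drive + sin(2 * pi * 30 * t)
  out <- lockin_filter(x, 500, 140, 1)
  expect_lt(max(abs(out$signal - drive)) / max(abs(drive)), 1e-9)
  # constant series -> all-zero output (DC always excluded)
  out0 <- lockin_filter(rep(3.7, 100), 500, 140, 1)
  expect_equal(out0$signal, rep(0, 100), tolerance = 1e-12)
})

test_that("lock-in output is spectrally pure and the filter is idempotent", {
  set.seed(21)
  x <- rnorm(1000)
  out <- lockin_filter(x, 500, 140, 1)
  # off-band energy after filtering below 1e-10 of output energy
  spec <- Mod(stats::fft(out$signal))^2
  keep <- speckleglucose:::lockin_band_bins(1000, 500, 140, 1) + 1
  expect_lt(sum(spec[-keep]) / sum(spec[keep]), 1e-10)
  # linear idempotent projection
  twice <- lockin_filter(out$signal, 500, 140, 1)
  expect_equal(twice$signal, out$signal, tolerance = 1e-10)
  # linearity
  y <- rnorm(1000)
  lx <- lockin_filter(x, 500, 140, 1)$signal
  ly <- lockin_filter(y, 500, 140, 1)$signal
  lxy <- lockin_filter(2 * x + 3 * y, 500, 140, 1)$signal
  expect_equal(lxy, 2 * lx + 3 * ly, tolerance = 1e-9)
  expect_error(lockin_filter(x, 500, 260, 1), "Nyquist")
  expect_error(lockin_filter(c(1, 2), 500, 140), "length")
})

test_that("band energy fraction behaves as a Parseval ratio", {
  t <- (0:999) / 500
  in_band <- sin(2 * pi * 140 * t)
  expect_equal(band_energy_fraction(in_band, 500, 140, 1), 1, tolerance = 1e-9)
  out_band <- sin(2 * pi * 55 * t)
  expect_lt(band_energy_fraction(out_band, 500, 140, 5), 0.01)
  set.seed(22)
  noise <- rnorm(1000)
  expect_equal(band_energy_fraction(noise, 500, 140, 250), 1, tolerance = 1e-12)
  f <- band_energy_fraction(noise, 500, 140, 3)
  expect_gte(f, 0); expect_lte(f, 1)
  expect_error(band_energy_fraction(rep(1, 100), 500, 140, 1), "degenerate")
})

test_that("series normalization has the stated ranges and moments", {
  z <- normalize_series(c(1, 2, 3), "zscore")
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(normalize_series(c(0, 5, 10), "minmax"), c(0, 0.5, 1))
  x <- rnorm(50)
  expect_equal(normalize_series(normalize_series(x, "zscore"), "zscore"),
               normalize_series(x, "zscore"), tolerance = 1e-12)
  expect_error(normalize_series(rep(2, 10), "zscore"), "degenerate")
})

test_that("field-on recordings concentrate more energy at the drive frequency", {
  frac <- function(field_on, seed) {
    p <- simulation_protocol(frame_size = 32, fps = 500, duration = 0.5,
                             glucose_level = 146, field_on = field_on,
                             seed = seed)
    ds <- track_video(simulate_recording(p), "sequential")
    mean(c(band_energy_fraction(ds$dx, 500, 140, 3),
           band_energy_fraction(ds$dy, 500, 140, 3)))
  }
  on_mean <- mean(vapply(1:3, function(s) frac(TRUE, s), numeric(1)))
  off_mean <- mean(vapply(1:3, function(s) frac(FALSE, s), numeric(1)))
  expect_gt(on_mean, off_mean)
})
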