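test_that("cross-correlation surface is normalized and peaks correctly", {
  a <- simulate_speckle_field(64, 4, seed = 1)
  surf <- cross_correlate(a, a)
  expect_equal(surf[1, 1], 1, tolerance = 1e-10)
  expect_lte(max(surf), 1 + 1e-10)
  # lag (0,0) equals the Pearson correlation for any frame pair
  b <- simulate_speckle_field(64, 4, seed = 2)
  expect_equal(cross_correlate(a, b)[1, 1], cor(as.numeric(a), as.numeric(b)),
               tolerance = 1e-10)
  # independent fields: whole surface small
  expect_lt(max(abs(cross_correlate(a, b))), 0.2)
  expect_error(cross_correlate(a, matrix(1, 64, 64)), "constant")
  expect_error(cross_correlate(a, b[1:32, 1:32]), "equal shapes")
})

test_that("integer circular shifts are recovered exactly", {
  a <- simulate_speckle_field(64, 4, seed = 3)
  for (sh in list(c(3, -2), c(0, 5), c(-7, -1))) {
    b <- a[(seq_len(64) - 1 - sh[2]) %% 64 + 1, (seq_len(64) - 1 - sh[1]) %% 64 + 1]
    est <- estimate_shift(cross_correlate(a, b), subpixel = FALSE)
    expect_equal(est$dx, sh[1])
    expect_equal(est$dy, sh[2])
    expect_equal(est$peak, 1, tolerance = 1e-10)
  }
})

test_that("delta surface gives zero shift with unit peak", {
  surf <- matrix(0, 16, 16)
  surf[1, 1] <- 1
  est <- estimate_shift(surf)
  expect_equal(est$dx, 0)
  expect_equal(est$dy, 0)
  expect_equal(est$peak, 1)
})

test_that("subpixel estimates track the upsampled dense-correlation oracle", {
  errs <- c()
  for (seed in 1:20) {
    a <- simulate_speckle_field(64, 4, seed = seed)
    b <- oracle_fourier_shift(a, 0.5, -0.5)
    surf <- cross_correlate(a, b)
    est <- estimate_shift(surf)
    orc <- oracle_upsampled_peak(surf, factor = 16)
    errs <- c(errs, abs(est$dx - orc$dx), abs(est$dy - orc$dy))
  }
  expect_lt(max(errs), 0.1)
})

test_that("tracking a static noiseless video gives zero series with unit peaks", {
  p <- simulation_protocol(frame_size = 32, fps = 500, duration = 0.05, seed = 4)
  m <- motion_model(glucose_gain = 0, hb_amplitude = 0, pulse_amplitude = 0,
                    drift_step = 0, boiling_rate = 0, noise_std = 0)
  v <- simulate_recording(p, m)
  ds <- track_video(v)
  expect_equal(length(ds$dx), p$frames_per_video - 1)
  expect_equal(ds$dx, rep(0, length(ds$dx)), tolerance = 1e-12)
  expect_equal(ds$dy, rep(0, length(ds$dy)), tolerance = 1e-12)
  expect_equal(ds$peak, rep(1, length(ds$peak)), tolerance = 1e-9)
  expect_error(track_video(v$frames[, , 1, drop = FALSE]), "2 frames")
})

test_that("tracking recovers the injected ground-truth motion", {
  p <- simulation_protocol(frame_size = 64, fps = 500, duration = 0.3,
                           glucose_level = 198, seed = 5)
  m <- motion_model(noise_std = 0, boiling_rate = 0, drift_step = 0)
  v <- simulate_recording(p, m)
  seq_ds <- track_video(v, "sequential")
  err_seq <- sqrt(mean((seq_ds$dx - diff(v$truth$dx))^2 +
                       (seq_ds$dy - diff(v$truth$dy))^2))
  expect_lt(err_seq, 0.05)
  fix_ds <- track_video(v, "fixed_reference")
  err_fix <- sqrt(mean((fix_ds$dx - v$truth$dx[-1])^2 +
                       (fix_ds$dy - v$truth$dy[-1])^2))
  expect_lt(err_fix, 0.05)
  # cumulative sequential shifts approximate fixed-reference shifts
  expect_lt(max(abs(cumsum(seq_ds$dx) - fix_ds$dx)), 0.1)
})

test_that("shift estimation is equivariant under a global integer shift", {
  p <- simulation_protocol(frame_size = 32, fps = 500, duration = 0.05, seed = 6)
  v <- simulate_recording(p, motion_model(noise_std = 0))
  shift_all <- function(frames, sx, sy) {
    out <- frames
    n <- dim(frames)[1]
    for (i in seq_len(dim(frames)[3])) {
      out[, , i] <- frames[(seq_len(n) - 1 - sy) %% n + 1,
                           (seq_len(n) - 1 - sx) %% n + 1, i]
    }
    out
  }
  ds0 <- track_video(v$frames, "fixed_reference")
  ds1 <- track_video(shift_all(v$frames, 4, -3), "fixed_reference")
  # both videos shifted identically: relative series unchanged
  expect_equal(ds1$dx, ds0$dx, tolerance = 1e-8)
  expect_equal(ds1$dy, ds0$dy, tolerance = 1e-8)
  # shifting only the later frames adds the constant offset
  mixed <- v$frames
  mixed[, , -1] <- shift_all(v$frames, 4, -3)[, , -1]
  ds2 <- track_video(mixed, "fixed_reference")
  expect_equal(ds2$dx, ds0$dx + 4, tolerance = 0.05)
  expect_equal(ds2$dy, ds0$dy - 3, tolerance = 0.05)
})

test_that("sequential tracking of field-on fixtures peaks at the drive frequency", {
  for (seed in 1:3) {
    p <- simulation_protocol(frame_size = 32, fps = 500, duration = 1,
                             glucose_level = 198, field_on = TRUE, seed = seed)
    v <- simulate_recording(p)
    ds <- track_video(v, "sequential")
    pg <- oracle_periodogram(ds$dy, p$fps)
    expect_equal(pg$freq[which.max(pg$power)], 140)
  }
})

test_that("displacement series serializes to CSV", {
  p <- simulation_protocol(frame_size = 32, fps = 500, duration = 0.02, seed = 7)
  ds <- track_video(simulate_recording(p))
  path <- tempfile(fileext = ".csv")
  write_displacement_series(ds, path)
  back <- read.csv(path)
  expect_equal(names(back), c("t", "dx", "dy", "peak"))
  expect_equal(back$dx, ds$dx)
  unlink(path)
})
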