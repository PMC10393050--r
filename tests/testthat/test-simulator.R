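test_that("speckle field is deterministic, unit-contrast and seed-decorrelated", {
  f1 <- simulate_speckle_field(128, 4, seed = 3)
  f2 <- simulate_speckle_field(128, 4, seed = 3)
  expect_identical(f1, f2)
  expect_true(all(f1 >= 0))
  # fully developed speckle: contrast (sd/mean) ~ 1
  contrasts <- vapply(1:8, function(s) {
    f <- simulate_speckle_field(256, 4, seed = s)
    sd(f) / mean(f)
  }, numeric(1))
  expect_true(all(abs(contrasts - 1) < 0.1))
  # independent seeds decorrelate
  a <- simulate_speckle_field(128, 4, seed = 1)
  b <- simulate_speckle_field(128, 4, seed = 2)
  expect_lt(max(abs(cross_correlate(a, b))), 0.2)
  expect_error(simulate_speckle_field(64, 64), "smaller")
  expect_error(simulate_speckle_field(64, 0.5), ">= 1")
})

test_that("protocol validation enforces Nyquist and positivity", {
  expect_error(simulation_protocol(fps = 200, drive_frequency = 140), "Nyquist")
  expect_error(simulation_protocol(glucose_level = 0), "> 0")
  p <- simulation_protocol()
  expect_equal(p$frames_per_video, 2501L)
  expect_equal(p$fps, 500)
  expect_equal(p$frame_size, 128L)
  expect_equal(p$drive_frequency, 140)
  expect_equal(p$field_strength, 150)
})

test_that("static scene yields identical frames", {
  p <- simulation_protocol(frame_size = 32, fps = 500, duration = 0.05,
                           glucose_level = 100, seed = 4)
  m <- motion_model(glucose_gain = 0, hb_amplitude = 0, pulse_amplitude = 0,
                    drift_step = 0, boiling_rate = 0, noise_std = 0)
  v <- simulate_recording(p, m)
  for (i in 2:dim(v$frames)[3]) {
    expect_equal(v$frames[, , i], v$frames[, , 1], tolerance = 1e-12)
  }
})

test_that("field-on displacement spectrum peaks at the drive frequency", {
  p <- simulation_protocol(frame_size = 32, fps = 500, duration = 1,
                           glucose_level = 150, field_on = TRUE, seed = 5)
  v <- simulate_recording(p)
  pg <- oracle_periodogram(v$truth$dx, p$fps)
  fs_bin <- p$fps / length(v$truth$dx)
  expect_lt(abs(pg$freq[which.max(pg$power)] - 140), fs_bin)
  # injected amplitude strictly monotone in glucose across the level range
  amp_at <- function(g) {
    pp <- p; pp$glucose_level <- g
    vv <- simulate_recording(pp)
    pg <- oracle_periodogram(vv$truth$dx, p$fps)
    sqrt(sum(pg$power[abs(pg$freq - 140) < 2 * fs_bin]))
  }
  amps <- vapply(reference_levels()$glucose_level, amp_at, numeric(1))
  expect_true(all(diff(amps) > 0))
})

test_that("field-off truth has no drive-frequency line above the noise floor", {
  p <- simulation_protocol(frame_size = 32, fps = 500, duration = 1,
                           glucose_level = 198, field_on = FALSE, seed = 5)
  v <- simulate_recording(p)
  pg <- oracle_periodogram(v$truth$dx, p$fps)
  fs_bin <- p$fps / length(v$truth$dx)
  at_drive <- max(pg$power[abs(pg$freq - 140) < 2 * fs_bin])
  off_band <- median(pg$power[abs(pg$freq - 140) > 5])
  expect_lt(at_drive, 5 * off_band)
})

test_that("recordings are reproducible and carry matching ground truth", {
  p <- simulation_protocol(frame_size = 32, fps = 500, duration = 0.1, seed = 6)
  v1 <- simulate_recording(p)
  v2 <- simulate_recording(p)
  expect_identical(v1$frames, v2$frames)
  expect_identical(v1$truth, v2$truth)
  expect_equal(nrow(v1$truth), p$frames_per_video)
  expect_equal(dim(v1$frames), c(32L, 32L, p$frames_per_video))
  expect_true(all(v1$frames >= 0))
})

test_that("fixture dataset manifest structure and determinism", {
  ref <- reference_levels()
  p <- simulation_protocol(frame_size = 32, fps = 500, duration = 0.05)
  # 13 levels x 5 replicates -> 130 rows per field condition (260 total)
  m1 <- generate_fixture_dataset(p, ref, 5, tempfile("fix"), dry_run = TRUE)
  expect_equal(nrow(m1), 2 * 13 * 5)
  expect_equal(sum(m1$field_on), 13 * 5)
  m2 <- generate_fixture_dataset(p, ref, 5, tempfile("fix"), dry_run = TRUE)
  expect_identical(m1[, c("glucose_level", "field_on", "seed")],
                   m2[, c("glucose_level", "field_on", "seed")])
  # one level, one replicate -> 2 rows, files written and readable
  out <- tempfile("fix1")
  mw <- generate_fixture_dataset(p, ref[1, , drop = FALSE], 1, out, seed = 2)
  expect_equal(nrow(mw), 2)
  expect_true(all(file.exists(mw$path)))
  expect_true(file.exists(file.path(out, "manifest.csv")))
  frames <- read_speckle_frames(mw$path[1])
  expect_equal(dim(frames)[3], p$frames_per_video)
  truth <- read.csv(sub("\\.tiff$", "_truth.csv", mw$path[1]))
  expect_equal(names(truth), c("t", "dx", "dy"))
  unlink(out, recursive = TRUE)
})

test_that("TIFF round trip preserves frame structure", {
  p <- simulation_protocol(frame_size = 32, fps = 500, duration = 0.02, seed = 8)
  v <- simulate_recording(p)
  path <- tempfile(fileext = ".tiff")
  write_speckle_video(v, path)
  back <- read_speckle_frames(path)
  expect_equal(dim(back), dim(v$frames))
  # written frames are globally rescaled; correlation must be ~1
  expect_gt(cor(as.numeric(back), as.numeric(v$frames)), 0.999999)
  unlink(path)
})
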