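test_that("image generator is deterministic and respects its ground truth", {
  spec <- small_scene(n_frames = 6)
  a <- generate_image_sequence(spec, seed = 42)
  b <- generate_image_sequence(spec, seed = 42)
  expect_identical(a$images$frames, b$images$frames)
  c <- generate_image_sequence(spec, seed = 43)
  expect_false(identical(a$images$frames, c$images$frames))

  # no motion: truth rows constant across frames
  flat <- small_scene(n_frames = 5,
                      gait = list(frequency_hz = 1, amplitude_mm = 0, phase_rad = 0),
                      oscillations = list())
  g <- generate_image_sequence(flat, seed = 1)
  for (side in c("superficial", "deep")) {
    expect_equal(apply(g$scene$landmark_truth[[side]], 2, function(col) max(col) - min(col)),
                 rep(0, 19))
  }

  # single 8 Hz / 1 mm component: truth displacement is the exact sinusoid
  osc <- small_scene(n_frames = 100,
                     gait = list(frequency_hz = 1, amplitude_mm = 0, phase_rad = 0),
                     oscillations = list(list(frequency_hz = 8, amplitude_mm = 1,
                                              phase_rad = 0.3)))
  g2 <- generate_image_sequence(osc, seed = 2)
  t <- g2$scene$timestamps
  expect_equal(g2$scene$displacement_mm, sin(2 * pi * 8 * t + 0.3), tolerance = 1e-12)
  # and the truth landmark rows move by exactly -displacement/mm_per_px
  dy <- g2$scene$landmark_truth$superficial[, 10] -
    g2$scene$landmark_truth$superficial[1, 10]
  expect_equal(dy, -(g2$scene$displacement_mm - g2$scene$displacement_mm[1]) /
                 osc$mm_per_px_y, tolerance = 1e-12)
})

test_that("scene validation rejects impossible geometry", {
  expect_error(scene_spec(width_px = 500), "19 landmarks")
  expect_error(scene_spec(oscillations = list(list(frequency_hz = 50, amplitude_mm = 1,
                                                   phase_rad = 0))), "Nyquist")
  # crossing boundaries
  crossed <- small_scene(n_frames = 2)
  crossed$deep$c0 <- 90
  expect_error(generate_image_sequence(crossed, seed = 1), "strictly below")
  # boundary exits the image
  big <- small_scene(n_frames = 4,
                     gait = list(frequency_hz = 1.3, amplitude_mm = 40, phase_rad = 0))
  expect_error(generate_image_sequence(big, seed = 1), "exit the image")
})

test_that("deep boundary stays below superficial in generated scenes", {
  for (seed in 1:3) {
    spec <- small_scene(n_frames = 8,
                        oscillations = list(list(frequency_hz = 5 + seed,
                                                 amplitude_mm = 1.5, phase_rad = seed)))
    g <- generate_image_sequence(spec, seed = seed)
    expect_true(all(g$scene$landmark_truth$deep > g$scene$landmark_truth$superficial))
  }
})

test_that("image, trace and landmark files round-trip", {
  spec <- small_scene(n_frames = 3)
  g <- generate_image_sequence(spec, seed = 9)
  tf <- withr::local_tempfile(fileext = ".tif")
  write_image_sequence(g$images, tf)
  back <- read_image_sequence(tf)
  expect_identical(back$frames, g$images$frames)
  expect_equal(back$frame_rate_hz, g$images$frame_rate_hz)
  expect_equal(back$mm_per_px_y, g$images$mm_per_px_y)

  ftr <- generate_force_trace("running", noise_sd_N = 5, seed = 4)
  cf <- withr::local_tempfile(fileext = ".csv")
  write_trace(ftr, cf)
  ftr2 <- read_trace(cf, "force")
  expect_equal(ftr2$values, ftr$values, tolerance = 1e-12)
  expect_equal(ftr2$sampling_rate_hz, ftr$sampling_rate_hz, tolerance = 1e-9)

  lmf <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(g$scene$landmark_truth$superficial, lmf)
  lm <- read_landmarks(lmf)
  expect_equal(lm$y, unname(g$scene$landmark_truth$superficial), tolerance = 1e-12)
  expect_equal(lm$x_columns, standard_columns())
})

test_that("force generator encodes the quarter-wave interval by construction", {
  for (f in c(8, 15, 22)) {
    tr <- generate_force_trace("running", stance_duration_s = 4 / f + 0.06,
                               impact_frequency_hz = f)
    expect_equal(tr$truth$impact_peak_time_s - tr$truth$max_rfd_time_s, 1 / (4 * f),
                 tolerance = 1e-12)
  }
  tw <- generate_force_trace("walking", stance_duration_s = 0.7, impact_frequency_hz = 10)
  expect_equal(tw$truth$impact_peak_time_s - tw$truth$max_rfd_time_s, 1 / 40,
               tolerance = 1e-12)

  # parameter validation
  expect_error(generate_force_trace("running", impact_frequency_hz = 1), "\\(2, 100\\)")
  expect_error(generate_force_trace("running", stance_duration_s = 0.2,
                                    impact_frequency_hz = 10), "must exceed")
})

test_that("zero impact amplitude leaves the active peak as the first maximum", {
  tr <- generate_force_trace("running", stance_duration_s = 0.45,
                             impact_frequency_hz = 10, impact_amplitude_N = 0,
                             active_peak_N = 1500)
  v <- tr$values
  # first local maximum of the whole trace is the global (active) peak
  local_max <- which(diff(sign(diff(v))) < 0) + 1L
  expect_equal(v[local_max[1]], max(v), tolerance = 1e-9)
})

test_that("EMG generator is deterministic, band-limited and envelope-true", {
  a <- generate_emg_trace(1, list(c(0.2, 0.8)), seed = 5)
  b <- generate_emg_trace(1, list(c(0.2, 0.8)), seed = 5)
  expect_identical(a$values, b$values)
  expect_lt(abs(mean(a$values)), 1e-8)

  expect_warning(sil <- generate_emg_trace(0.5, list(), seed = 1), "silent")
  expect_equal(max(abs(sil$values)), 0)

  expect_error(generate_emg_trace(1, list(c(0, 1)), band_hz = c(20, 1100)), "within")

  # artifact stays below 10 Hz and its power lands in low frequencies only
  art <- generate_emg_trace(2, list(c(0.5, 1.5)), artifact = list(frequency_hz = 4,
                                                                  amplitude = 2), seed = 6)
  base <- generate_emg_trace(2, list(c(0.5, 1.5)), seed = 6)
  dif <- art$values - base$values
  X <- Mod(stats::fft(dif))^2
  f <- (seq_along(dif) - 1) * 2000 / length(dif)
  low <- sum(X[f < 10 | f > 2000 - 10])
  expect_gt(low / sum(X), 0.99)
  expect_error(generate_emg_trace(1, list(c(0, 1)),
                                  artifact = list(frequency_hz = 20, amplitude = 1)),
               "below 10 Hz")
})
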