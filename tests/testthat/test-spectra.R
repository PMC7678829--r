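test_that("transverse displacement applies the sign convention once", {
  standing <- landmark_shape(rep(200, 19))
  y <- matrix(200, 8, 19)
  traj <- y
  d0 <- transverse_displacement(y, standing, mm_per_px_y = 50 / 512,
                                stance_metadata = list(frame_rate_hz = 80))
  expect_equal(max(abs(d0$displacement_mm)), 0)

  # +10.24 px deeper at 0.0977 mm/px is -1.0 mm (deep)
  y2 <- y; y2[, 5] <- 200 + 10.24
  d2 <- transverse_displacement(y2, standing, mm_per_px_y = 0.0977,
                                stance_metadata = list(frame_rate_hz = 80))
  expect_equal(d2$displacement_mm[1, 5], -1.0, tolerance = 1e-3)

  # column mismatch is an error
  odd <- landmark_shape(rep(200, 19), x_columns = standard_columns() + 1)
  spec <- small_scene(n_frames = 6)
  g <- generate_image_sequence(spec, seed = 2)
  m <- train_from_truth(g, label_every = 2)
  tr <- segment_sequence(m, g$images)
  expect_error(transverse_displacement(tr, odd), "columns")
})

test_that("stride-frequency high-pass matches the Butterworth oracle", {
  fs <- 80
  n <- 400
  t <- (0:(n - 1)) / fs
  mk <- function(v) {
    structure(list(displacement_mm = matrix(v, ncol = 1), frame_rate_hz = fs,
                   x_columns = 16, metadata = list()), class = "displacement_set")
  }
  # constant input is rejected to well below 0.1% of its level
  hp <- highpass_stride(mk(rep(3.3, n)), 2.6)
  expect_lt(max(abs(hp$displacement_mm[50:350, 1])), 3.3e-3)
  # 20 Hz passes within 2%
  hp20 <- highpass_stride(mk(sin(2 * pi * 20 * t)), 2.6)
  amp <- (max(hp20$displacement_mm[50:350, 1]) - min(hp20$displacement_mm[50:350, 1])) / 2
  expect_equal(amp, 1, tolerance = 0.02)
  # 1 Hz at 3.1 Hz cutoff is attenuated below 10%
  hp1 <- highpass_stride(mk(sin(2 * pi * 1 * t)), 3.1)
  expect_lt(max(abs(hp1$displacement_mm[50:350, 1])), 0.1)
  # too-short series names the minimum length
  expect_error(highpass_stride(mk(rep(0, 20)), 2.6), "at least 27")
})

test_that("power spectrum and cumulative frequency follow the closed forms", {
  fs <- 80
  t <- (0:79) / fs  # integer cycles for exact bins
  for (a in c(1, 2.5)) {
    s <- power_spectrum(a * sin(2 * pi * 8 * t), fs)
    expect_equal(s$peak_power_mm2, a^2 / 2, tolerance = 1e-9)
    peak_f <- s$frequencies_hz[which.max(s$power_mm2)]
    expect_equal(peak_f, 8)
    expect_lt(abs(s$cumulative_frequency_hz - 8), fs / length(t))
  }
  # doubling amplitude multiplies power by 4, cumulative frequency unchanged
  s1 <- power_spectrum(sin(2 * pi * 8 * t), fs)
  s2 <- power_spectrum(2 * sin(2 * pi * 8 * t), fs)
  expect_equal(s2$power_mm2, 4 * s1$power_mm2, tolerance = 1e-12)
  expect_equal(s2$cumulative_frequency_hz, s1$cumulative_frequency_hz, tolerance = 1e-12)

  # two equal-power components: matches the brute-force cumulative oracle
  x <- sin(2 * pi * 6 * t) + sin(2 * pi * 14 * t + 0.7)
  s3 <- power_spectrum(x, fs)
  expect_equal(s3$cumulative_frequency_hz,
               cf50_oracle(s3$frequencies_hz, s3$power_mm2), tolerance = 1e-12)
  expect_gt(s3$cumulative_frequency_hz, 6)
  expect_lt(s3$cumulative_frequency_hz, 14)

  # all-zero series: flagged, cumulative frequency 0
  s0 <- power_spectrum(rep(0, 64), fs)
  expect_true(s0$zero_spectrum)
  expect_equal(s0$cumulative_frequency_hz, 0)
  expect_equal(max(s0$power_mm2), 0)
})

test_that("cumulative frequency is scale-invariant and monotone in power share", {
  fs <- 80
  t <- (0:159) / fs
  base <- sin(2 * pi * 6 * t)
  cfs <- vapply(c(0.3, 0.6, 1, 1.8, 3), function(a2) {
    power_spectrum(base + a2 * sin(2 * pi * 14 * t), fs)$cumulative_frequency_hz
  }, numeric(1))
  expect_true(all(diff(cfs) > 0))
  # positive rescaling leaves the cumulative frequency untouched
  s <- power_spectrum(base + 0.6 * sin(2 * pi * 14 * t), fs)
  s_scaled <- power_spectrum(17 * (base + 0.6 * sin(2 * pi * 14 * t)), fs)
  expect_equal(s_scaled$cumulative_frequency_hz, s$cumulative_frequency_hz,
               tolerance = 1e-12)
})

test_that("region assignment groups landmarks 2-6, 8-12, 14-18 (1-based)", {
  fs <- 80
  t <- (0:63) / fs
  sums <- lapply(0:18, function(j) {
    power_spectrum((1 + j / 10) * sin(2 * pi * 8 * t), fs, landmark = j)
  })
  out <- assign_regions(sums)
  regions <- vapply(out$summaries, function(s) s$region, character(1))
  expect_equal(sum(regions == "distal"), 5)
  expect_equal(sum(regions == "mid"), 5)
  expect_equal(sum(regions == "proximal"), 5)
  expect_equal(sum(regions == "none"), 4)
  # 0-based indices 1-5 / 7-11 / 13-17
  expect_equal(which(regions == "distal") - 1L, 1:5)
  expect_equal(which(regions == "mid") - 1L, 7:11)
  expect_equal(which(regions == "proximal") - 1L, 13:17)
  # region means equal brute-force means over the listed indices
  pk <- vapply(sums, function(s) s$peak_power_mm2, numeric(1))
  expect_equal(out$regions$peak_power_mm2[out$regions$region == "mid"],
               mean(pk[7:11 + 1]), tolerance = 1e-12)
  # identical spectra give identical region means
  same <- lapply(0:18, function(j) power_spectrum(sin(2 * pi * 8 * t), fs, landmark = j))
  rs <- assign_regions(same)$regions
  expect_equal(length(unique(rs$peak_power_mm2)), 1)
  expect_error(assign_regions(sums[1:18]), "19")
})

test_that("stance resampling interpolates linearly onto 100 points", {
  const <- matrix(2.5, 37, 3)
  expect_equal(resample_stance(const), matrix(2.5, 100, 3))
  ramp <- matrix(seq(0, 1, length.out = 50), 50, 1)
  r <- resample_stance(ramp)
  expect_equal(r[1, 1], 0)
  expect_equal(r[100, 1], 1)
  expect_equal(r[, 1], seq(0, 1, length.out = 100), tolerance = 1e-12)
  # gait-band sinusoid at the ~80 Hz native rate: linear-interpolation
  # error stays below 2% of amplitude (bound (2 pi f / fs)^2 / 8)
  fs <- 80
  t <- (0:59) / fs
  x <- matrix(sin(2 * pi * 4 * t), ncol = 1)
  rs <- resample_stance(x)
  t_out <- seq(t[1], t[length(t)], length.out = 100)
  expect_lt(max(abs(rs[, 1] - sin(2 * pi * 4 * t_out))), 0.02)
})
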