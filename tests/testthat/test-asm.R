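test_that("PDM handles degenerate and rank-1 training sets", {
  same <- lapply(1:4, function(i) landmark_shape(rep(120, 19)))
  pdm <- build_pdm(same)
  expect_equal(pdm$n_modes, 0L)
  expect_equal(pdm$mean_shape, c(standard_columns(), rep(120, 19)))
  # constrained reconstruction of anything returns the mean
  out <- pdm_constrain(pdm, c(standard_columns(), rep(300, 19)))
  expect_equal(out$v, pdm$mean_shape)

  # shapes = mean +/- t * v: one mode parallel to v with variance var(t)
  v <- withr::with_seed(11, rnorm(19))
  v <- v / sqrt(sum(v^2))
  tvals <- c(-2, -1, 0.5, 1, 1.5)
  shapes <- lapply(tvals, function(tt) landmark_shape(120 + tt * v))
  pdm1 <- build_pdm(shapes)
  expect_equal(pdm1$n_modes, 1L)
  mode_y <- pdm1$modes[20:38, 1]
  expect_equal(abs(sum(mode_y * v)), 1, tolerance = 1e-10)
  expect_equal(pdm1$variances[1], stats::var(tvals), tolerance = 1e-10)
})

test_that("PDM eigenstructure matches an independent SVD oracle", {
  shapes <- random_shapes(20, seed = 21)
  pdm <- build_pdm(shapes, variance_fraction = 1)
  X <- t(sapply(shapes, function(s) c(s$points[, 1], s$points[, 2])))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  lam_oracle <- sv$d^2 / (nrow(X) - 1)
  nz <- which(lam_oracle > 1e-10)
  expect_equal(pdm$variances[nz], lam_oracle[nz], tolerance = 1e-8)
  for (i in head(nz, 5)) {
    expect_equal(abs(sum(pdm$modes[, i] * sv$v[, i])), 1, tolerance = 1e-8)
  }
})

test_that("PDM projection is idempotent and modes are orthonormal", {
  shapes <- random_shapes(12, seed = 5)
  pdm <- build_pdm(shapes)
  expect_true(all(diff(pdm$variances) <= 1e-12))
  G <- crossprod(pdm$modes)
  expect_equal(G, diag(pdm$n_modes), tolerance = 1e-10)
  v <- shape_to_vec(random_shapes(1, base = 130, seed = 99)[[1]])
  first <- pdm_constrain(pdm, v)
  second <- pdm_constrain(pdm, first$v)
  expect_equal(second$b, first$b, tolerance = 1e-10)
  expect_equal(second$v, first$v, tolerance = 1e-10)
  # clamp property
  expect_true(all(abs(first$b) <= 3 * sqrt(pdm$variances) + 1e-12))
})

test_that("intensity models capture a sharp band and survive degenerate input", {
  # bright horizontal band: mean profile derivative is extremal at the crossing
  spec <- small_scene(n_frames = 4,
                      gait = list(frequency_hz = 1, amplitude_mm = 0, phase_rad = 0),
                      oscillations = list(), speckle_sigma_px = 1.2)
  g <- generate_image_sequence(spec, seed = 3)
  labels <- lapply(0:3, function(f) {
    landmark_shape(g$scene$landmark_truth$superficial[f + 1, ], frame_index = f)
  })
  ipm <- build_intensity_models(g$images, labels, k = 6)
  mu <- ipm$levels[[1]]$mean[10, ]
  # band has a Gaussian cross-section (sigma 3 px), so the intensity
  # derivative is extremal ~3 px either side of the centre sample
  expect_gt(max(abs(mu[4:10])), max(abs(mu[c(1, 2, 12, 13)])))

  # constant image: zero profiles, no NaN from the normalisation guard
  const <- image_sequence(array(100L, dim = c(2, 64, 640)), 80, 0.1, 0.1)
  labs <- list(landmark_shape(rep(32, 19), frame_index = 0L))
  ipm0 <- build_intensity_models(const, labs, k = 4, n_levels = 2)
  expect_true(all(ipm0$levels[[1]]$mean == 0))
  expect_true(all(is.finite(ipm0$levels[[1]]$inv_cov)))

  # single labelled frame: covariance is the epsilon regulariser only
  one <- build_intensity_models(g$images, labels[1], k = 4, n_levels = 1)
  iv <- one$levels[[1]]$inv_cov[1, , ]
  expect_equal(iv, diag(diag(iv)[1], nrow(iv)), tolerance = 1e-6)
})

test_that("fit_shape recovers truth and degrades gracefully", {
  spec <- small_scene(n_frames = 24)
  g <- generate_image_sequence(spec, seed = 13)
  m <- train_from_truth(g, label_every = 6)
  truth <- g$scene$landmark_truth$superficial
  img <- g$images$frames[3, , ]

  # init at truth stays at truth
  r <- fit_shape(m, img, landmark_shape(truth[3, ], frame_index = 2L))
  expect_lt(sqrt(mean((r$shape$points[, 2] - truth[3, ])^2)), 1)
  expect_true(all(abs(r$diagnostics$b) <= 3 * sqrt(m$pdm$variances) + 1e-9))

  # init displaced 10 px: mean absolute transverse error under 1 mm
  r2 <- fit_shape(m, img, landmark_shape(truth[3, ] + 10, frame_index = 2L),
                  n_levels = 5)
  err_mm <- mean(abs(r2$shape$points[, 2] - truth[3, ])) * g$images$mm_per_px_y
  expect_lt(err_mm, 1)

  # zero-mode model returns the mean shape regardless of the image
  pdm0 <- build_pdm(lapply(1:3, function(i) landmark_shape(truth[3, ])))
  m0 <- shape_model(pdm0, m$intensity)
  r0 <- fit_shape(m0, img, landmark_shape(truth[3, ] + 25, frame_index = 2L))
  expect_equal(r0$shape$points[, 2], unname(truth[3, ]), tolerance = 1e-9)
})

test_that("segment_sequence tracks static and oscillating scenes", {
  static <- small_scene(n_frames = 10,
                        gait = list(frequency_hz = 1, amplitude_mm = 0, phase_rad = 0),
                        oscillations = list())
  g <- generate_image_sequence(static, seed = 17)
  m <- train_from_truth(g, label_every = 3)
  traj <- segment_sequence(m, g$images)
  expect_equal(nrow(traj$y), 10)
  expect_lt(max(apply(traj$y, 2, function(col) max(col) - min(col))), 1)

  # single-frame sequence
  one <- image_sequence(g$images$frames[1, , , drop = FALSE], 80,
                        g$images$mm_per_px_x, g$images$mm_per_px_y)
  t1 <- segment_sequence(m, one)
  expect_equal(nrow(t1$y), 1)

  # oscillating scene: recovered displacement correlates > 0.95 with truth
  osc <- small_scene(n_frames = 48)
  go <- generate_image_sequence(osc, seed = 19)
  mo <- train_from_truth(go, label_every = 8)
  to <- segment_sequence(mo, go$images)
  truth_d <- go$scene$landmark_truth$superficial[, 10]
  expect_gt(stats::cor(to$y[, 10], truth_d), 0.95)

  # landmark cardinality and spacing in every frame
  expect_equal(ncol(to$y), 19)
  expect_equal(unname(diff(to$x_columns)), rep(32, 18))
})

test_that("shape models persist through the archive round trip", {
  spec <- small_scene(n_frames = 8)
  g <- generate_image_sequence(spec, seed = 23)
  m <- train_from_truth(g, label_every = 4)
  p <- withr::local_tempfile(fileext = ".rds")
  write_shape_model(m, p)
  m2 <- read_shape_model(p)
  expect_equal(m2$pdm$mean_shape, m$pdm$mean_shape)
  expect_equal(m2$intensity$levels[[1]]$mean, m$intensity$levels[[1]]$mean)
  img <- g$images$frames[2, , ]
  init <- landmark_shape(g$scene$landmark_truth$superficial[2, ], frame_index = 1L)
  expect_equal(fit_shape(m2, img, init)$shape$points,
               fit_shape(m, img, init)$shape$points)
})
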