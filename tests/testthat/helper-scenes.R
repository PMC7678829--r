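# Shared fixtures: small synthetic scenes kept cheap enough for unit tests.

small_scene <- function(n_frames = 40, oscillations = list(list(frequency_hz = 8,
                                                                amplitude_mm = 1,
                                                                phase_rad = 0)),
                        gait = list(frequency_hz = 1.3, amplitude_mm = 2, phase_rad = 0),
                        ...) {
  scene_spec(n_frames = n_frames, height_px = 288,
             superficial = list(c0 = 95, c1 = 0.01, c2 = 0),
             deep = list(c0 = 195, c1 = 0.015, c2 = -5e-6),
             gait = gait, oscillations = oscillations, ...)
}

# Train a superficial-aponeurosis model from ground-truth labels.
train_from_truth <- function(gen, side = "superficial", label_every = 8) {
  idx <- seq(0, dim(gen$images$frames)[1] - 1, by = label_every)
  labels <- lapply(idx, function(f) {
    landmark_shape(gen$scene$landmark_truth[[side]][f + 1, ], frame_index = f)
  })
  train_shape_model(gen$images, labels, source_id = paste0("test_", side))
}

# Random valid landmark shapes for PDM tests.
random_shapes <- function(n, base = 120, sd = 8, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) landmark_shape(base + rnorm(19, sd = sd)))
  })
}
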