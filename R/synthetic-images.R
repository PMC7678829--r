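# Synthetic B-mode ultrasound scenes. Two bright curvilinear aponeurosis
# bands (Gaussian cross-section) ride on multiplicative, smoothed
# Rayleigh-distributed speckle. Boundary motion is a prescribed
# low-frequency gait trajectory plus higher-frequency transverse
# oscillation components, so the true landmark positions -- and hence the
# true displacement spectrum -- are known exactly.

#' Standard landmark columns
#'
#' Column (x) pixel coordinates of the 19 evenly-spaced landmarks used for
#' aponeurosis segmentation: `x_j = offset + spacing * j`, `j = 0..n-1`
#' (0-based pixel coordinates).
#'
#' @param n number of landmarks (default 19).
#' @param spacing pixel spacing between landmarks (default 32).
#' @param offset column of the first landmark (default 16).
#' @return numeric vector of column coordinates.
#' @export
standard_columns <- function(n = 19L, spacing = 32L, offset = 16L) {
  offset + spacing * (seq_len(n) - 1L)
}

#' Describe a synthetic ultrasound scene
#'
#' Collects the geometric and textural parameters of a synthetic scene.
#' Each aponeurosis boundary is a quadratic curve
#' `row = c0 + c1 * col + c2 * col^2` (0-based pixel coordinates, row
#' increasing with depth). Both boundaries translate vertically with a
#' shared trajectory: a low-frequency gait component plus any number of
#' oscillation components `(frequency_hz, amplitude_mm, phase_rad)`.
#' Positive displacement is superficial (toward the skin, smaller row).
#'
#' @param width_px,height_px image size in pixels; width must fit the 19
#'   standard landmark columns (>= 608 px at the default spacing).
#' @param n_frames number of frames.
#' @param frame_rate_hz frame rate (default 80).
#' @param mm_per_px_x,mm_per_px_y physical pixel scale; defaults map the
#'   608 x 512 px image to a 60 x 50 mm field of view.
#' @param superficial,deep lists with `c0`, `c1`, `c2` boundary coefficients.
#' @param gait list `(frequency_hz, amplitude_mm, phase_rad)` for the gross
#'   gait trajectory; amplitude 0 disables it.
#' @param oscillations list of `(frequency_hz, amplitude_mm, phase_rad)`
#'   transverse oscillation components; all must be below Nyquist.
#' @param band_sigma_px Gaussian cross-section half-width of the bright
#'   bands, in px.
#' @param band_intensity,background_intensity 8-bit intensity of the bands
#'   and of the speckle background floor.
#' @param speckle_sigma_px smoothing of the Rayleigh speckle field.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(width_px = 608L, height_px = 512L, n_frames = 100L,
                       frame_rate_hz = 80,
                       mm_per_px_x = 60 / 608, mm_per_px_y = 50 / 512,
                       superficial = list(c0 = 160, c1 = 0.01, c2 = 0),
                       deep = list(c0 = 330, c1 = 0.02, c2 = -1e-5),
                       gait = list(frequency_hz = 1.3, amplitude_mm = 3, phase_rad = 0),
                       oscillations = list(list(frequency_hz = 8, amplitude_mm = 1, phase_rad = 0)),
                       band_sigma_px = 3, band_intensity = 170,
                       background_intensity = 35, speckle_sigma_px = 1.2) {
  cols <- standard_columns()
  if (width_px < max(cols) + 16) {
    stop(sprintf("image width %d px cannot fit 19 landmarks at 32 px spacing (need >= %d px)",
                 width_px, max(cols) + 16))
  }
  stopifnot(frame_rate_hz > 0, n_frames >= 1, mm_per_px_x > 0, mm_per_px_y > 0)
  for (comp in oscillations) {
    if (comp$frequency_hz >= frame_rate_hz / 2) {
      stop(sprintf("oscillation component at %g Hz is at or above Nyquist (%g Hz)",
                   comp$frequency_hz, frame_rate_hz / 2))
    }
  }
  structure(list(width_px = as.integer(width_px), height_px = as.integer(height_px),
                 n_frames = as.integer(n_frames), frame_rate_hz = frame_rate_hz,
                 mm_per_px_x = mm_per_px_x, mm_per_px_y = mm_per_px_y,
                 superficial = superficial, deep = deep, gait = gait,
                 oscillations = oscillations, band_sigma_px = band_sigma_px,
                 band_intensity = band_intensity,
                 background_intensity = background_intensity,
                 speckle_sigma_px = speckle_sigma_px),
            class = "scene_spec")
}

# Shared vertical displacement trajectory in mm (positive = superficial).
scene_displacement_mm <- function(spec, t) {
  d <- rep(0, length(t))
  g <- spec$gait
  if (!is.null(g) && g$amplitude_mm != 0) {
    d <- d + g$amplitude_mm * sin(2 * pi * g$frequency_hz * t + g$phase_rad)
  }
  for (comp in spec$oscillations) {
    d <- d + comp$amplitude_mm * sin(2 * pi * comp$frequency_hz * t + comp$phase_rad)
  }
  d
}

#' Generate a synthetic ultrasound image sequence
#'
#' Renders the scene described by a [scene_spec()]: per frame, a Rayleigh
#' speckle field is smoothed and applied multiplicatively to the sum of a
#' background floor and the two Gaussian-profile aponeurosis bands, then
#' quantised to 8 bits. The returned ground truth holds the exact boundary
#' curves, the injected displacement trajectory and the true landmark rows
#' at the 19 standard columns.
#'
#' @param spec a [scene_spec()].
#' @param seed integer seed; the same seed reproduces the pixel data
#'   bit-exactly.
#' @return list with elements `images` (an `image_sequence`) and `scene`
#'   (a `ground_truth_scene`).
#' @export
generate_image_sequence <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "scene_spec"))
  w <- spec$width_px; h <- spec$height_px; nf <- spec$n_frames
  cols0 <- 0:(w - 1L)
  t <- (seq_len(nf) - 1L) / spec$frame_rate_hz
  disp_mm <- scene_displacement_mm(spec, t)
  disp_px <- disp_mm / spec$mm_per_px_y          # positive = superficial = smaller row

  base_sup <- spec$superficial$c0 + spec$superficial$c1 * cols0 + spec$superficial$c2 * cols0^2
  base_deep <- spec$deep$c0 + spec$deep$c1 * cols0 + spec$deep$c2 * cols0^2

  margin <- 3 * spec$band_sigma_px
  sup_rows <- outer(-disp_px, rep(1, w)) + outer(rep(1, nf), base_sup)
  deep_rows <- outer(-disp_px, rep(1, w)) + outer(rep(1, nf), base_deep)
  if (any(deep_rows <= sup_rows)) stop("deep boundary must lie strictly below the superficial boundary")
  if (min(sup_rows) < margin || max(deep_rows) > h - 1 - margin) {
    stop("boundary curves exit the image for the requested motion; enlarge the image or reduce amplitudes")
  }

  rows0 <- 0:(h - 1L)
  frames <- array(0L, dim = c(nf, h, w))
  withr::with_seed(as.integer(seed), {
    for (f in seq_len(nf)) {
      # Rayleigh speckle, smoothed, normalised to unit mean -> multiplicative
      ray <- sqrt(-2 * log(runif(h * w)))
      spk <- gaussian_blur(matrix(ray, h, w), spec$speckle_sigma_px)
      spk <- spk / mean(spk)
      band <- spec$band_intensity *
        (exp(-outer(rows0, sup_rows[f, ], "-")^2 / (2 * spec$band_sigma_px^2)) +
         exp(-outer(rows0, deep_rows[f, ], "-")^2 / (2 * spec$band_sigma_px^2)))
      img <- (spec$background_intensity + band) * spk
      frames[f, , ] <- as.integer(pmin.int(pmax.int(round(img), 0), 255))
    }
  })

  xs <- standard_columns()
  truth_sup <- sup_rows[, xs + 1L, drop = FALSE]
  truth_deep <- deep_rows[, xs + 1L, drop = FALSE]

  images <- image_sequence(frames, spec$frame_rate_hz, spec$mm_per_px_x, spec$mm_per_px_y)
  scene <- structure(list(
    spec = spec,
    x_columns = xs,
    displacement_mm = disp_mm,
    timestamps = t,
    landmark_truth = list(superficial = truth_sup, deep = truth_deep),
    oscillation_components = spec$oscillations,
    seed = as.integer(seed)), class = "ground_truth_scene")
  list(images = images, scene = scene)
}

#' Construct an image sequence object
#'
#' @param frames 3-D integer array `(frame, row, column)`, 8-bit range.
#' @param frame_rate_hz frame rate in Hz.
#' @param mm_per_px_x,mm_per_px_y physical pixel scale.
#' @return object of class `image_sequence` with per-frame `timestamps`.
#' @export
image_sequence <- function(frames, frame_rate_hz, mm_per_px_x, mm_per_px_y) {
  stopifnot(length(dim(frames)) == 3, frame_rate_hz > 0,
            mm_per_px_x > 0, mm_per_px_y > 0)
  if (min(frames) < 0 || max(frames) > 255) stop("frame intensities must lie in the 8-bit range 0..255")
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 mm_per_px_x = mm_per_px_x, mm_per_px_y = mm_per_px_y,
                 timestamps = (seq_len(dim(frames)[1]) - 1L) / frame_rate_hz),
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_sequence: %d frames of %d x %d px at %.3g Hz (%.3g x %.3g mm/px)\n",
              d[1], d[2], d[3], x$frame_rate_hz, x$mm_per_px_x, x$mm_per_px_y))
  invisible(x)
}

n_frames <- function(images) dim(images$frames)[1]
get_frame <- function(images, f) images$frames[f, , ]

#' Write / read an image sequence as multi-page TIFF plus YAML sidecar
#'
#' The 8-bit grayscale frames go to a multi-page TIFF; frame rate and pixel
#' scale go to `<path>.yml`. The round trip is bit-exact.
#'
#' @param images an `image_sequence`.
#' @param path TIFF file path.
#' @return `write_image_sequence` returns `path` invisibly;
#'   `read_image_sequence` returns an `image_sequence`.
#' @export
write_image_sequence <- function(images, path) {
  stopifnot(inherits(images, "image_sequence"))
  nf <- n_frames(images)
  pages <- lapply(seq_len(nf), function(f) get_frame(images, f) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  yaml::write_yaml(list(frame_rate_hz = images$frame_rate_hz,
                        mm_per_px_x = images$mm_per_px_x,
                        mm_per_px_y = images$mm_per_px_y),
                   paste0(path, ".yml"), precision = 15L)
  invisible(path)
}

#' @rdname write_image_sequence
#' @export
read_image_sequence <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  frames <- array(0L, dim = c(length(pages), h, w))
  for (f in seq_along(pages)) frames[f, , ] <- as.integer(round(pages[[f]] * 255))
  image_sequence(frames, meta$frame_rate_hz, meta$mm_per_px_x, meta$mm_per_px_y)
}

#' Write / read landmark coordinates as CSV
#'
#' CSV columns `frame,point_index,x_px,y_px` with 0-based frame and point
#' indices, matching the training-label and segmentation-output format.
#'
#' @param y matrix `n_frames x 19` of landmark rows (y, px), or a
#'   `landmark_trajectory`.
#' @param x_columns landmark columns (defaults to [standard_columns()]).
#' @param path CSV path.
#' @param frames optional 0-based frame indices (default `0:(nrow-1)`).
#' @return `write_landmarks` returns `path` invisibly; `read_landmarks`
#'   returns a list with `y` (matrix frames x points), `x_columns`, `frames`.
#' @export
write_landmarks <- function(y, path, x_columns = standard_columns(), frames = NULL) {
  if (inherits(y, "landmark_trajectory")) {
    x_columns <- y$x_columns
    y <- y$y
  }
  if (is.null(frames)) frames <- 0:(nrow(y) - 1L)
  df <- data.frame(frame = rep(frames, each = ncol(y)),
                   point_index = rep(0:(ncol(y) - 1L), nrow(y)),
                   x_px = rep(x_columns, nrow(y)),
                   y_px = as.vector(t(y)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("frame", "point_index", "x_px", "y_px") %in% names(df)))
  frames <- sort(unique(df$frame))
  pts <- sort(unique(df$point_index))
  y <- matrix(NA_real_, length(frames), length(pts))
  idx <- cbind(match(df$frame, frames), df$point_index + 1L)
  y[idx] <- df$y_px
  xcol <- df$x_px[match(pts, df$point_index)]
  list(y = y, x_columns = xcol, frames = frames)
}
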