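# Shared numeric helpers: zero-phase IIR filtering, separable Gaussian
# smoothing, image pyramids and bilinear sampling. These back both the
# synthetic generators and the ASM search, so they live in one place.

#' Zero-phase Butterworth filter
#'
#' Applies a Butterworth filter forward and backward (zero phase lag) with
#' odd-symmetric end extension so that edge transients fall outside the
#' returned samples. Zero-phase filtering is used throughout because timing
#' estimates (impact peaks, displacement phase) must not be lag-shifted.
#'
#' @param x numeric vector.
#' @param cutoff_hz scalar cutoff, or length-2 band for `type = "pass"`.
#' @param fs sampling rate in Hz.
#' @param order filter order (default 4).
#' @param type `"low"`, `"high"` or `"pass"`.
#' @return filtered vector, same length as `x`.
#' @export
zerophase_butter <- function(x, cutoff_hz, fs, order = 4, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  nyq <- fs / 2
  if (any(cutoff_hz >= nyq)) {
    stop(sprintf("cutoff %s Hz must lie below the Nyquist frequency %g Hz",
                 paste(cutoff_hz, collapse = "-"), nyq))
  }
  if (any(cutoff_hz <= 0)) stop("cutoff frequencies must be positive")
  n <- length(x)
  min_n <- 3L * (2L * order + 1L)
  if (n < min_n) {
    stop(sprintf("series of length %d is too short for zero-phase order-%d filtering; need at least %d samples",
                 n, order, min_n))
  }
  flt <- signal::butter(order, cutoff_hz / nyq, type = type)
  pad <- min(min_n, n - 1L)
  head_pad <- 2 * x[1] - x[(pad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(flt, c(head_pad, x, tail_pad))
  y[(pad + 1L):(pad + n)]
}

gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with replicate padding; kernel must be odd-length.
# Implemented as shifted slice accumulation, which vectorises well.
conv_cols <- function(m, kern) {
  r <- (length(kern) - 1L) %/% 2L
  nr <- nrow(m)
  mp <- m[c(rep(1L, r), seq_len(nr), rep(nr, r)), , drop = FALSE]
  out <- kern[1] * mp[seq_len(nr), , drop = FALSE]
  for (j in 2:length(kern)) {
    out <- out + kern[j] * mp[(j - 1L) + seq_len(nr), , drop = FALSE]
  }
  out
}

sep_conv2 <- function(m, kern) {
  t(conv_cols(t(conv_cols(m, kern)), kern))
}

gaussian_blur <- function(m, sigma) sep_conv2(m, gauss_kernel(sigma))

# Coarse-to-fine image pyramid: level 1 is the native image; each further
# level is blurred (sigma = 1 px) and decimated by 2 in both directions.
image_pyramid <- function(m, n_levels) {
  stopifnot(n_levels >= 1)
  pyr <- vector("list", n_levels)
  pyr[[1]] <- m
  for (l in seq_len(n_levels - 1L)) {
    prev <- pyr[[l]]
    sm <- gaussian_blur(prev, 1)
    pyr[[l + 1L]] <- sm[seq(1L, nrow(prev), by = 2L), seq(1L, ncol(prev), by = 2L), drop = FALSE]
  }
  pyr
}

# Bilinear interpolation at 0-based pixel coordinates (x = column, y = row);
# coordinates outside the image are clamped to the edge.
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2L)
  y0 <- pmin(floor(y), nr - 2L)
  fx <- x - x0
  fy <- y - y0
  i <- as.integer(y0) + 1L
  j <- as.integer(x0) + 1L
  img[cbind(i, j)] * (1 - fx) * (1 - fy) +
    img[cbind(i, j + 1L)] * fx * (1 - fy) +
    img[cbind(i + 1L, j)] * (1 - fx) * fy +
    img[cbind(i + 1L, j + 1L)] * fx * fy
}

# Trapezoidal cumulative integral over (possibly non-uniform) grid x.
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum(diff(x) * (y[-n] + y[-1]) / 2))
}
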