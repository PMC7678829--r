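# Point distribution model over the 19-landmark aponeurosis shape.
#
# Shapes are 38-vectors (x_1..x_19, y_1..y_19) in full-resolution pixel
# coordinates. No Procrustes alignment is performed: the absolute position
# of the aponeurosis in the image frame (relative to the skin-mounted
# probe) is the measurand, so translation must remain inside the shape
# space rather than being factored out as pose.

#' Construct a landmark shape
#'
#' @param y numeric vector of 19 landmark rows (y, px).
#' @param x_columns landmark columns; defaults to [standard_columns()].
#' @param frame_index optional 0-based frame index.
#' @return object of class `landmark_shape` with a `points` matrix (19 x 2,
#'   columns `x`, `y`).
#' @export
landmark_shape <- function(y, x_columns = standard_columns(), frame_index = NA_integer_) {
  stopifnot(length(y) == length(x_columns), all(is.finite(y)))
  structure(list(points = cbind(x = as.numeric(x_columns), y = as.numeric(y)),
                 frame_index = frame_index),
            class = "landmark_shape")
}

shape_to_vec <- function(shape) as.numeric(shape$points)
vec_to_shape <- function(v, frame_index = NA_integer_) {
  n <- length(v) %/% 2L
  landmark_shape(v[(n + 1L):(2L * n)], x_columns = v[seq_len(n)], frame_index = frame_index)
}

#' Build a point distribution model from training shapes
#'
#' Stacks the training shapes as 38-vectors, eigendecomposes their
#' covariance, and retains the smallest number of leading modes whose
#' cumulative variance reaches `variance_fraction`. Identical training
#' shapes give a valid degenerate model with zero modes.
#'
#' @param training_shapes list of [landmark_shape()] objects (>= 2).
#' @param variance_fraction fraction of total shape variance to retain
#'   (default 0.98).
#' @return object of class `pdm` with `mean_shape` (38-vector), `modes`
#'   (orthonormal columns), `variances` (descending eigenvalues) and
#'   `n_modes`.
#' @export
build_pdm <- function(training_shapes, variance_fraction = 0.98) {
  stopifnot(length(training_shapes) >= 2,
            variance_fraction > 0, variance_fraction <= 1)
  X <- t(vapply(training_shapes, shape_to_vec,
                numeric(2L * nrow(training_shapes[[1]]$points))))
  mean_shape <- colMeans(X)
  C <- cov(X)
  eig <- eigen(C, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  total <- sum(lambda)
  if (total <= .Machine$double.eps * length(lambda)) {
    n_modes <- 0L
  } else {
    n_modes <- which(cumsum(lambda) / total >= variance_fraction)[1]
  }
  structure(list(mean_shape = mean_shape,
                 modes = eig$vectors[, seq_len(n_modes), drop = FALSE],
                 variances = lambda[seq_len(n_modes)],
                 n_modes = as.integer(n_modes),
                 n_training = nrow(X)),
            class = "pdm")
}

#' Project a shape onto a PDM and reconstruct under the +/- 3 SD constraint
#'
#' Computes mode coefficients `b = P' (x - mean)`, clamps each `b_i` to
#' `[-3 sqrt(lambda_i), +3 sqrt(lambda_i)]`, and reconstructs
#' `x = mean + P b`. With zero modes the mean shape is returned.
#'
#' @param pdm a [build_pdm()] model.
#' @param v shape as a 38-vector.
#' @param n_sd clamp width in standard deviations (default 3).
#' @return list with `v` (reconstructed 38-vector), `b` (clamped
#'   coefficients) and `clamped` (logical per mode).
#' @export
pdm_constrain <- function(pdm, v, n_sd = 3) {
  if (pdm$n_modes == 0L) {
    return(list(v = pdm$mean_shape, b = numeric(0), clamped = logical(0)))
  }
  b <- drop(crossprod(pdm$modes, v - pdm$mean_shape))
  lim <- n_sd * sqrt(pdm$variances)
  clamped <- abs(b) > lim
  b <- pmin(pmax(b, -lim), lim)
  list(v = pdm$mean_shape + drop(pdm$modes %*% b), b = b, clamped = clamped)
}

#' @export
print.pdm <- function(x, ...) {
  cat(sprintf("pdm: %d landmarks, %d training shapes, %d modes (total variance %.4g)\n",
              length(x$mean_shape) / 2, x$n_training, x$n_modes, sum(x$variances)))
  invisible(x)
}
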