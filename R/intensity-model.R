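# Per-landmark intensity-profile statistics for the ASM search.
#
# At each resolution level the image is smoothed and decimated by 2. At
# each landmark the image intensity is sampled along the local boundary
# normal (perpendicular to the line joining the neighbouring landmarks),
# differentiated, and normalised by the sum of absolute values; mean and
# covariance over the labelled frames form a Gaussian profile model whose
# Mahalanobis distance scores candidate positions during search.

# Unit normals per landmark, oriented toward larger row (deeper tissue).
shape_normals <- function(points) {
  n <- nrow(points)
  prev <- points[c(1, seq_len(n - 1L)), , drop = FALSE]
  nxt <- points[c(2:n, n), , drop = FALSE]
  d <- nxt - prev
  len <- sqrt(rowSums(d^2))
  len[len == 0] <- 1
  tx <- d[, 1] / len; ty <- d[, 2] / len
  nx <- -ty; ny <- tx
  flip <- ny < 0
  nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]
  cbind(nx, ny)
}

# Sample the normalised intensity-derivative profile of length 2k+1 at one
# landmark. `pos` in 0-based level coordinates; step 1 px at this level.
# Returns the derivative profile, or all zeros for a flat patch.
sample_profile <- function(img, pos, normal, k) {
  steps <- (-(k + 1L)):(k + 1L)
  xs <- pos[1] + steps * normal[1]
  ys <- pos[2] + steps * normal[2]
  g <- bilinear_sample(img, xs, ys)
  dg <- (g[-(1:2)] - g[seq_len(length(g) - 2L)]) / 2
  s <- sum(abs(dg))
  if (s > 0) dg / s else dg
}

# As above but for the extended search profile: derivative samples at
# offsets -(k+range)..(k+range) so candidate sub-profiles can be sliced.
sample_search_profile <- function(img, pos, normal, k, range) {
  m <- k + range
  steps <- (-(m + 1L)):(m + 1L)
  xs <- pos[1] + steps * normal[1]
  ys <- pos[2] + steps * normal[2]
  g <- bilinear_sample(img, xs, ys)
  (g[-(1:2)] - g[seq_len(length(g) - 2L)]) / 2
}

#' Build multi-resolution intensity-profile models
#'
#' Trains, for each landmark and each resolution level, the mean and
#' covariance of the normalised intensity-gradient profile sampled along
#' the local boundary normal at the labelled landmark positions. The
#' covariance is regularised by adding `epsilon_scale` times its mean
#' diagonal to the diagonal, so single-frame training and flat patches
#' remain well-posed.
#'
#' @param images an [image_sequence()].
#' @param labels list of [landmark_shape()] with valid `frame_index`
#'   (0-based) identifying the labelled frames.
#' @param k profile half-length; profiles have `2k + 1` samples (default 6).
#' @param n_levels number of resolution levels to train (default 5, so the
#'   5-level initial-frame search is available; routine frames use 3).
#' @param epsilon_scale covariance diagonal regulariser (default 1e-6).
#' @return object of class `intensity_profile_model`: per level, per
#'   landmark mean profile, covariance and its inverse; plus `k`,
#'   `n_levels` and a `clamped_landmarks` flag matrix for profiles that
#'   had to be clamped at the image edge.
#' @export
build_intensity_models <- function(images, labels, k = 6L, n_levels = 5L,
                                   epsilon_scale = 1e-6) {
  stopifnot(inherits(images, "image_sequence"), length(labels) >= 1, k >= 3)
  nl <- length(labels)
  np <- nrow(labels[[1]]$points)
  plen <- 2L * k + 1L
  nf <- n_frames(images)
  edge_flag <- matrix(FALSE, np, n_levels)

  profiles <- array(NA_real_, dim = c(n_levels, nl, np, plen))
  for (li in seq_len(nl)) {
    fidx <- labels[[li]]$frame_index
    if (is.na(fidx) || fidx < 0 || fidx >= nf) {
      stop(sprintf("label %d has frame_index %s outside the sequence", li, fidx))
    }
    pyr <- image_pyramid(get_frame(images, fidx + 1L), n_levels)
    pts <- labels[[li]]$points
    normals <- shape_normals(pts)
    for (lev in seq_len(n_levels)) {
      sc <- 2^(lev - 1L)
      img <- pyr[[lev]]
      for (p in seq_len(np)) {
        pos <- pts[p, ] / sc
        reach <- (k + 1) * max(abs(normals[p, ]))
        if (pos[1] < reach || pos[1] > ncol(img) - 1 - reach ||
            pos[2] < reach || pos[2] > nrow(img) - 1 - reach) {
          edge_flag[p, lev] <- TRUE
        }
        profiles[lev, li, p, ] <- sample_profile(img, pos, normals[p, ], k)
      }
    }
  }

  levels <- vector("list", n_levels)
  for (lev in seq_len(n_levels)) {
    mean_p <- matrix(0, np, plen)
    inv_cov <- array(0, dim = c(np, plen, plen))
    for (p in seq_len(np)) {
      G <- matrix(profiles[lev, , p, ], nrow = nl)
      mu <- colMeans(G)
      S <- if (nl >= 2) cov(G) else matrix(0, plen, plen)
      eps <- epsilon_scale * mean(diag(S))
      if (!is.finite(eps) || eps <= 0) eps <- epsilon_scale
      S <- S + diag(eps, plen)
      mean_p[p, ] <- mu
      inv_cov[p, , ] <- solve(S)
    }
    levels[[lev]] <- list(mean = mean_p, inv_cov = inv_cov)
  }
  structure(list(levels = levels, k = as.integer(k), n_levels = as.integer(n_levels),
                 clamped_landmarks = edge_flag),
            class = "intensity_profile_model")
}

#' Assemble a trained active shape model
#'
#' @param pdm a [build_pdm()] point distribution model.
#' @param intensity a [build_intensity_models()] profile model.
#' @param source_id identifier of the image source (participant / probe
#'   setup) the model was trained on; models are bound to one source.
#' @param training_frames 0-based indices of the labelled frames.
#' @return object of class `shape_model`.
#' @export
shape_model <- function(pdm, intensity, source_id = "unknown", training_frames = integer()) {
  stopifnot(inherits(pdm, "pdm"), inherits(intensity, "intensity_profile_model"))
  structure(list(pdm = pdm, intensity = intensity, source_id = source_id,
                 training_frames = training_frames),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("shape_model (source '%s'): %d modes, k = %d, %d levels, trained on %d frames\n",
              x$source_id, x$pdm$n_modes, x$intensity$k, x$intensity$n_levels,
              length(x$training_frames)))
  invisible(x)
}

#' Save / load a trained shape model
#'
#' Persists the PDM and intensity-profile statistics as a versioned RDS
#' archive.
#'
#' @param model a [shape_model()].
#' @param path file path.
#' @return `write_shape_model` returns `path` invisibly; `read_shape_model`
#'   the model.
#' @export
write_shape_model <- function(model, path) {
  stopifnot(inherits(model, "shape_model"))
  saveRDS(list(format = "sonomuscle_shape_model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname write_shape_model
#' @export
read_shape_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "sonomuscle_shape_model")) {
    stop("not a sonomuscle shape-model archive")
  }
  obj$model
}
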