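# Multi-resolution active-shape-model search.
#
# Coarse-to-fine over resolution levels: at each level every landmark
# slides along its boundary normal to the candidate position whose
# normalised intensity-gradient profile minimises the Mahalanobis distance
# to the trained profile model; the updated point set is then projected
# onto the PDM with each mode coefficient clamped to +/- 3 SD, and the
# x-coordinates are re-pinned to the standard columns. Iteration stops
# when fewer than 10% of landmarks move more than 1 px (full resolution)
# or when max_iter is reached.

#' Fit the shape model to a single image frame
#'
#' @param model a [shape_model()].
#' @param image one grayscale frame (matrix, rows = depth).
#' @param init initial [landmark_shape()].
#' @param search_range candidate positions searched each side of the
#'   current landmark, in profile steps per level (default 4).
#' @param max_iter iteration cap per level (default 20).
#' @param n_levels resolution levels to use (default 3; 5 for
#'   sequence-initial frames). Capped at the model's trained levels.
#' @return list with `shape` (fitted [landmark_shape()]) and `diagnostics`
#'   (`iterations` per level, final `b`, `clamped`, `mean_mahalanobis`,
#'   `converged`).
#' @export
fit_shape <- function(model, image, init, search_range = 4L, max_iter = 20L,
                      n_levels = 3L) {
  stopifnot(inherits(model, "shape_model"), inherits(init, "landmark_shape"))
  n_levels <- min(n_levels, model$intensity$n_levels)
  k <- model$intensity$k
  np <- nrow(init$points)
  x_cols <- init$points[, 1]
  pyr <- image_pyramid(image, n_levels)

  v <- shape_to_vec(init)
  iterations <- integer(n_levels)
  converged <- TRUE
  b <- numeric(model$pdm$n_modes)
  clamped <- logical(model$pdm$n_modes)
  mean_md <- NA_real_

  for (lev in seq(n_levels, 1L)) {
    sc <- 2^(lev - 1L)
    img <- pyr[[lev]]
    prof <- model$intensity$levels[[lev]]
    level_converged <- FALSE
    for (it in seq_len(max_iter)) {
      pts <- matrix(v, np, 2)
      normals <- shape_normals(pts)
      md <- numeric(np)
      new_pts <- pts
      for (p in seq_len(np)) {
        dg <- sample_search_profile(img, pts[p, ] / sc, normals[p, ], k, search_range)
        best_s <- 0L; best_d <- Inf
        mu <- prof$mean[p, ]
        W <- prof$inv_cov[p, , ]
        for (s in (-search_range):search_range) {
          sub <- dg[(s + search_range + 1L):(s + search_range + 2L * k + 1L)]
          tot <- sum(abs(sub))
          if (tot > 0) sub <- sub / tot
          r <- sub - mu
          d <- drop(r %*% W %*% r)
          # tie-break: smallest displacement wins on equal distance
          if (d < best_d - 1e-12 ||
              (abs(d - best_d) <= 1e-12 && abs(s) < abs(best_s))) {
            best_d <- d; best_s <- s
          }
        }
        md[p] <- best_d
        new_pts[p, ] <- pts[p, ] + best_s * sc * normals[p, ]
      }
      con <- pdm_constrain(model$pdm, as.numeric(new_pts))
      b <- con$b; clamped <- con$clamped
      v_new <- con$v
      # re-pin x to the standard columns after reconstruction
      v_new[seq_len(np)] <- x_cols
      moved <- abs(v_new[(np + 1L):(2L * np)] - v[(np + 1L):(2L * np)])
      v <- v_new
      mean_md <- mean(md)
      iterations[lev] <- it
      if (mean(moved > 1) < 0.1) { level_converged <- TRUE; break }
    }
    if (!level_converged) converged <- FALSE
  }
  list(shape = landmark_shape(v[(np + 1L):(2L * np)], x_columns = x_cols,
                              frame_index = init$frame_index),
       diagnostics = list(iterations = iterations, b = b, clamped = clamped,
                          mean_mahalanobis = mean_md, converged = converged))
}

#' Segment a whole image sequence
#'
#' The first frame is initialised from `init` (or the PDM mean shape) and
#' searched over 5 resolution levels; each later frame is initialised from
#' the previous frame's solution and searched over 3 levels. A frame whose
#' fit fails carries the previous shape forward and is flagged.
#'
#' @param model a [shape_model()] or a list of them (e.g. superficial and
#'   deep aponeurosis); a list shares the per-frame image pyramids and
#'   returns one trajectory per model.
#' @param images an [image_sequence()].
#' @param init optional initial [landmark_shape()] (or list, one per
#'   model).
#' @param search_range,max_iter passed to [fit_shape()].
#' @return a `landmark_trajectory` (or list of them): `y` matrix
#'   (frames x 19), `x_columns`, `frame_rate_hz`, `mm_per_px_y`, per-frame
#'   `diagnostics` data frame and `flags`.
#' @export
segment_sequence <- function(model, images, init = NULL, search_range = 4L,
                             max_iter = 20L) {
  single <- inherits(model, "shape_model")
  models <- if (single) list(model) else model
  stopifnot(all(vapply(models, inherits, logical(1), "shape_model")),
            inherits(images, "image_sequence"))
  inits <- if (is.null(init)) {
    lapply(models, function(m) vec_to_shape(m$pdm$mean_shape, frame_index = 0L))
  } else if (inherits(init, "landmark_shape")) list(init) else init
  stopifnot(length(inits) == length(models))

  nf <- n_frames(images)
  nm <- length(models)
  np <- nrow(inits[[1]]$points)
  ys <- lapply(seq_len(nm), function(i) matrix(NA_real_, nf, np))
  diags <- lapply(seq_len(nm), function(i)
    data.frame(frame = 0:(nf - 1L), iterations = NA_integer_,
               mean_mahalanobis = NA_real_, converged = NA, carried = FALSE))
  current <- inits
  for (f in seq_len(nf)) {
    img <- get_frame(images, f)
    lv <- if (f == 1L) 5L else 3L
    for (mi in seq_len(nm)) {
      res <- tryCatch(
        fit_shape(models[[mi]], img, current[[mi]], search_range = search_range,
                  max_iter = max_iter, n_levels = lv),
        error = function(e) NULL)
      if (is.null(res)) {
        diags[[mi]]$carried[f] <- TRUE
        ys[[mi]][f, ] <- current[[mi]]$points[, 2]
      } else {
        current[[mi]] <- res$shape
        current[[mi]]$frame_index <- f  # init for next frame
        ys[[mi]][f, ] <- res$shape$points[, 2]
        diags[[mi]]$iterations[f] <- sum(res$diagnostics$iterations)
        diags[[mi]]$mean_mahalanobis[f] <- res$diagnostics$mean_mahalanobis
        diags[[mi]]$converged[f] <- res$diagnostics$converged
      }
    }
  }
  out <- lapply(seq_len(nm), function(mi) {
    structure(list(y = ys[[mi]], x_columns = inits[[mi]]$points[, 1],
                   frame_rate_hz = images$frame_rate_hz,
                   mm_per_px_y = images$mm_per_px_y,
                   diagnostics = diags[[mi]],
                   source_id = models[[mi]]$source_id),
              class = "landmark_trajectory")
  })
  if (single) out[[1]] else out
}

#' @export
print.landmark_trajectory <- function(x, ...) {
  cat(sprintf("landmark_trajectory: %d frames x %d landmarks at %g Hz (%d carried)\n",
              nrow(x$y), ncol(x$y), x$frame_rate_hz, sum(x$diagnostics$carried)))
  invisible(x)
}

#' Train a full shape model from an image sequence and labels
#'
#' Convenience wrapper: builds the PDM and the multi-resolution intensity
#' models from the same labelled frames and assembles a [shape_model()].
#'
#' @inheritParams build_intensity_models
#' @param variance_fraction passed to [build_pdm()].
#' @param source_id image-source identifier stored in the model.
#' @return a [shape_model()].
#' @export
train_shape_model <- function(images, labels, k = 6L, n_levels = 5L,
                              variance_fraction = 0.98, source_id = "unknown") {
  pdm <- build_pdm(labels, variance_fraction = variance_fraction)
  ipm <- build_intensity_models(images, labels, k = k, n_levels = n_levels)
  shape_model(pdm, ipm, source_id = source_id,
              training_frames = vapply(labels, function(l) as.integer(l$frame_index),
                                       integer(1)))
}
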