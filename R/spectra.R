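# From landmark trajectories to oscillation metrics: transverse
# displacement in mm relative to quiet standing, stride-frequency
# high-pass, 0-40 Hz power spectra, peak power and the frequency at which
# the cumulative area under the power-frequency curve reaches 50%, and
# grouping of landmarks into distal / mid / proximal image regions.

#' Transverse displacement relative to quiet standing
#'
#' `d_j(t) = -(y_j(t) - y_j,standing) * mm_per_px_y`: row index grows with
#' depth, so positive displacement is superficial (toward the skin) and
#' negative is deep.
#'
#' @param traj a `landmark_trajectory` from [segment_sequence()] (or a
#'   plain frames x landmarks matrix of rows in px).
#' @param standing [landmark_shape()] segmented from a quiet-standing
#'   image; must share the trajectory's columns.
#' @param mm_per_px_y depth pixel scale (taken from `traj` when present).
#' @param stance_metadata optional list (condition label,
#'   `stride_frequency_hz`, ...) carried through to the spectra.
#' @return object of class `displacement_set`: `displacement_mm` matrix
#'   (frames x landmarks), `frame_rate_hz`, `x_columns`, `metadata`.
#' @export
transverse_displacement <- function(traj, standing, mm_per_px_y = NULL,
                                    stance_metadata = list()) {
  stopifnot(inherits(standing, "landmark_shape"))
  if (inherits(traj, "landmark_trajectory")) {
    if (!isTRUE(all.equal(as.numeric(traj$x_columns),
                          as.numeric(standing$points[, 1])))) {
      stop("trajectory and standing shape use different landmark columns")
    }
    if (is.null(mm_per_px_y)) mm_per_px_y <- traj$mm_per_px_y
    y <- traj$y
    fr <- traj$frame_rate_hz
  } else {
    y <- traj
    fr <- stance_metadata$frame_rate_hz
    stopifnot(!is.null(mm_per_px_y), !is.null(fr))
  }
  d <- -sweep(y, 2, standing$points[, 2]) * mm_per_px_y
  structure(list(displacement_mm = d, frame_rate_hz = fr,
                 x_columns = if (inherits(traj, "landmark_trajectory")) traj$x_columns
                             else standing$points[, 1],
                 metadata = stance_metadata),
            class = "displacement_set")
}

#' High-pass displacement at the stride frequency
#'
#' Zero-phase fourth-order Butterworth high-pass per landmark series,
#' removing gross gait motion below the stride frequency so that the
#' spectra isolate the tissue oscillations.
#'
#' @param displ a [transverse_displacement()] set.
#' @param stride_frequency_hz cutoff; the per-condition stride frequency.
#' @param order filter order (default 4).
#' @return filtered `displacement_set` (cutoff recorded in metadata).
#' @export
highpass_stride <- function(displ, stride_frequency_hz, order = 4) {
  stopifnot(inherits(displ, "displacement_set"))
  out <- displ
  out$displacement_mm <- apply(displ$displacement_mm, 2, zerophase_butter,
                               cutoff_hz = stride_frequency_hz,
                               fs = displ$frame_rate_hz, order = order,
                               type = "high")
  out$metadata$stride_frequency_hz <- stride_frequency_hz
  out
}

#' Power spectrum and summary statistics of one displacement series
#'
#' One-sided FFT power `P(f) = 2 |X(f)|^2 / N^2` of the unwindowed series
#' (a unit-amplitude sinusoid yields ~ 0.5 mm^2 at its bin), truncated to
#' `[0, f_max]`. Peak power is the maximum of `P` on the grid. The
#' cumulative frequency is the smallest `f*` at which the trapezoidal area
#' under `P` from 0 to `f*` reaches 50% of the total area on
#' `[0, f_max]`, linearly interpolated inside the crossing bin.
#'
#' @param series numeric displacement series in mm (length >= 16).
#' @param fs sampling (frame) rate in Hz.
#' @param f_max spectrum ceiling (default 40 Hz).
#' @param landmark optional 0-based landmark index to record.
#' @return object of class `spectrum_summary`: `frequencies_hz`,
#'   `power_mm2`, `peak_power_mm2`, `cumulative_frequency_hz`, `landmark`,
#'   `region` (`"none"` until [assign_regions()]), `zero_spectrum` flag.
#' @export
power_spectrum <- function(series, fs, f_max = 40, landmark = NA_integer_) {
  stopifnot(all(is.finite(series)), length(series) >= 16, fs > 0)
  n <- length(series)
  X <- fft(series)
  nh <- n %/% 2L
  freq <- (0:nh) * fs / n
  P <- Mod(X[1:(nh + 1L)])^2 / n^2
  dbl <- 2:(nh + 1L)
  if (n %% 2L == 0L) dbl <- 2:nh  # Nyquist bin is not doubled
  P[dbl] <- 2 * P[dbl]
  keep <- freq <= f_max
  freq <- freq[keep]; P <- P[keep]

  total <- cumtrapz(freq, P)
  area <- total[length(total)]
  zero <- area <= 0
  if (zero) {
    cf <- 0
  } else {
    half <- 0.5 * area
    i <- which(total >= half)[1]
    cf <- if (i == 1L) freq[1] else {
      freq[i - 1L] + (half - total[i - 1L]) / (total[i] - total[i - 1L]) *
        (freq[i] - freq[i - 1L])
    }
  }
  structure(list(frequencies_hz = freq, power_mm2 = P,
                 peak_power_mm2 = max(P), cumulative_frequency_hz = cf,
                 landmark = landmark, region = "none", zero_spectrum = zero),
            class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("spectrum_summary (landmark %s, %s): peak %.4g mm^2, cumulative frequency %.3g Hz\n",
              x$landmark, x$region, x$peak_power_mm2, x$cumulative_frequency_hz))
  invisible(x)
}

#' Spectra for all landmarks of a displacement set
#'
#' @param displ a (high-passed) `displacement_set`.
#' @param f_max spectrum ceiling (default 40 Hz).
#' @return list of 19 [power_spectrum()] summaries, landmark indices
#'   0..18.
#' @export
landmark_spectra <- function(displ, f_max = 40) {
  stopifnot(inherits(displ, "displacement_set"))
  lapply(seq_len(ncol(displ$displacement_mm)), function(j) {
    power_spectrum(displ$displacement_mm[, j], displ$frame_rate_hz,
                   f_max = f_max, landmark = j - 1L)
  })
}

# 0-based landmark indices per image region (the conventional 1-based
# lists 2-6 / 8-12 / 14-18 over 19 landmarks).
region_indices <- function() {
  list(distal = 1:5, mid = 7:11, proximal = 13:17)
}

#' Assign image regions to landmark spectra
#'
#' Landmarks 1-5, 7-11 and 13-17 (0-based) form the distal, mid and
#' proximal regions; the remaining 4 landmarks are labelled `"none"`.
#'
#' @param summaries list of exactly 19 `spectrum_summary` objects ordered
#'   by landmark.
#' @return list with `summaries` (regions filled in) and `regions`, a data
#'   frame of per-region means of peak power and cumulative frequency.
#' @export
assign_regions <- function(summaries) {
  if (length(summaries) != 19) {
    stop(sprintf("expected 19 landmark summaries, got %d", length(summaries)))
  }
  reg <- region_indices()
  labels <- rep("none", 19)
  for (nm in names(reg)) labels[reg[[nm]] + 1L] <- nm
  for (i in seq_along(summaries)) summaries[[i]]$region <- labels[i]
  regions <- do.call(rbind, lapply(names(reg), function(nm) {
    idx <- reg[[nm]] + 1L
    data.frame(region = nm,
               peak_power_mm2 = mean(vapply(summaries[idx],
                                            function(s) s$peak_power_mm2, numeric(1))),
               cumulative_frequency_hz = mean(vapply(summaries[idx],
                                                     function(s) s$cumulative_frequency_hz,
                                                     numeric(1))))
  }))
  list(summaries = summaries, regions = regions)
}

#' Resample a stance-phase displacement to a fixed number of points
#'
#' Linear interpolation onto `n` evenly spaced points across the stance
#' interval. This is a reporting aid (trace averaging across strides and
#' participants); spectra are always computed on the native-rate series.
#'
#' @param displ a `displacement_set` (or numeric matrix frames x
#'   landmarks).
#' @param n number of output points (default 100).
#' @return matrix `n x landmarks`.
#' @export
resample_stance <- function(displ, n = 100L) {
  m <- if (inherits(displ, "displacement_set")) displ$displacement_mm else displ
  stopifnot(nrow(m) >= 2)
  s_in <- seq(0, 1, length.out = nrow(m))
  s_out <- seq(0, 1, length.out = n)
  apply(m, 2, function(col) approx(s_in, col, xout = s_out)$y)
}
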