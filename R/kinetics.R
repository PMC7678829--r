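# Ground reaction force processing: low-pass filtering, stance detection,
# and the impact input-signal frequency -- the inverse of (four times) the
# interval between maximal rate of force development and the first impact
# force maximum. That interval spans a quarter of a whole oscillation of
# the impact transient, so the default convention is f = 1/(4 * dt); the
# literal reading f = 1/dt is also available and the two differ by exactly
# a factor of 4.

#' Low-pass filter a force trace
#'
#' Zero-phase fourth-order Butterworth low-pass (forward-backward), the
#' standard treatment that keeps the impact content while removing
#' measurement noise. Length is preserved.
#'
#' @param trace a [force_trace()].
#' @param cutoff_hz cutoff frequency (default 60 Hz).
#' @param order filter order (default 4).
#' @return filtered [force_trace()] (truth carried through).
#' @export
lowpass_force <- function(trace, cutoff_hz = 60, order = 4) {
  stopifnot(inherits(trace, "force_trace"))
  force_trace(zerophase_butter(trace$values, cutoff_hz, trace$sampling_rate_hz,
                               order = order, type = "low"),
              trace$sampling_rate_hz, truth = trace$truth)
}

#' Detect stance phases by force thresholding
#'
#' Contact is an upward crossing of `threshold_N`, toe-off the following
#' downward crossing; intervals shorter than `min_duration_s` are
#' discarded as noise. The trace should be low-pass filtered first.
#'
#' @param trace a [force_trace()].
#' @param threshold_N detection threshold in N (default 20).
#' @param min_duration_s minimum stance duration (default 0.1 s).
#' @return object of class `stance_events`: matrix `intervals` with
#'   columns `contact_time_s`, `toeoff_time_s`, plus the threshold used.
#' @export
detect_stance <- function(trace, threshold_N = 20, min_duration_s = 0.1) {
  stopifnot(inherits(trace, "force_trace"))
  above <- trace$values > threshold_N
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1)
  ends <- which(d == -1) - 1L
  keep <- (ends - starts + 1L) / trace$sampling_rate_hz >= min_duration_s
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0) warning("no stance phases detected above the threshold")
  intervals <- cbind(contact_time_s = trace$time_s[starts],
                     toeoff_time_s = trace$time_s[ends])
  structure(list(intervals = intervals, threshold_N = threshold_N),
            class = "stance_events")
}

#' @export
print.stance_events <- function(x, ...) {
  cat(sprintf("stance_events: %d intervals (threshold %g N)\n",
              nrow(x$intervals), x$threshold_N))
  invisible(x)
}

#' Impact input-signal frequency for one stance phase
#'
#' The rate of force development (RFD) is the central finite-difference
#' time derivative of the force. Within the first `impact_window_fraction`
#' of stance, `t_max_rfd` is the RFD maximum and `t_peak_force` the first
#' local force maximum after it (falling back to the window's global
#' maximum when no interior local maximum exists, as in walking traces
#' without a distinct transient). The frequency is `1/(4 * dt)` under the
#' quarter-wave convention or `1/dt` under `direct_inverse`.
#'
#' @param trace a (filtered) [force_trace()].
#' @param stance length-2 numeric `c(contact_time_s, toeoff_time_s)`, or a
#'   `stance_events` row index via `stance_events[i, ]`.
#' @param convention `"quarter_wave"` (default) or `"direct_inverse"`.
#' @param impact_window_fraction fraction of stance searched for the
#'   impact (default 0.25; transients occur in early stance and the
#'   late-stance push-off peak must be excluded).
#' @return object of class `input_frequency_result`: `t_max_rfd`,
#'   `t_peak_force`, `delta_t`, `frequency_hz`, `convention`.
#' @export
input_frequency <- function(trace, stance,
                            convention = c("quarter_wave", "direct_inverse"),
                            impact_window_fraction = 0.25) {
  stopifnot(inherits(trace, "force_trace"))
  convention <- match.arg(convention)
  fs <- trace$sampling_rate_hz
  t0 <- stance[1]; t1 <- stance[2]
  stopifnot(t1 > t0, t0 >= trace$time_s[1], t1 <= trace$time_s[length(trace$time_s)])
  i0 <- which.min(abs(trace$time_s - t0))
  iw <- which.min(abs(trace$time_s - (t0 + impact_window_fraction * (t1 - t0))))
  if (iw - i0 < 3) stop("impact window contains too few samples")

  v <- trace$values
  n <- length(v)
  rfd <- c(NA, (v[3:n] - v[1:(n - 2)]) * fs / 2, NA)
  win <- i0:iw
  i_rfd <- win[which.max(rfd[win])]

  after <- (i_rfd + 1L):iw
  va <- v[after]
  loc <- which(diff(sign(diff(c(v[i_rfd], va, v[min(iw + 1L, n)])))) < 0)
  i_peak <- if (length(loc) > 0) after[loc[1]] else after[which.max(va)]
  if (i_peak <= i_rfd) stop("no impact peak after max RFD")

  dt <- (i_peak - i_rfd) / fs
  freq <- if (convention == "quarter_wave") 1 / (4 * dt) else 1 / dt
  structure(list(t_max_rfd = trace$time_s[i_rfd],
                 t_peak_force = trace$time_s[i_peak],
                 delta_t = dt, frequency_hz = freq, convention = convention),
            class = "input_frequency_result")
}

#' @export
print.input_frequency_result <- function(x, ...) {
  cat(sprintf("input frequency %.2f Hz (%s; dt = %.4f s, max RFD at %.4f s, peak at %.4f s)\n",
              x$frequency_hz, x$convention, x$delta_t, x$t_max_rfd, x$t_peak_force))
  invisible(x)
}

#' Input frequency for every stance of a trace
#'
#' @param trace a (filtered) [force_trace()].
#' @param stance a `stance_events` object from [detect_stance()].
#' @inheritParams input_frequency
#' @return data frame `stance_index, t_max_rfd, t_peak_force, delta_t_s,
#'   input_frequency_hz, convention`.
#' @export
input_frequency_per_stance <- function(trace, stance,
                                       convention = c("quarter_wave", "direct_inverse"),
                                       impact_window_fraction = 0.25) {
  convention <- match.arg(convention)
  stopifnot(inherits(stance, "stance_events"))
  res <- lapply(seq_len(nrow(stance$intervals)), function(i) {
    r <- input_frequency(trace, stance$intervals[i, ], convention = convention,
                         impact_window_fraction = impact_window_fraction)
    data.frame(stance_index = i - 1L, t_max_rfd = r$t_max_rfd,
               t_peak_force = r$t_peak_force, delta_t_s = r$delta_t,
               input_frequency_hz = r$frequency_hz, convention = r$convention)
  })
  do.call(rbind, res)
}
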