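# Synthetic vertical ground reaction force and surface EMG. Both carry a
# `truth` record so downstream estimators can be validated exactly.
#
# The running trace is built so that the interval between maximal rate of
# force development and the first (impact) force maximum is exactly a
# quarter period of the requested impact frequency: the impact transient
# rises as a raised cosine A/2 * (1 - cos(2*pi*f*t')), whose steepest rise
# is at t' = 1/(4f) and whose peak is at t' = 1/(2f). The active half of
# stance starts with zero slope at the impact peak, so the early-stance
# timing is untouched by superposition.

#' Construct a force trace object
#'
#' @param values vertical force per sample (N).
#' @param sampling_rate_hz sampling rate (default 2000).
#' @param truth optional generator ground-truth record.
#' @return object of class `force_trace`.
#' @export
force_trace <- function(values, sampling_rate_hz = 2000, truth = NULL) {
  stopifnot(all(is.finite(values)), sampling_rate_hz > 0)
  structure(list(values = values, sampling_rate_hz = sampling_rate_hz,
                 time_s = (seq_along(values) - 1L) / sampling_rate_hz,
                 truth = truth),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("force_trace: %d samples at %g Hz (%.3g s), peak %.1f N\n",
              length(x$values), x$sampling_rate_hz,
              length(x$values) / x$sampling_rate_hz, max(x$values)))
  invisible(x)
}

# Active bump shape on u in [0, 1]: squared-sine rise (zero slope at onset,
# so it cannot disturb the impact-peak timing) joined C1 at u = 0.5 to a
# plain sine fall, which reaches zero with finite slope so that
# threshold-based toe-off detection lands within a couple of samples.
active_bump <- function(u) {
  g <- numeric(length(u))
  lo <- u >= 0 & u <= 0.5
  hi <- u > 0.5 & u <= 1
  g[lo] <- sin(pi * u[lo])^2
  g[hi] <- sin(pi * u[hi])
  g
}

# One running stance: raised-cosine impact transient + delayed active bump;
# the impact oscillation continues with exponential decay.
running_stance <- function(tt, f, a_imp, a_act, T_st) {
  t_half <- 1 / (2 * f)
  y <- numeric(length(tt))
  rise <- tt <= t_half
  y[rise] <- a_imp / 2 * (1 - cos(2 * pi * f * tt[rise]))
  late <- !rise
  tl <- tt[late]
  decay <- exp(-(tl - t_half) * 2 * f)
  y[late] <- a_imp / 2 * (1 - cos(2 * pi * f * tl)) * decay +
    a_act * active_bump((tl - t_half) / (T_st - t_half))
  y
}

# One walking stance: first hump rises as a raised cosine at the impact
# frequency (quarter-wave timing identical to running), eases into a valley,
# then a second push-off hump returns to zero at toe-off.
walking_stance <- function(tt, f, a1, a2, T_st) {
  t_half <- 1 / (2 * f)
  t_mid <- 0.5 * T_st
  t_h2 <- 0.75 * T_st
  a_v <- 0.7 * min(a1, a2)
  y <- numeric(length(tt))
  s1 <- tt <= t_half
  y[s1] <- a1 / 2 * (1 - cos(2 * pi * f * tt[s1]))
  s2 <- tt > t_half & tt <= t_mid
  y[s2] <- a_v + (a1 - a_v) / 2 * (1 + cos(pi * (tt[s2] - t_half) / (t_mid - t_half)))
  s3 <- tt > t_mid & tt <= t_h2
  y[s3] <- a_v + (a2 - a_v) / 2 * (1 - cos(pi * (tt[s3] - t_mid) / (t_h2 - t_mid)))
  s4 <- tt > t_h2
  y[s4] <- a2 * cos(pi / 2 * (tt[s4] - t_h2) / (T_st - t_h2))
  y
}

#' Generate a synthetic vertical ground reaction force trace
#'
#' Running traces consist of a raised-cosine impact transient at
#' `impact_frequency_hz` plus a delayed active peak; walking traces are the
#' classic double hump whose first hump rises at the impact frequency. In
#' both gaits the interval from maximal rate of force development to the
#' first force maximum equals `1 / (4 * impact_frequency_hz)` by
#' construction, and is recorded in `truth`.
#'
#' @param gait `"running"` or `"walking"`.
#' @param stance_duration_s stance duration; must exceed
#'   `4 / impact_frequency_hz`.
#' @param impact_frequency_hz impact transient frequency, in (2, 100) Hz.
#' @param impact_amplitude_N impact transient peak (N); 0 removes the
#'   transient (running) so the active peak is the first maximum.
#' @param active_peak_N active (push-off) peak force (N).
#' @param sampling_rate_hz sampling rate (default 2000).
#' @param n_stances number of stance phases.
#' @param swing_duration_s zero-force gap between stances.
#' @param lead_in_s zero-force lead-in before the first contact.
#' @param noise_sd_N additive Gaussian measurement noise (default 0).
#' @param seed seed for the noise (ignored when `noise_sd_N = 0`).
#' @return a [force_trace()] whose `truth` holds `impact_frequency_hz`,
#'   per-stance `stance_intervals`, `max_rfd_time_s` and
#'   `impact_peak_time_s`.
#' @export
generate_force_trace <- function(gait = c("running", "walking"),
                                 stance_duration_s = 0.35,
                                 impact_frequency_hz = 15,
                                 impact_amplitude_N = 600,
                                 active_peak_N = 1500,
                                 sampling_rate_hz = 2000,
                                 n_stances = 1L,
                                 swing_duration_s = 0.4,
                                 lead_in_s = 0.05,
                                 noise_sd_N = 0,
                                 seed = 1L) {
  gait <- match.arg(gait)
  f <- impact_frequency_hz
  if (f <= 2 || f >= 100) stop("impact_frequency_hz must lie in (2, 100) Hz")
  if (stance_duration_s <= 4 / f) {
    stop(sprintf("stance_duration_s = %g s must exceed 4/impact_frequency_hz = %g s",
                 stance_duration_s, 4 / f))
  }
  fs <- sampling_rate_hz
  stride_s <- stance_duration_s + swing_duration_s
  total_s <- lead_in_s + n_stances * stride_s
  if (lead_in_s + (n_stances - 1) * stride_s + 1 / (2 * f) >= total_s) {
    stop("impact transient peak would exceed the trace duration")
  }
  n <- as.integer(round(total_s * fs))
  tgrid <- (seq_len(n) - 1L) / fs
  values <- numeric(n)
  intervals <- matrix(0, n_stances, 2,
                      dimnames = list(NULL, c("contact_time_s", "toeoff_time_s")))
  rfd_times <- peak_times <- numeric(n_stances)
  for (s in seq_len(n_stances)) {
    t0 <- lead_in_s + (s - 1) * stride_s
    in_st <- tgrid >= t0 & tgrid <= t0 + stance_duration_s
    tt <- tgrid[in_st] - t0
    values[in_st] <- if (gait == "running") {
      running_stance(tt, f, impact_amplitude_N, active_peak_N, stance_duration_s)
    } else {
      walking_stance(tt, f, active_peak_N, active_peak_N, stance_duration_s)
    }
    intervals[s, ] <- c(t0, t0 + stance_duration_s)
    rfd_times[s] <- t0 + 1 / (4 * f)
    peak_times[s] <- t0 + 1 / (2 * f)
  }
  if (noise_sd_N > 0) {
    values <- values + withr::with_seed(as.integer(seed), rnorm(n, sd = noise_sd_N))
  }
  force_trace(values, fs,
              truth = list(impact_frequency_hz = f,
                           stance_intervals = intervals,
                           max_rfd_time_s = rfd_times,
                           impact_peak_time_s = peak_times,
                           gait = gait))
}

#' Construct an EMG trace object
#'
#' @param values voltage samples (arbitrary units).
#' @param sampling_rate_hz sampling rate (default 2000).
#' @param truth optional generator ground-truth record.
#' @return object of class `emg_trace`.
#' @export
emg_trace <- function(values, sampling_rate_hz = 2000, truth = NULL) {
  stopifnot(all(is.finite(values)), sampling_rate_hz > 0)
  structure(list(values = values, sampling_rate_hz = sampling_rate_hz,
                 time_s = (seq_along(values) - 1L) / sampling_rate_hz,
                 truth = truth),
            class = "emg_trace")
}

#' Generate a synthetic surface EMG trace
#'
#' Band-limited Gaussian noise multiplied by burst envelopes (raised-cosine
#' on/off ramps), optionally plus a low-frequency motion-artifact sinusoid
#' (below 10 Hz). The burst envelope is recorded in `truth`.
#'
#' @param duration_s trace duration.
#' @param burst_windows list of `c(start_s, end_s)` activity windows; an
#'   empty list yields a silent trace with a warning.
#' @param band_hz two-element passband of the noise carrier, within
#'   `(0, fs/2)`.
#' @param burst_amplitude RMS amplitude of the carrier inside bursts.
#' @param artifact optional list `(frequency_hz, amplitude)` with
#'   `frequency_hz < 10`.
#' @param ramp_s raised-cosine ramp at burst edges (default 10 ms).
#' @param sampling_rate_hz sampling rate (default 2000).
#' @param seed seed for the noise carrier.
#' @return an [emg_trace()]; `truth$envelope` is the applied envelope.
#' @export
generate_emg_trace <- function(duration_s, burst_windows,
                               band_hz = c(20, 450), burst_amplitude = 1,
                               artifact = NULL, ramp_s = 0.01,
                               sampling_rate_hz = 2000, seed = 1L) {
  fs <- sampling_rate_hz
  if (any(band_hz <= 0) || any(band_hz >= fs / 2)) {
    stop(sprintf("band %g-%g Hz must lie within (0, %g) Hz", band_hz[1], band_hz[2], fs / 2))
  }
  n <- as.integer(round(duration_s * fs))
  t <- (seq_len(n) - 1L) / fs
  env <- numeric(n)
  if (length(burst_windows) == 0) {
    warning("no burst windows supplied; generating a silent EMG trace")
  }
  for (w in burst_windows) {
    ramp_up <- t >= w[1] & t < w[1] + ramp_s
    ramp_dn <- t > w[2] - ramp_s & t <= w[2]
    core <- t >= w[1] + ramp_s & t <= w[2] - ramp_s
    env[core] <- 1
    env[ramp_up] <- pmax(env[ramp_up], 0.5 * (1 - cos(pi * (t[ramp_up] - w[1]) / ramp_s)))
    env[ramp_dn] <- pmax(env[ramp_dn], 0.5 * (1 - cos(pi * (w[2] - t[ramp_dn]) / ramp_s)))
  }
  carrier <- withr::with_seed(as.integer(seed), rnorm(n))
  carrier <- zerophase_butter(carrier, band_hz, fs, order = 4, type = "pass")
  carrier <- burst_amplitude * carrier / stats::sd(carrier)
  values <- carrier * env
  if (!is.null(artifact)) {
    if (artifact$frequency_hz >= 10) stop("motion artifact must lie below 10 Hz")
    values <- values + artifact$amplitude * sin(2 * pi * artifact$frequency_hz * t)
  }
  values <- values - mean(values)
  emg_trace(values, fs, truth = list(envelope = env, burst_windows = burst_windows,
                                     band_hz = band_hz, artifact = artifact))
}

#' Write / read a 1-D physiological trace as CSV
#'
#' CSV columns `time_s,value`; the sampling rate is recovered from the time
#' column on reading.
#'
#' @param trace a `force_trace` or `emg_trace`.
#' @param path CSV path.
#' @param type `"force"` or `"emg"` (for `read_trace`).
#' @return `write_trace` returns `path` invisibly; `read_trace` the
#'   reconstructed trace (without `truth`).
#' @export
write_trace <- function(trace, path) {
  write.csv(data.frame(time_s = trace$time_s, value = trace$values),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, type = c("force", "emg")) {
  type <- match.arg(type)
  df <- read.csv(path)
  stopifnot(all(c("time_s", "value") %in% names(df)))
  fs <- 1 / mean(diff(df$time_s))
  if (type == "force") force_trace(df$value, fs) else emg_trace(df$value, fs)
}
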