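# EMG intensity through a bank of 11 non-linearly scaled wavelets.
#
# Center frequencies follow cf_j = (1/scale) * (j + q)^r with the standard
# parameters scale = 0.3, q = 1.45, r = 1.959, which place the band edges
# at 6.90 Hz (j = 0) and 395.44 Hz (j = 10). Each wavelet is defined in
# the frequency domain as W_j(f) = (f/cf_j)^(cf_j*scale) *
# exp((1 - f/cf_j) * cf_j * scale), a unimodal gain peaking at cf_j. The
# lowest band is excluded from the total intensity to suppress
# low-frequency motion artifact.

#' Center frequencies of the non-linearly scaled wavelet bank
#'
#' `cf_j = (1/scale) * (j + q)^r` for `j = 0..n-1`.
#'
#' @param n number of wavelets (default 11).
#' @param scale,q,r bank parameters (defaults 0.3, 1.45, 1.959).
#' @return numeric vector of center frequencies in Hz, strictly increasing.
#' @export
center_frequencies <- function(n = 11L, scale = 0.3, q = 1.45, r = 1.959) {
  stopifnot(n >= 1, scale > 0, r > 0)
  (1 / scale) * ((seq_len(n) - 1L) + q)^r
}

# Wavelet gain in the frequency domain (before grid normalisation).
wavelet_gain <- function(f, cf, scale) {
  e <- cf * scale
  g <- numeric(length(f))
  pos <- f > 0
  g[pos] <- (f[pos] / cf)^e * exp((1 - f[pos] / cf) * e)
  g
}

#' Build the wavelet filter bank on an FFT grid
#'
#' Evaluates each wavelet's gain on the FFT frequency grid for a trace of
#' `n_samples` at `fs` Hz, scales each filter so its maximum gain on the
#' grid is 1, and forces the gain at 0 Hz to 0. A wavelet whose center
#' frequency exceeds Nyquist is zeroed above Nyquist with a warning.
#'
#' @param fs sampling rate in Hz.
#' @param n_samples trace length the bank will be applied to.
#' @param n,scale,q,r passed to [center_frequencies()].
#' @param normalisation `"peak"` (max gain 1, default) or `"sum"` (filters
#'   jointly scaled so their summed gain plateaus near 1, for users who
#'   need approximate signal reconstruction from the band sum).
#' @return object of class `wavelet_bank`: `center_frequencies_hz`,
#'   `gains` (matrix n_wavelets x n_freq, one-sided grid), `freq_hz`,
#'   `n_samples`, `fs`.
#' @export
build_wavelet_bank <- function(fs, n_samples, n = 11L, scale = 0.3, q = 1.45,
                               r = 1.959, normalisation = c("peak", "sum")) {
  normalisation <- match.arg(normalisation)
  cf <- center_frequencies(n, scale, q, r)
  nyq <- fs / 2
  if (cf[n] >= nyq) {
    warning(sprintf("highest center frequency %.2f Hz is at or above Nyquist (%g Hz); gains above Nyquist are zero",
                    cf[n], nyq))
  }
  nh <- n_samples %/% 2L
  freq <- (0:nh) * fs / n_samples
  gains <- t(vapply(cf, function(c1) wavelet_gain(freq, c1, scale), numeric(nh + 1L)))
  gains[, 1] <- 0
  if (normalisation == "peak") {
    mx <- apply(gains, 1, max)
    mx[mx == 0] <- 1
    gains <- gains / mx
  } else {
    plateau <- colSums(gains)
    ref <- stats::median(plateau[freq > cf[2] & freq < min(cf[n], nyq)])
    gains <- gains / ref
  }
  structure(list(center_frequencies_hz = cf, gains = gains, freq_hz = freq,
                 n_samples = as.integer(n_samples), fs = fs,
                 scale = scale, q = q, r = r, normalisation = normalisation),
            class = "wavelet_bank")
}

#' @export
print.wavelet_bank <- function(x, ...) {
  cat(sprintf("wavelet_bank: %d wavelets spanning %.2f-%.2f Hz (fs %g Hz, %d samples, %s-normalised)\n",
              length(x$center_frequencies_hz), min(x$center_frequencies_hz),
              max(x$center_frequencies_hz), x$fs, x$n_samples, x$normalisation))
  invisible(x)
}

#' EMG intensity per wavelet band
#'
#' Filters the trace in the frequency domain with each wavelet and
#' demodulates with the analytic signal: `intensity_j(t) = |z_j(t)|^2 / 2`,
#' the instantaneous mean-square power of band `j` (a unit-amplitude
#' sinusoid at a center frequency gives intensity 0.5). The total is the
#' sum over bands 1..10 -- the first wavelet is excluded to suppress
#' motion artifact.
#'
#' @param trace an [emg_trace()] (>= 64 samples).
#' @param bank a matching [build_wavelet_bank()]; built on the fly when
#'   omitted.
#' @return object of class `intensity_trace`: `band` matrix
#'   (n_samples x n_wavelets), `total` (sum over bands excluding the
#'   first), `time_s`, `sampling_rate_hz`, `normalisation_reference`
#'   (NULL until [normalize_intensity()]).
#' @export
emg_intensity <- function(trace, bank = NULL) {
  stopifnot(inherits(trace, "emg_trace"))
  x <- trace$values
  n <- length(x)
  if (n < 64) stop("EMG trace must have at least 64 samples")
  if (is.null(bank)) bank <- build_wavelet_bank(trace$sampling_rate_hz, n)
  stopifnot(inherits(bank, "wavelet_bank"), bank$n_samples == n)
  X <- fft(x)
  nh <- n %/% 2L
  nw <- nrow(bank$gains)
  band <- matrix(0, n, nw)
  for (j in seq_len(nw)) {
    # analytic band signal: one-sided spectrum doubled, negative half zeroed
    Y <- complex(real = numeric(n))
    g <- bank$gains[j, ]
    Y[1] <- X[1] * g[1]
    if (n %% 2L == 0L) {
      Y[2:nh] <- 2 * X[2:nh] * g[2:nh]
      Y[nh + 1L] <- X[nh + 1L] * g[nh + 1L]
    } else {
      Y[2:(nh + 1L)] <- 2 * X[2:(nh + 1L)] * g[2:(nh + 1L)]
    }
    z <- fft(Y, inverse = TRUE) / n
    band[, j] <- Mod(z)^2 / 2
  }
  total <- rowSums(band[, -1L, drop = FALSE])
  structure(list(band = band, total = total, time_s = trace$time_s,
                 sampling_rate_hz = trace$sampling_rate_hz,
                 center_frequencies_hz = bank$center_frequencies_hz,
                 normalisation_reference = NULL),
            class = "intensity_trace")
}

#' Normalise intensity traces to their common peak
#'
#' Divides every trace's total (and per-band) intensity by the single
#' maximum total intensity across all conditions, so the maximum of the
#' normalised ensemble is exactly 1.
#'
#' @param traces named list of `intensity_trace` objects, one per
#'   locomotion condition.
#' @return the list with normalised intensities; each element's
#'   `normalisation_reference` records the peak value and the condition it
#'   came from.
#' @export
normalize_intensity <- function(traces) {
  stopifnot(length(traces) >= 1,
            all(vapply(traces, inherits, logical(1), "intensity_trace")))
  peaks <- vapply(traces, function(tr) max(tr$total), numeric(1))
  if (max(peaks) <= 0) stop("cannot normalise silent EMG: all intensities are zero")
  ref <- max(peaks)
  ref_cond <- names(peaks)[which.max(peaks)]
  if (is.null(ref_cond)) ref_cond <- as.character(which.max(peaks))
  lapply(traces, function(tr) {
    tr$total <- tr$total / ref
    tr$band <- tr$band / ref
    tr$normalisation_reference <- list(peak = ref, condition = ref_cond)
    tr
  })
}
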