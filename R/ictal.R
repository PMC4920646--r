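#' Morlet wavelet parameters
#'
#' Parameters of the continuous wavelet transform used for ictal peak-
#' frequency estimation: an analytic Morlet mother wavelet with resolution
#' parameter `f0` (frequency-to-bandwidth ratio; the wavelet's Gaussian
#' envelope has time SD `f0/f` seconds at analysis frequency `f`, i.e.
#' spectral SD `f/(2*pi*f0)` Hz), evaluated on a linear 0.1 Hz grid over
#' 5--14 Hz. Edge effects are mitigated by reflection padding.
#'
#' @param f0 resolution parameter (dimensionless).
#' @param freq_range_hz analysis range (Hz).
#' @param n_freqs number of grid frequencies (linear spacing).
#' @param pad_s reflection padding on each side (s).
#' @export
wavelet_params <- function(f0 = 1, freq_range_hz = c(5, 14), n_freqs = 91,
                           pad_s = 2) {
  if (n_freqs < 2L) stop("n_freqs must be >= 2")
  if (diff(freq_range_hz) <= 0) stop("invalid freq_range_hz")
  structure(list(f0 = f0, freq_range_hz = freq_range_hz, n_freqs = n_freqs,
                 pad_s = pad_s), class = "wavelet_params")
}

wavelet_freq_grid <- function(params) {
  seq(params$freq_range_hz[1L], params$freq_range_hz[2L],
      length.out = params$n_freqs)
}

#' Morlet continuous wavelet transform power
#'
#' FFT-based analytic Morlet CWT of a signal segment. The wavelet is
#' amplitude-normalized (unit peak in the frequency domain) so that a pure
#' tone yields the same ridge power at every analysis frequency. The
#' segment is reflection-padded by `pad_s` on each side and the padding is
#' trimmed from the output.
#'
#' @param segment numeric signal vector.
#' @param fs sampling rate (Hz).
#' @param params a [wavelet_params()].
#' @return List with `power` (matrix, frequencies in rows x time in
#'   columns), `freqs_hz`, and `times_s` (relative to segment start).
#' @export
morlet_cwt <- function(segment, fs, params = wavelet_params()) {
  freqs <- wavelet_freq_grid(params)
  if (max(freqs) >= fs / 2) stop("frequency range exceeds Nyquist")
  np <- round(params$pad_s * fs)
  n <- length(segment)
  # a segment must span a few wavelet widths at the lowest frequency
  if (n + 2L * np < 3 * round(fs * params$f0 / min(freqs)))
    stop("segment too short for the requested wavelet resolution")
  np <- min(np, n - 1L)
  padded <- c(rev(segment[seq_len(np) + 1L]), segment,
              rev(segment[(n - np):(n - 1L)]))
  # zero-pad to a 2-3-5-smooth length for fast FFT convolution
  m <- stats::nextn(length(padded), c(2, 3, 5))
  padded <- c(padded, numeric(m - length(padded)))
  X <- stats::fft(padded)
  nu <- (seq_len(m) - 1L) * fs / m
  power <- matrix(0, nrow = length(freqs), ncol = n)
  for (k in seq_along(freqs)) {
    f <- freqs[k]
    sigma_f <- f / (2 * pi * params$f0)
    # analytic wavelet: Gaussian around +f only, unit peak
    H <- exp(-0.5 * ((nu - f) / sigma_f)^2)
    H[nu > fs / 2] <- 0
    w <- stats::fft(X * H, inverse = TRUE) / m
    power[k, ] <- Mod(w[(np + 1L):(np + n)])^2
  }
  list(power = power, freqs_hz = freqs, times_s = (seq_len(n) - 1L) / fs)
}

#' Ridge of a time-frequency power matrix
#'
#' For every time point, the grid frequency maximizing power. Ties are
#' broken toward the lower frequency (which makes the all-zero degenerate
#' case return the lowest grid frequency).
#'
#' @param cwt output of [morlet_cwt()] (or any list with `power` and
#'   `freqs_hz`).
#' @return Numeric vector of instantaneous ridge frequencies (Hz).
#' @export
ridge_frequency <- function(cwt) {
  if (!length(cwt$power)) stop("empty power matrix")
  idx <- apply(cwt$power, 2L, which.max) # which.max takes the first (lowest)
  cwt$freqs_hz[idx]
}

#' Mean wavelet peak frequency of one SWD
#'
#' Extracts the event's samples from the recording, computes the Morlet
#' CWT, and returns the arithmetic mean of the ridge frequency over the
#' event span `[start_s, end_s)`.
#'
#' @param rec an `eeg_recording`.
#' @param start_s,end_s event interval in session seconds.
#' @param params a [wavelet_params()].
#' @param channel analysis channel.
#' @return Mean ridge frequency (Hz).
#' @export
swd_peak_frequency <- function(rec, start_s, end_s,
                               params = wavelet_params(), channel = 1L) {
  if (end_s - start_s < 1) stop("event shorter than 1 s")
  x <- rec_channel(rec, channel)
  i0 <- max(1L, floor((start_s - rec$t0) * rec$fs) + 1L)
  i1 <- min(length(x), ceiling((end_s - rec$t0) * rec$fs))
  cw <- morlet_cwt(x[i0:i1], rec$fs, params)
  mean(ridge_frequency(cw))
}

#' Per-event and per-animal ictal peak frequency
#'
#' `ictal_peak_frequencies()` computes the mean wavelet peak frequency of
#' every treatment-period SWD (events starting at or after the injection);
#' `animal_peak_frequency()` averages the per-SWD means without weighting
#' and reports the SEM across SWDs. With no eligible SWD the result is
#' missing (`NA`), never zero.
#'
#' @param rec an `eeg_recording`.
#' @param events a `"swd_events"` data frame of detected SWDs.
#' @param params a [wavelet_params()].
#' @param channel analysis channel.
#' @param treatment_only restrict to events with `start_s >= 0`.
#' @return `ictal_peak_frequencies()`: the events data frame with
#'   `mean_wavelet_freq_hz` filled in (restricted to the analyzed rows);
#'   `animal_peak_frequency()`: list with `mean_hz`, `sem_hz`, `n`.
#' @export
ictal_peak_frequencies <- function(rec, events, params = wavelet_params(),
                                   channel = 1L, treatment_only = TRUE) {
  ev <- events[events$label == "swd", , drop = FALSE]
  if (treatment_only) ev <- ev[ev$start_s >= 0, , drop = FALSE]
  if (nrow(ev)) {
    x <- rec_channel(rec, channel)
    ev$mean_wavelet_freq_hz <- vapply(seq_len(nrow(ev)), function(k) {
      i0 <- max(1L, floor((ev$start_s[k] - rec$t0) * rec$fs) + 1L)
      i1 <- min(length(x), ceiling((ev$end_s[k] - rec$t0) * rec$fs))
      mean(ridge_frequency(morlet_cwt(x[i0:i1], rec$fs, params)))
    }, 0)
  }
  ev
}

#' @rdname ictal_peak_frequencies
#' @param per_swd_means numeric vector of per-SWD mean frequencies.
#' @export
animal_peak_frequency <- function(per_swd_means) {
  per_swd_means <- per_swd_means[is.finite(per_swd_means)]
  n <- length(per_swd_means)
  if (n == 0L) return(list(mean_hz = NA_real_, sem_hz = NA_real_, n = 0L))
  list(mean_hz = mean(per_swd_means),
       sem_hz = if (n > 1L) stats::sd(per_swd_means) / sqrt(n) else NA_real_,
       n = n)
}
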