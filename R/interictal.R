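#' Interictal spectral-analysis parameters
#'
#' Parameters of the masked interictal band-power analysis: anti-aliased
#' resampling to 200 Hz, a Gaussian-window short-time Fourier transform
#' with about 1 Hz spectral resolution (`f0 = 1`: Gaussian taper with
#' spectral SD 1 Hz, i.e. time SD `1/(2*pi)` s, truncated at +-4 SD) on a
#' 1 Hz frequency grid over 1--80 Hz, and the five conventional bands with
#' 48--52 Hz excluded from gamma to avoid mains contamination.
#'
#' @param resample_hz target sampling rate (Hz).
#' @param freq_range_hz analysis grid range (Hz), integer bins.
#' @param f0 spectral resolution parameter: the Gaussian taper's spectral
#'   SD in Hz.
#' @param bands named list of inclusive integer-bin band edges.
#' @param notch_exclusion_hz inclusive bin range excluded from gamma.
#' @param min_run_s minimum unmasked run length analyzed (s).
#' @param min_unmasked_fraction epochs with less unmasked time than this
#'   are reported missing.
#' @export
spectral_params <- function(resample_hz = 200, freq_range_hz = c(1, 80),
                            f0 = 1,
                            bands = list(delta = c(1, 4), theta = c(5, 8),
                                         alpha = c(9, 12), beta = c(13, 30),
                                         gamma = c(31, 80)),
                            notch_exclusion_hz = c(48, 52),
                            min_run_s = 2, min_unmasked_fraction = 0.1) {
  if (resample_hz <= 2 * freq_range_hz[2L])
    stop("resample_hz must exceed twice the top analysis frequency")
  structure(list(resample_hz = resample_hz, freq_range_hz = freq_range_hz,
                 f0 = f0, bands = bands,
                 notch_exclusion_hz = notch_exclusion_hz,
                 min_run_s = min_run_s,
                 min_unmasked_fraction = min_unmasked_fraction),
            class = "spectral_params")
}

#' Anti-aliased resampling of a recording
#'
#' Zero-phase FIR low-pass filtering at 0.8x the target Nyquist frequency
#' followed by rate conversion (plain decimation for integer ratios,
#' polyphase resampling otherwise). A recording already at the target rate
#' passes through unchanged.
#'
#' @param rec an `eeg_recording`.
#' @param target_hz target sampling rate, below `rec$fs`.
#' @return The resampled `eeg_recording`.
#' @export
antialias_resample <- function(rec, target_hz = 200) {
  if (target_hz == rec$fs) return(rec)
  if (target_hz > rec$fs) stop("target_hz must not exceed the sampling rate")
  cutoff <- 0.8 * (target_hz / 2)
  h <- as.numeric(signal::fir1(128L, cutoff / (rec$fs / 2)))
  n <- nrow(rec$samples)
  n2 <- round(n * target_hz / rec$fs)
  smooth <- function(k) stats::nextn(k, c(2, 3, 5)) == k
  if (smooth(n) && smooth(n2)) {
    # zero-phase FIR applied in the frequency domain (|H|^2, the filtfilt
    # response), followed by exact bandlimited rate conversion
    half <- floor(n2 / 2)
    # FIR response sampled on the length-n FFT grid (filtfilt: |H|^2)
    g <- Mod(stats::fft(c(h, numeric(n - length(h)))))[1:(half + 1L)]^2
    out <- apply(rec$samples, 2L, function(x) {
      X <- stats::fft(x)
      n_neg <- n2 - half - 1L
      Y <- c(X[1:(half + 1L)] * g,
             X[(n - n_neg + 1L):n] * rev(g[2:(n_neg + 1L)]))
      Re(stats::fft(Y, inverse = TRUE)) / n
    })
  } else {
    out <- apply(rec$samples, 2L, function(x) {
      y <- signal::filtfilt(h, 1, x)
      ratio <- rec$fs / target_hz
      if (abs(ratio - round(ratio)) < 1e-9) {
        y[seq(1L, length(y), by = round(ratio))]
      } else {
        fr <- as.integer(attr(fractions_int(target_hz, rec$fs), "pq"))
        signal::resample(y, fr[1L], fr[2L])
      }
    })
  }
  out <- as.matrix(out)[seq_len(n2), , drop = FALSE]
  recording(out, fs = target_hz, channel_labels = rec$channel_labels,
            t0 = rec$t0)
}

# small rational approximation p/q = a/b reduced
fractions_int <- function(a, b) {
  g <- function(x, y) if (y == 0) x else g(y, x %% y)
  d <- g(a, b)
  structure(a / b, pq = c(a / d, b / d))
}

gaussian_taper <- function(fs, f0) {
  sigma_t <- 1 / (2 * pi * f0)
  half <- round(4 * sigma_t * fs)
  tt <- (-half:half) / fs
  exp(-0.5 * (tt / sigma_t)^2)
}

#' Gaussian-window short-time Fourier power spectrum
#'
#' Spectrogram of a segment with a Gaussian taper of spectral SD `f0` Hz,
#' hop of half a window, evaluated on the integer 1--80 Hz grid. Power is
#' scaled as one-sided spectral density (uV^2/Hz) so that summing over the
#' full grid approximates the signal variance per unit bandwidth.
#'
#' @param segment numeric signal vector.
#' @param fs sampling rate (Hz).
#' @param params a [spectral_params()].
#' @return List with `power` (frequencies x time windows), `freqs_hz`
#'   (integer grid), `n_windows`.
#' @export
stft_power <- function(segment, fs, params = spectral_params()) {
  w <- gaussian_taper(fs, params$f0)
  L <- length(w)
  hop <- floor(L / 2)
  if (length(segment) < L + hop)
    stop("segment too short for the STFT window")
  starts <- seq(1L, length(segment) - L + 1L, by = hop)
  nfft <- 2L * fs # 0.5 Hz native grid
  mat <- vapply(starts, function(s) {
    seg <- segment[s:(s + L - 1L)] * w
    c(seg, numeric(nfft - L))
  }, numeric(nfft))
  spec <- stats::mvfft(mat)
  freqs_all <- (seq_len(nfft) - 1L) * fs / nfft
  grid <- seq(params$freq_range_hz[1L], params$freq_range_hz[2L])
  idx <- match(grid, round(freqs_all, 6L))
  U <- sum(w^2)
  power <- 2 * Mod(spec[idx, , drop = FALSE])^2 / (fs * U)
  list(power = power, freqs_hz = grid, n_windows = length(starts))
}

band_bins <- function(params) {
  lapply(stats::setNames(names(params$bands), names(params$bands)),
         function(b) {
           e <- params$bands[[b]]
           bins <- seq(e[1L], e[2L])
           if (b == "gamma")
             bins <- setdiff(bins, seq(params$notch_exclusion_hz[1L],
                                       params$notch_exclusion_hz[2L]))
           bins
         })
}

#' Masked per-epoch band powers
#'
#' Resamples the recording, rasterizes the excluded events (SWDs,
#' artifacts, sleep) into a sample mask, and computes, for every 20-min
#' epoch of the session, the Gaussian-window STFT on each unmasked run of
#' at least `min_run_s` seconds. Spectra are averaged over time weighted
#' by run length, and band power is the mean spectral density over the
#' band's integer bins, with 48--52 Hz excluded from gamma. Epochs with
#' less than `min_unmasked_fraction` of unmasked time are reported
#' missing.
#'
#' @param rec an `eeg_recording` (any rate; resampled internally).
#' @param exclude_events event data frame of intervals to exclude.
#' @param exclude_labels labels to exclude (default SWD, artifact, sleep).
#' @param design a [session_design()].
#' @param params a [spectral_params()].
#' @param channel analysis channel.
#' @param pad_s guard band added around excluded intervals (s).
#' @return Data frame with one row per epoch x band: `epoch_index`,
#'   `band`, `power` (uV^2/Hz; `NA` if missing), `fraction_unmasked`.
#' @export
epoch_band_powers <- function(rec, exclude_events,
                              exclude_labels = c("swd", "artifact", "sleep"),
                              design = session_design(),
                              params = spectral_params(), channel = 1L,
                              pad_s = 0) {
  rs <- antialias_resample(rec, params$resample_hz)
  x <- rec_channel(rs, channel)
  fs <- rs$fs
  mask <- rasterize_mask(exclude_events, exclude_labels, rs, pad_s = pad_s)
  bins <- band_bins(params)
  epochs <- epoch_indices(design)
  out <- list()
  for (e in epochs) {
    bd <- epoch_bounds(e, design)
    i0 <- max(1L, floor((bd[1L] - rs$t0) * fs) + 1L)
    i1 <- min(length(x), floor((bd[2L] - rs$t0) * fs))
    if (i1 < i0) next
    sub <- mask[i0:i1]
    frac <- mean(!sub)
    runs <- unmasked_runs(sub)
    runs <- runs[(runs$last - runs$first + 1L) / fs >= params$min_run_s, ,
                 drop = FALSE]
    pows <- stats::setNames(rep(NA_real_, length(bins)), names(bins))
    if (frac >= params$min_unmasked_fraction && nrow(runs)) {
      acc <- 0; wsum <- 0
      for (k in seq_len(nrow(runs))) {
        seg <- x[(i0 + runs$first[k] - 1L):(i0 + runs$last[k] - 1L)]
        if (length(seg) < 2 * length(gaussian_taper(fs, params$f0)) / 2) next
        st <- tryCatch(stft_power(seg, fs, params), error = function(e) NULL)
        if (is.null(st)) next
        wt <- length(seg)
        acc <- acc + rowMeans(st$power) * wt
        wsum <- wsum + wt
      }
      if (wsum > 0) {
        spec <- acc / wsum
        grid <- seq(params$freq_range_hz[1L], params$freq_range_hz[2L])
        for (b in names(bins))
          pows[[b]] <- mean(spec[match(bins[[b]], grid)])
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      epoch_index = e, band = names(bins), power = unname(pows),
      fraction_unmasked = frac, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Normalize band powers to control period and vehicle group
#'
#' Per animal and band, each epoch's power is expressed as a percentage of
#' the mean of that band over the animal's two control epochs; the result
#' is then expressed as a percentage of the vehicle group's mean at the
#' matching epoch. Zero or missing control power propagates as missing.
#'
#' @param table long data frame with columns `animal`, `arm`,
#'   `epoch_index`, `band`, `power`.
#' @param design a [session_design()].
#' @param vehicle_arm name of the vehicle arm in `arm`.
#' @return The table with `pct_control` and `pct_vehicle` columns added.
#' @export
normalize_band_powers <- function(table, design = session_design(),
                                  vehicle_arm = "vehicle") {
  normalize_epoch_values(table, "power", design, vehicle_arm)
}
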