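#' Detection parameters for spike-and-wave discharges
#'
#' Parameters of the semi-automatic SWD detector. The defaults follow the
#' published protocol for GAERS EEG: DC removal with a 0.1 s time constant,
#' an amplitude threshold of k standard deviations above and below the mean
#' of a manually (or automatically) chosen interictal baseline with k in
#' 5--9, grouping of threshold crossings with a 0.2 s maximum onset
#' interval and a 0.4 s maximum continuation interval, amalgamation of
#' putative SWDs less than 0.5 s apart, discarding of events shorter than
#' 1 s, and acceptance only of events with at least 75% of their
#' instantaneous peak frequencies inside 5--12 Hz (which rejects sleep
#' spindles and artifacts).
#'
#' @param hp_time_constant_s DC-removal high-pass time constant (s).
#' @param threshold_sd threshold in baseline SDs; must lie in `[5, 9]`.
#' @param max_onset_interval_s two crossings closer than this open a
#'   putative SWD (s).
#' @param max_continuation_interval_s crossings join an open putative SWD
#'   while consecutive gaps stay below this (s).
#' @param amalgamation_gap_s putative SWDs closer than this are merged (s).
#' @param min_duration_s events shorter than this are discarded (s).
#' @param freq_band_hz inclusive band for the instantaneous-frequency
#'   criterion (Hz).
#' @param min_fraction_in_band minimum fraction of instantaneous
#'   frequencies inside `freq_band_hz`.
#' @param peak_collapse_window_s crossing events (either polarity) closer
#'   than this are collapsed into a single peak, so one spike-wave complex
#'   contributes one peak (s).
#' @return An object of class `"detection_params"`.
#' @export
detection_params <- function(hp_time_constant_s = 0.1, threshold_sd = 6,
                             max_onset_interval_s = 0.2,
                             max_continuation_interval_s = 0.4,
                             amalgamation_gap_s = 0.5, min_duration_s = 1.0,
                             freq_band_hz = c(5, 12),
                             min_fraction_in_band = 0.75,
                             peak_collapse_window_s = 0.06) {
  if (threshold_sd < 5 || threshold_sd > 9)
    stop("threshold_sd must lie in [5, 9]")
  if (min_fraction_in_band <= 0 || min_fraction_in_band > 1)
    stop("min_fraction_in_band must lie in (0, 1]")
  if (max_onset_interval_s > max_continuation_interval_s)
    stop("max_onset_interval_s must not exceed max_continuation_interval_s")
  structure(list(hp_time_constant_s = hp_time_constant_s,
                 threshold_sd = threshold_sd,
                 max_onset_interval_s = max_onset_interval_s,
                 max_continuation_interval_s = max_continuation_interval_s,
                 amalgamation_gap_s = amalgamation_gap_s,
                 min_duration_s = min_duration_s,
                 freq_band_hz = freq_band_hz,
                 min_fraction_in_band = min_fraction_in_band,
                 peak_collapse_window_s = peak_collapse_window_s),
            class = "detection_params")
}

#' DC removal by first-order high-pass filtering
#'
#' Subtracts an exponential running mean with time constant `tau_s` from
#' the signal; equivalent to a first-order high-pass with cutoff
#' `1/(2*pi*tau_s)` (about 1.6 Hz for the default 0.1 s).
#'
#' @param x numeric signal vector.
#' @param fs sampling rate (Hz).
#' @param tau_s time constant (s), > 0.
#' @return Filtered signal of the same length.
#' @export
highpass_dc_remove <- function(x, fs, tau_s = 0.1) {
  if (tau_s <= 0) stop("tau_s must be > 0")
  a <- 1 - exp(-1 / (fs * tau_s))
  m <- stats::filter(a * x, 1 - a, method = "recursive", init = x[1L])
  as.numeric(x - m)
}

#' Baseline statistics of an interictal reference segment
#'
#' Mean and standard deviation of the DC-removed signal over a reference
#' interval of awake, artifact-free, seizure-free EEG; the detection
#' threshold is defined as `threshold_sd` baseline SDs above and below this
#' mean.
#'
#' @param x the DC-removed signal (one channel).
#' @param fs sampling rate (Hz).
#' @param t0 session time of the first sample (s).
#' @param interval numeric `c(start, end)` in session seconds; at least
#'   10 s long and inside the recording.
#' @param ground_truth optional event data frame; a warning is issued if
#'   the interval overlaps any `swd` or `artifact` event.
#' @return List of class `"baseline_stats"` with `interval`, `mean_uv`,
#'   `sd_uv`.
#' @export
baseline_stats <- function(x, fs, t0, interval, ground_truth = NULL) {
  if (diff(interval) < 10) stop("baseline interval must be at least 10 s")
  i0 <- floor((interval[1L] - t0) * fs) + 1L
  i1 <- floor((interval[2L] - t0) * fs)
  if (i0 < 1L || i1 > length(x)) stop("baseline interval outside recording")
  if (!is.null(ground_truth) && nrow(ground_truth)) {
    bad <- ground_truth$label %in% c("swd", "artifact") &
      ground_truth$start_s < interval[2L] & ground_truth$end_s > interval[1L]
    if (any(bad)) warning("baseline interval overlaps SWD/artifact events")
  }
  seg <- x[i0:i1]
  s <- stats::sd(seg)
  if (!is.finite(s) || s < 1e-9) stop("degenerate baseline (zero variance)")
  structure(list(interval = interval, mean_uv = mean(seg), sd_uv = s),
            class = "baseline_stats")
}

#' Automatic selection of a baseline interval
#'
#' Deterministic replacement for the manual selection of an interictal
#' reference segment: the longest interval of the control period that is
#' awake and free of SWDs, artifacts and sleep (according to the supplied
#' annotations) is returned, capped at 120 s from its start. At least 60 s
#' of eligible time must exist.
#'
#' @param rec an `eeg_recording`.
#' @param events annotations used for exclusion (ground truth or previously
#'   marked events); labels `swd`, `artifact`, `sleep` and `spindle` are
#'   excluded.
#' @param design a `session_design`.
#' @param min_s,cap_s minimum required and maximum returned length (s).
#' @return Numeric `c(start, end)` in session seconds.
#' @export
auto_baseline <- function(rec, events, design = session_design(),
                          min_s = 60, cap_s = 120) {
  ctrl <- c(max(design$control_start_s, rec$t0),
            min(design$injection_s, rec$t0 + rec_duration(rec)))
  if (diff(ctrl) < min_s) stop("control period too short for auto baseline")
  ev <- events[events$label %in% c("swd", "artifact", "sleep", "spindle") &
                 events$start_s < ctrl[2L] & events$end_s > ctrl[1L], ,
               drop = FALSE]
  if (nrow(ev) == 0L) {
    gaps <- data.frame(start = ctrl[1L], end = ctrl[2L])
  } else {
    ev <- ev[order(ev$start_s), , drop = FALSE]
    # merge overlapping excluded intervals
    st <- ev$start_s; en <- ev$end_s
    ms <- st[1L]; me <- en[1L]; gs <- numeric(); ge <- numeric()
    if (nrow(ev) > 1L) for (k in 2L:nrow(ev)) {
      if (st[k] <= me) me <- max(me, en[k]) else {
        gs <- c(gs, ms); ge <- c(ge, me); ms <- st[k]; me <- en[k]
      }
    }
    gs <- c(gs, ms); ge <- c(ge, me)
    bounds <- c(ctrl[1L], rbind(pmax(pmin(gs, ctrl[2L]), ctrl[1L]),
                                pmax(pmin(ge, ctrl[2L]), ctrl[1L])), ctrl[2L])
    m <- matrix(bounds, ncol = 2L, byrow = TRUE)
    gaps <- data.frame(start = m[, 1L], end = m[, 2L])
    gaps <- gaps[gaps$end - gaps$start > 0, , drop = FALSE]
  }
  gaps$len <- gaps$end - gaps$start
  gaps <- gaps[gaps$len >= min_s, , drop = FALSE]
  if (nrow(gaps) == 0L)
    stop("no eligible baseline interval of >= ", min_s,
         " s in the control period; supply one manually")
  best <- gaps[which.max(gaps$len), ]
  c(best$start, min(best$start + cap_s, best$end))
}

#' Threshold-crossing peak events
#'
#' Finds contiguous excursions of the DC-removed signal above
#' `mean + k*sd` or below `mean - k*sd`; each excursion contributes one
#' event at its onset time, tagged with its polarity. Both polarities are
#' merged into one time-sorted stream, and events within
#' `collapse_window_s` of the previously kept event are collapsed into it,
#' so that one spike-wave complex yields a single peak.
#'
#' @param x DC-removed signal.
#' @param fs sampling rate (Hz).
#' @param t0 session time of first sample (s).
#' @param baseline a `"baseline_stats"` object.
#' @param k threshold in baseline SDs.
#' @param collapse_window_s collapse window (s).
#' @return Numeric vector of peak times in session seconds.
#' @export
detect_crossings <- function(x, fs, t0, baseline, k = 6,
                             collapse_window_s = 0.06) {
  hi <- baseline$mean_uv + k * baseline$sd_uv
  lo <- baseline$mean_uv - k * baseline$sd_uv
  onsets <- function(cond) {
    d <- diff(c(FALSE, cond))
    which(d == 1L)
  }
  idx <- sort(c(onsets(x > hi), onsets(x < lo)))
  if (length(idx) == 0L) return(numeric())
  times <- t0 + (idx - 1L) / fs
  collapse_peaks(times, collapse_window_s)
}

collapse_peaks <- function(times, window_s) {
  if (length(times) <= 1L) return(times)
  keep <- numeric(length(times))
  keep[1L] <- times[1L]
  m <- 1L
  for (t in times[-1L]) {
    if (t - keep[m] >= window_s) {
      m <- m + 1L
      keep[m] <- t
    }
  }
  keep[seq_len(m)]
}

#' Group peak events into putative SWDs
#'
#' A putative SWD opens when two consecutive peaks are separated by less
#' than the maximum onset interval; further peaks are incorporated while
#' each consecutive gap stays below the maximum continuation interval. The
#' event closes at the last incorporated peak. Start and end are the first
#' and last peak, extended by half the peak collapse window on each side.
#'
#' @param peaks time-sorted peak times (s).
#' @param max_onset_s maximum onset interval (s).
#' @param max_continuation_s maximum continuation interval (s).
#' @param edge_pad_s extension applied to both ends (s); half the peak
#'   collapse window by default.
#' @return List of putative SWDs, each a list with `start_s`, `end_s`,
#'   `peak_times_s`.
#' @export
group_crossings <- function(peaks, max_onset_s = 0.2, max_continuation_s = 0.4,
                            edge_pad_s = 0.03) {
  out <- list()
  n <- length(peaks)
  i <- 1L
  while (i < n) {
    if (peaks[i + 1L] - peaks[i] < max_onset_s) {
      j <- i + 1L
      while (j < n && peaks[j + 1L] - peaks[j] < max_continuation_s) j <- j + 1L
      out[[length(out) + 1L]] <- list(
        start_s = peaks[i] - edge_pad_s,
        end_s = peaks[j] + edge_pad_s,
        peak_times_s = peaks[i:j])
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Amalgamate nearby putative SWDs
#'
#' Merges consecutive putative SWDs whose inter-event gap is below
#' `gap_s`, concatenating their peaks; merging is applied iteratively until
#' a fixed point is reached, so chains of closely spaced events collapse
#' into one.
#'
#' @param putatives list of putative SWDs (see [group_crossings()]).
#' @param gap_s amalgamation gap (s).
#' @return List of putative SWDs.
#' @export
amalgamate <- function(putatives, gap_s = 0.5) {
  repeat {
    n <- length(putatives)
    if (n <= 1L) return(putatives)
    merged <- list(putatives[[1L]])
    changed <- FALSE
    for (k in 2L:n) {
      last <- merged[[length(merged)]]
      cur <- putatives[[k]]
      if (cur$start_s - last$end_s < gap_s) {
        last$end_s <- max(last$end_s, cur$end_s)
        last$peak_times_s <- c(last$peak_times_s, cur$peak_times_s)
        merged[[length(merged)]] <- last
        changed <- TRUE
      } else {
        merged[[length(merged) + 1L]] <- cur
      }
    }
    putatives <- merged
    if (!changed) return(putatives)
  }
}

#' Discard putative SWDs shorter than a minimum duration
#'
#' Events with `end_s - start_s >= min_s` are kept (the boundary is
#' inclusive: a duration of exactly `min_s` survives).
#'
#' @param putatives list of putative SWDs.
#' @param min_s minimum duration (s).
#' @export
duration_filter <- function(putatives, min_s = 1.0) {
  Filter(function(p) (p$end_s - p$start_s) >= min_s - 1e-9, putatives)
}

#' Instantaneous-frequency selection criterion
#'
#' Instantaneous frequencies are the reciprocals of the intervals between
#' consecutive peaks. An event is accepted if at least `min_frac` of them
#' lie inside `band` (inclusive at both edges); this discriminates genuine
#' ~7 Hz spike-and-wave trains from sleep spindles (~10--14 Hz) and
#' broadband artifacts. Events with fewer than two peaks are rejected with
#' `frac_in_band = 0`.
#'
#' @param putative one putative SWD.
#' @param band inclusive frequency band `c(lo, hi)` in Hz.
#' @param min_frac minimum in-band fraction.
#' @return The putative SWD with fields `instantaneous_freqs_hz`,
#'   `frac_in_band` and `accepted` added.
#' @export
frequency_criterion <- function(putative, band = c(5, 12), min_frac = 0.75) {
  pk <- putative$peak_times_s
  if (length(pk) < 2L) {
    putative$instantaneous_freqs_hz <- numeric()
    putative$frac_in_band <- 0
    putative$accepted <- FALSE
    return(putative)
  }
  f <- 1 / diff(pk)
  frac <- mean(f >= band[1L] & f <= band[2L])
  putative$instantaneous_freqs_hz <- f
  putative$frac_in_band <- frac
  putative$accepted <- frac >= min_frac
  putative
}

#' Detect spike-and-wave discharges in a recording
#'
#' Runs the full semi-automatic detection pipeline on one channel:
#' DC removal, baseline statistics, threshold-crossing peak events,
#' grouping, amalgamation, minimum-duration filtering, and the
#' instantaneous-frequency criterion -- in exactly that order. Only
#' accepted events are returned.
#'
#' @param rec an `eeg_recording`.
#' @param params a [detection_params()] object.
#' @param baseline either a numeric interval `c(start, end)` in session
#'   seconds, or `"auto"` to select one with [auto_baseline()] (which then
#'   requires `events`).
#' @param events annotations used only for automatic baseline selection
#'   (the algorithmic stand-in for the analyst's manual choice of a clean
#'   awake segment); not used by the detector itself.
#' @param channel analysis channel (index or label).
#' @return A `"swd_events"` data frame of accepted SWDs with per-event
#'   attributes (`n_peaks`, `frac_in_band`, `accepted`). The detection
#'   report -- baseline interval, mean/SD, and the number of candidates
#'   surviving each stage -- is attached as attribute `"report"`.
#' @export
detect_swds <- function(rec, params = detection_params(), baseline = "auto",
                        events = NULL, channel = 1L) {
  x <- highpass_dc_remove(rec_channel(rec, channel), rec$fs,
                          params$hp_time_constant_s)
  if (identical(baseline, "auto")) {
    if (is.null(events))
      stop("baseline = 'auto' requires annotation events for exclusion")
    baseline <- auto_baseline(rec, events)
  }
  bl <- baseline_stats(x, rec$fs, rec$t0, baseline)
  peaks <- detect_crossings(x, rec$fs, rec$t0, bl, params$threshold_sd,
                            params$peak_collapse_window_s)
  grouped <- group_crossings(peaks, params$max_onset_interval_s,
                             params$max_continuation_interval_s,
                             edge_pad_s = params$peak_collapse_window_s / 2)
  amal <- amalgamate(grouped, params$amalgamation_gap_s)
  long <- duration_filter(amal, params$min_duration_s)
  judged <- lapply(long, frequency_criterion, band = params$freq_band_hz,
                   min_frac = params$min_fraction_in_band)
  acc <- Filter(function(p) p$accepted, judged)
  out <- event_list(
    start_s = vapply(acc, `[[`, 0, "start_s"),
    end_s = vapply(acc, `[[`, 0, "end_s"),
    label = rep("swd", length(acc)),
    n_peaks = vapply(acc, function(p) length(p$peak_times_s), 0L),
    frac_in_band = vapply(acc, `[[`, 0, "frac_in_band"),
    accepted = rep(TRUE, length(acc)))
  attr(out, "report") <- list(
    baseline_interval = bl$interval, baseline_mean_uv = bl$mean_uv,
    baseline_sd_uv = bl$sd_uv, threshold_sd = params$threshold_sd,
    n_peaks = length(peaks), n_putative = length(grouped),
    n_amalgamated = length(amal), n_min_duration = length(long),
    n_accepted = length(acc))
  out
}

#' Match detected events against ground truth
#'
#' Greedy one-to-one matching by decreasing intersection-over-union (IoU);
#' a pair is matched when its IoU reaches `min_iou`. Used to score detector
#' precision and recall against the synthetic generator's ground truth.
#'
#' @param detected,truth event data frames (intervals in seconds).
#' @param min_iou minimum IoU for a match.
#' @return List with `n_detected`, `n_truth`, `n_matched`, `precision`,
#'   `recall`, and the matched index pairs.
#' @export
match_events <- function(detected, truth, min_iou = 0.5) {
  nd <- nrow(detected); nt <- nrow(truth)
  pairs <- NULL
  if (nd && nt) {
    for (i in seq_len(nd)) {
      ov_lo <- pmax(detected$start_s[i], truth$start_s)
      ov_hi <- pmin(detected$end_s[i], truth$end_s)
      inter <- pmax(0, ov_hi - ov_lo)
      uni <- (detected$end_s[i] - detected$start_s[i]) +
        (truth$end_s - truth$start_s) - inter
      iou <- inter / uni
      j <- which(iou >= min_iou)
      if (length(j))
        pairs <- rbind(pairs, cbind(i = i, j = j, iou = iou[j]))
    }
  }
  matched <- matrix(numeric(), ncol = 3L)
  if (!is.null(pairs)) {
    pairs <- pairs[order(-pairs[, "iou"]), , drop = FALSE]
    used_i <- logical(nd); used_j <- logical(nt)
    keep <- logical(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, "i"]; j <- pairs[k, "j"]
      if (!used_i[i] && !used_j[j]) {
        keep[k] <- TRUE; used_i[i] <- TRUE; used_j[j] <- TRUE
      }
    }
    matched <- pairs[keep, , drop = FALSE]
  }
  m <- nrow(matched)
  list(n_detected = nd, n_truth = nt, n_matched = m,
       precision = if (nd) m / nd else NA_real_,
       recall = if (nt) m / nt else NA_real_,
       matches = matched)
}
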