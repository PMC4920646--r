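EVENT_LABELS <- c("swd", "spindle", "artifact", "sleep")
EVENT_COLS <- c("start_s", "end_s", "label", "n_peaks", "frac_in_band",
                "mean_wavelet_freq_hz", "accepted")

#' Event lists
#'
#' An event list is a data frame of half-open time intervals
#' `[start_s, end_s)` in session seconds, each carrying a label
#' (`swd`, `spindle`, `artifact` or `sleep`) and optional per-event
#' attributes: number of detected peaks, fraction of instantaneous
#' frequencies inside the SWD band, mean wavelet peak frequency, and an
#' acceptance flag. Events are kept sorted by start time; within one label
#' they must not overlap. Times are stored at 1 ms resolution.
#'
#' @param start_s,end_s numeric vectors of interval bounds in seconds.
#' @param label character vector of labels.
#' @param n_peaks,frac_in_band,mean_wavelet_freq_hz,accepted optional
#'   per-event attributes.
#' @return A sorted, validated data frame of class `"swd_events"`.
#' @export
event_list <- function(start_s = numeric(), end_s = numeric(),
                       label = character(), n_peaks = NA_integer_,
                       frac_in_band = NA_real_,
                       mean_wavelet_freq_hz = NA_real_, accepted = NA) {
  n <- length(start_s)
  rec_n <- function(v) rep_len(v, n)
  n_peaks <- rec_n(n_peaks); frac_in_band <- rec_n(frac_in_band)
  mean_wavelet_freq_hz <- rec_n(mean_wavelet_freq_hz)
  accepted <- rec_n(accepted)
  df <- data.frame(
    start_s = round(as.numeric(start_s), 3L),
    end_s = round(as.numeric(end_s), 3L),
    label = as.character(label),
    n_peaks = as.integer(n_peaks),
    frac_in_band = as.numeric(frac_in_band),
    mean_wavelet_freq_hz = as.numeric(mean_wavelet_freq_hz),
    accepted = as.logical(accepted),
    stringsAsFactors = FALSE)
  validate_events(df)
}

validate_events <- function(df) {
  stopifnot(all(EVENT_COLS %in% names(df)))
  df <- df[EVENT_COLS]
  if (nrow(df)) {
    if (!all(df$label %in% EVENT_LABELS))
      stop("unknown event label(s): ",
           paste(setdiff(df$label, EVENT_LABELS), collapse = ", "))
    if (any(df$start_s >= df$end_s)) stop("events must satisfy start_s < end_s")
    df <- df[order(df$start_s, df$end_s), , drop = FALSE]
    rownames(df) <- NULL
    for (lb in unique(df$label)) {
      e <- df[df$label == lb, ]
      if (nrow(e) > 1L && any(e$start_s[-1L] < e$end_s[-nrow(e)] - 1e-9))
        stop("overlapping events within label '", lb, "'")
    }
  }
  class(df) <- c("swd_events", "data.frame")
  df
}

#' @rdname event_list
#' @param events an event data frame.
#' @param labels labels to keep.
#' @export
filter_events <- function(events, labels) {
  validate_events(events[events$label %in% labels, , drop = FALSE])
}

#' Read and write event CSV files
#'
#' Events are stored as CSV with the fixed header
#' `start_s,end_s,label,n_peaks,frac_in_band,mean_wavelet_freq_hz,accepted`.
#' Times are written at 1 ms resolution so that a write/read round trip is
#' lossless. Files read back are validated and returned sorted by start
#' time.
#'
#' @param events an event data frame (see [event_list()]).
#' @param path CSV file path.
#' @return `read_events()` returns a `"swd_events"` data frame;
#'   `write_events()` returns `path` invisibly.
#' @export
write_events <- function(events, path) {
  events <- validate_events(as.data.frame(events))
  out <- events
  out$start_s <- sprintf("%.3f", out$start_s)
  out$end_s <- sprintf("%.3f", out$end_s)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(start_s = "numeric", end_s = "numeric",
                                       label = "character"))
  if (!all(c("start_s", "end_s", "label") %in% names(df)))
    stop("not an event CSV (missing required columns)")
  for (col in EVENT_COLS) if (is.null(df[[col]])) df[[col]] <- NA
  df$n_peaks <- as.integer(df$n_peaks)
  df$frac_in_band <- as.numeric(df$frac_in_band)
  df$mean_wavelet_freq_hz <- as.numeric(df$mean_wavelet_freq_hz)
  df$accepted <- as.logical(df$accepted)
  validate_events(df)
}

#' Rasterize events into a sample mask
#'
#' Marks every sample of a recording whose time lies inside `[start_s,
#' end_s)` of any event carrying one of the requested labels. Intervals are
#' clipped to the recording span. An optional guard band `pad_s` widens
#' every interval on both sides before rasterization (used to protect
#' spectral estimates from event-edge leakage).
#'
#' @param events an event data frame.
#' @param labels labels to rasterize (default: all present).
#' @param rec the `eeg_recording` the mask is aligned to.
#' @param pad_s symmetric padding added to each interval, in seconds.
#' @return An object of class `"sample_mask"`: logical vector (`TRUE` =
#'   masked/excluded) with attributes `fs`, `t0` and `provenance` (the
#'   labels that were rasterized).
#' @export
rasterize_mask <- function(events, labels = NULL, rec, pad_s = 0) {
  n <- nrow(rec$samples)
  mask <- logical(n)
  if (is.null(labels)) labels <- unique(events$label)
  ev <- events[events$label %in% labels, , drop = FALSE]
  if (nrow(ev)) {
    # sample i (1-based) covers time t0 + (i-1)/fs
    i0 <- ceiling((ev$start_s - pad_s - rec$t0) * rec$fs - 1e-9) + 1L
    i1 <- ceiling((ev$end_s + pad_s - rec$t0) * rec$fs - 1e-9) # last sample < end
    i0 <- pmax(i0, 1L)
    i1 <- pmin(i1, n)
    for (k in seq_len(nrow(ev))) if (i0[k] <= i1[k]) mask[i0[k]:i1[k]] <- TRUE
  }
  structure(mask, fs = rec$fs, t0 = rec$t0, provenance = labels,
            class = "sample_mask")
}

#' Unmasked runs of a sample mask
#'
#' Returns the maximal contiguous unmasked runs as sample index ranges.
#' @param mask a `"sample_mask"` (or plain logical vector, `TRUE` = masked).
#' @return data frame with columns `first`, `last` (1-based sample indices).
#' @export
unmasked_runs <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !r$values
  data.frame(first = starts[keep], last = ends[keep])
}
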