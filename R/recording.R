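#' EEG recording container
#'
#' A `Recording` holds one or more equal-length channels of continuous EEG in
#' microvolts, the sampling rate, and the session time of the first sample.
#' Session time is defined with the injection of the agonist (or vehicle) at
#' t = 0 s, so a standard session starts at t0 = -2400 s (40-min control
#' period) and ends at 7200 s (2-h treatment period).
#'
#' @param samples numeric vector (single channel) or matrix with one column
#'   per channel, in microvolts. Must be finite.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector of channel names; defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @param t0 session time of the first sample in seconds.
#' @return An object of class `"eeg_recording"` with fields `samples`
#'   (matrix, channels in columns), `fs`, `channel_labels`, `t0`.
#' @export
recording <- function(samples, fs, channel_labels = NULL, t0 = 0) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  if (is.vector(samples)) samples <- matrix(as.numeric(samples), ncol = 1L)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (anyNA(samples) || !all(is.finite(samples)))
    stop("samples must be finite (no NA/NaN/Inf)")
  if (is.null(channel_labels))
    channel_labels <- if (!is.null(colnames(samples))) colnames(samples)
      else paste0("ch", seq_len(ncol(samples)))
  if (length(channel_labels) != ncol(samples))
    stop("channel_labels length must match number of channels")
  structure(
    list(samples = samples, fs = fs,
         channel_labels = as.character(channel_labels), t0 = as.numeric(t0)),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz\n",
              ncol(x$samples), n, x$fs))
  cat(sprintf("  span: [%.3f, %.3f) s session time; channels: %s\n",
              x$t0, x$t0 + n / x$fs, paste(x$channel_labels, collapse = ", ")))
  invisible(x)
}

#' Number of samples and duration of a recording
#' @param rec an `eeg_recording`.
#' @return `n_samples`: integer sample count; `rec_duration`: seconds.
#' @export
n_samples <- function(rec) nrow(rec$samples)

#' @rdname n_samples
#' @export
rec_duration <- function(rec) nrow(rec$samples) / rec$fs

#' Extract one analysis channel as a numeric vector
#' @param rec an `eeg_recording`.
#' @param channel column index or channel label.
#' @export
rec_channel <- function(rec, channel = 1L) {
  if (is.character(channel)) {
    channel <- match(channel, rec$channel_labels)
    if (is.na(channel)) stop("unknown channel label")
  }
  rec$samples[, channel]
}

#' Sample times of a recording in session seconds
#' @param rec an `eeg_recording`.
#' @export
rec_times <- function(rec) rec$t0 + (seq_len(nrow(rec$samples)) - 1L) / rec$fs

#' Session design: timeline of the injection protocol
#'
#' Encodes the experimental timeline: a 40-min control period ending at the
#' injection of the drug or vehicle (t = 0), an optional antagonist
#' pre-injection 10 min before that, and a 2-h treatment period, all
#' quantified in 20-min epochs aligned to the injection.
#'
#' @param control_start_s start of the control period (default -2400).
#' @param injection_s injection time defining t = 0.
#' @param antagonist_injection_s optional antagonist pre-injection time
#'   (default -600; informational only).
#' @param treatment_end_s end of the treatment period (default 7200).
#' @param epoch_length_s epoch length in seconds (default 1200).
#' @return An object of class `"session_design"`.
#' @export
session_design <- function(control_start_s = -2400, injection_s = 0,
                           antagonist_injection_s = -600,
                           treatment_end_s = 7200, epoch_length_s = 1200) {
  d <- list(control_start_s = control_start_s, injection_s = injection_s,
            antagonist_injection_s = antagonist_injection_s,
            treatment_end_s = treatment_end_s, epoch_length_s = epoch_length_s)
  span_ctrl <- injection_s - control_start_s
  span_trt <- treatment_end_s - injection_s
  if (span_ctrl <= 0 || span_trt <= 0 || epoch_length_s <= 0)
    stop("inconsistent session design")
  if (span_ctrl %% epoch_length_s != 0 || span_trt %% epoch_length_s != 0)
    stop("control and treatment windows must be whole numbers of epochs")
  class(d) <- "session_design"
  d
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf("<session_design> control [%g, %g) s, treatment [%g, %g) s, epochs of %g s\n",
              x$control_start_s, x$injection_s, x$injection_s,
              x$treatment_end_s, x$epoch_length_s))
  invisible(x)
}

#' Epoch indices of a session design
#'
#' Epochs are indexed relative to the injection: the two control epochs are
#' -2 and -1, the six treatment epochs 0..5 (for the default design).
#' `epoch_index()` maps session times to epoch indices (`NA` outside the
#' session window); `epoch_bounds()` returns the half-open `[start, end)`
#' interval of one epoch.
#'
#' @param design a `session_design`.
#' @param t numeric vector of session times in seconds.
#' @export
epoch_index <- function(t, design = session_design()) {
  idx <- floor((t - design$injection_s) / design$epoch_length_s)
  lo <- (design$control_start_s - design$injection_s) / design$epoch_length_s
  hi <- (design$treatment_end_s - design$injection_s) / design$epoch_length_s
  idx[t < design$control_start_s | t >= design$treatment_end_s] <- NA_real_
  idx[!is.na(idx) & (idx < lo | idx >= hi)] <- NA_real_
  as.integer(idx)
}

#' @rdname epoch_index
#' @param index integer epoch index.
#' @export
epoch_bounds <- function(index, design = session_design()) {
  start <- design$injection_s + index * design$epoch_length_s
  c(start, start + design$epoch_length_s)
}

#' @rdname epoch_index
#' @export
epoch_indices <- function(design = session_design()) {
  lo <- (design$control_start_s - design$injection_s) / design$epoch_length_s
  hi <- (design$treatment_end_s - design$injection_s) / design$epoch_length_s
  seq.int(lo, hi - 1L)
}

#' @rdname epoch_index
#' @export
control_epochs <- function(design = session_design()) {
  idx <- epoch_indices(design)
  idx[idx < 0L]
}

#' @rdname epoch_index
#' @export
treatment_epochs <- function(design = session_design()) {
  idx <- epoch_indices(design)
  idx[idx >= 0L]
}

# ---- file I/O ----------------------------------------------------------

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Read and write EEG recordings
#'
#' Two on-disk formats are supported: `"edf"`, a minimal European Data
#' Format file (16-bit samples, 1-s data records; the session time of the
#' first sample is stored in the reserved header field), and `"raw"`, a
#' float32 little-endian binary (channels stored sequentially) next to a
#' JSON sidecar `<path>.json` holding `fs`, `channel_labels`, `t0` and `n`.
#' EDF is quantized to the 16-bit physical range of each channel; the raw
#' format is quantized to float32.
#'
#' @param path file path. For `"raw"` the sidecar is `<path>.json`.
#' @param format `"edf"` or `"raw"`.
#' @param rec an `eeg_recording` to write.
#' @return `read_recording()` returns an `eeg_recording`;
#'   `write_recording()` returns `path` invisibly.
#' @export
read_recording <- function(path, format = c("edf", "raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  rec <- switch(format, edf = read_edf(path), raw = read_raw_recording(path))
  if (anyNA(rec$samples) || !all(is.finite(rec$samples)))
    stop("recording contains non-finite samples")
  rec
}

#' @rdname read_recording
#' @export
write_recording <- function(rec, path, format = c("edf", "raw")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "eeg_recording"))
  switch(format, edf = write_edf(rec, path), raw = write_raw_recording(rec, path))
  invisible(path)
}

write_raw_recording <- function(rec, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$samples), con, size = 4L, endian = "little")
  jsonlite::write_json(
    list(fs = rec$fs, channel_labels = rec$channel_labels, t0 = rec$t0,
         n = nrow(rec$samples), n_channels = ncol(rec$samples)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_raw_recording <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing JSON sidecar header: ", sidecar)
  hdr <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("fs", "t0", "n", "n_channels")
  if (!all(need %in% names(hdr))) stop("sidecar header incomplete")
  n_total <- as.integer(hdr$n) * as.integer(hdr$n_channels)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n_total, size = 4L, endian = "little")
  if (length(x) != n_total) stop("raw file shorter than header declares")
  recording(matrix(x, ncol = hdr$n_channels),
            fs = hdr$fs, channel_labels = hdr$channel_labels, t0 = hdr$t0)
}

write_edf <- function(rec, path) {
  ns <- ncol(rec$samples)
  n <- nrow(rec$samples)
  if (abs(rec$fs - round(rec$fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(rec$fs))
  if (n %% fs != 0)
    stop("EDF writer requires a whole number of 1-s data records")
  n_rec <- n %/% fs
  pmin_ <- apply(rec$samples, 2L, min)
  pmax_ <- apply(rec$samples, 2L, max)
  degenerate <- pmax_ - pmin_ < 1e-12
  pmin_[degenerate] <- pmin_[degenerate] - 1
  pmax_[degenerate] <- pmax_[degenerate] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8L),
    pad_field("X X X X", 80L),
    pad_field("synthetic EEG", 80L),
    pad_field("01.01.26", 8L), pad_field("00.00.00", 8L),
    pad_field(256L + ns * 256L, 8L),
    pad_field(sprintf("t0=%.3f", rec$t0), 44L),
    pad_field(n_rec, 8L),
    pad_field("1", 8L),
    pad_field(ns, 4L))
  writeChar(hdr, con, eos = NULL)
  writeChar(paste0(vapply(rec$channel_labels, pad_field, "", width = 16L),
                   collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad_field("EEG", 80L), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad_field("uV", 8L), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(pmin_, function(v) pad_field(sprintf("%.8g", v), 8L), ""),
                   collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(pmax_, function(v) pad_field(sprintf("%.8g", v), 8L), ""),
                   collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad_field("-32768", 8L), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad_field("32767", 8L), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(pad_field("", 80L), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(rep(fs, ns), pad_field, "", width = 8L), collapse = ""),
            con, eos = NULL)
  writeChar(paste0(rep(pad_field("", 32L), ns), collapse = ""), con, eos = NULL)
  # digital conversion per channel
  dig <- matrix(0L, nrow = n, ncol = ns)
  for (j in seq_len(ns)) {
    g <- (pmax_[j] - pmin_[j]) / (32767 - (-32768))
    dig[, j] <- as.integer(round((rec$samples[, j] - pmin_[j]) / g) - 32768L)
  }
  dig[dig > 32767L] <- 32767L
  dig[dig < -32768L] <- -32768L
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(as.vector(dig[idx, , drop = FALSE])), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf_field <- function(raw_hdr, offset, width) {
  trimws(rawToChar(raw_hdr[(offset + 1L):(offset + width)]))
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 256L)
  if (length(hdr) < 256L) stop("unreadable EDF header (file too short)")
  n_hdr <- suppressWarnings(as.integer(read_edf_field(hdr, 184L, 8L)))
  reserved <- read_edf_field(hdr, 192L, 44L)
  n_rec <- suppressWarnings(as.integer(read_edf_field(hdr, 236L, 8L)))
  dur <- suppressWarnings(as.numeric(read_edf_field(hdr, 244L, 8L)))
  ns <- suppressWarnings(as.integer(read_edf_field(hdr, 252L, 4L)))
  if (anyNA(c(n_hdr, n_rec, dur, ns)) || ns < 1L)
    stop("unreadable EDF header")
  sig <- readBin(con, "raw", n = ns * 256L)
  if (length(sig) < ns * 256L) stop("unreadable EDF signal headers")
  fld <- function(off_per, width, skip) {
    vapply(seq_len(ns) - 1L, function(j)
      read_edf_field(sig, skip * ns + j * width, width), "")
  }
  labels <- fld(0L, 16L, 0L)
  # layout after labels: transducer 80, physdim 8, physmin 8, physmax 8,
  # digmin 8, digmax 8, prefilter 80, nsamp 8, reserved 32
  off <- function(widths) sum(widths) # cumulative byte offset helper
  base <- 16L * ns
  physmin <- as.numeric(vapply(seq_len(ns) - 1L, function(j)
    read_edf_field(sig, base + 80L * ns + 8L * ns + j * 8L, 8L), ""))
  physmax <- as.numeric(vapply(seq_len(ns) - 1L, function(j)
    read_edf_field(sig, base + 80L * ns + 16L * ns + j * 8L, 8L), ""))
  digmin <- as.numeric(vapply(seq_len(ns) - 1L, function(j)
    read_edf_field(sig, base + 80L * ns + 24L * ns + j * 8L, 8L), ""))
  digmax <- as.numeric(vapply(seq_len(ns) - 1L, function(j)
    read_edf_field(sig, base + 80L * ns + 32L * ns + j * 8L, 8L), ""))
  nsamp <- as.integer(vapply(seq_len(ns) - 1L, function(j)
    read_edf_field(sig, base + 80L * ns + 40L * ns + 80L * ns + j * 8L, 8L), ""))
  if (anyNA(c(physmin, physmax, digmin, digmax, nsamp)))
    stop("unreadable EDF signal headers")
  if (length(unique(nsamp / dur)) != 1L)
    stop("channels with unequal sampling rates are not supported")
  fs <- nsamp[1L] / dur
  n <- n_rec * nsamp[1L]
  out <- matrix(0, nrow = n, ncol = ns)
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      d <- readBin(con, "integer", n = nsamp[j], size = 2L,
                   signed = TRUE, endian = "little")
      if (length(d) != nsamp[j]) stop("EDF data truncated")
      g <- (physmax[j] - physmin[j]) / (digmax[j] - digmin[j])
      out[((r - 1L) * nsamp[j] + 1L):(r * nsamp[j]), j] <-
        physmin[j] + (d - digmin[j]) * g
    }
  }
  t0 <- 0
  m <- regmatches(reserved, regexec("t0=(-?[0-9.]+)", reserved))[[1L]]
  if (length(m) == 2L) t0 <- as.numeric(m[2L])
  recording(out, fs = fs, channel_labels = labels, t0 = t0)
}
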