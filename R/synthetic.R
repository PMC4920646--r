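# Frequency bands used by the background generator. Each band component is
# 1/f-shaped noise, band-limited to [lo, hi) Hz, scaled to the given awake
# standard deviation (microvolts). Edges sit between the integer analysis
# bins so that scaling a component scales the corresponding analysis band.
GEN_BANDS <- list(
  delta = list(lo = 0.5, hi = 4.5, sd_uv = 18),
  theta = list(lo = 4.5, hi = 8.5, sd_uv = 16),
  alpha = list(lo = 8.5, hi = 12.5, sd_uv = 12),
  beta  = list(lo = 12.5, hi = 30.5, sd_uv = 9),
  gamma = list(lo = 30.5, hi = 80.5, sd_uv = 7))

BAND_NAMES <- names(GEN_BANDS)

#' SWD waveform shape parameters
#'
#' Morphology of a synthetic spike-and-wave cycle: a sharp high-amplitude
#' spike occupying `spike_fraction` of each cycle, followed within the
#' cycle by the trough of a slower wave at the cycle frequency (harmonic-
#' sharpened by the optional 2f/3f components), with a
#' linear amplitude ramp at onset and offset. The default cycle frequency
#' is the GAERS population value of 6.90 Hz. Default amplitudes put the
#' spike at roughly 8x the DC-removed awake background SD (about 31 uV at
#' the default background), comfortably above the 5--9 SD detection
#' threshold window, as in real GAERS EEG where SWDs dominate the trace.
#'
#' @param cycle_freq_hz spike-and-wave cycle frequency (Hz).
#' @param spike_fraction fraction of the cycle occupied by the spike
#'   (FWHM of the spike bump).
#' @param spike_amp_uv spike amplitude (uV).
#' @param wave_amp_uv wave (fundamental sinusoid) amplitude (uV).
#' @param harmonics amplitude ratios of the 2f and 3f components relative
#'   to `wave_amp_uv`.
#' @param ramp_s onset/offset amplitude ramp (s).
#' @export
swd_shape_params <- function(cycle_freq_hz = 6.90, spike_fraction = 0.2,
                             spike_amp_uv = 250, wave_amp_uv = 150,
                             harmonics = c(0.15, 0.05), ramp_s = 0.2) {
  if (cycle_freq_hz <= 0) stop("cycle_freq_hz must be positive")
  structure(list(cycle_freq_hz = cycle_freq_hz,
                 spike_fraction = spike_fraction,
                 spike_amp_uv = spike_amp_uv, wave_amp_uv = wave_amp_uv,
                 harmonics = harmonics, ramp_s = ramp_s),
            class = "swd_shape_params")
}

#' Seizure point-process parameters
#'
#' Seizure starts follow an inhomogeneous Poisson process with a fixed
#' refractory gap after each seizure; durations are drawn from a gamma
#' distribution moment-matched to the GAERS population mean of 16.1 s and
#' SD of 14.3 s, truncated below at 1 s.
#'
#' @param rate_per_min baseline seizure initiation rate (events/min).
#' @param duration_family only `"gamma"` is implemented.
#' @param duration_mean_s,duration_sd_s moments of the (untruncated)
#'   duration distribution (s).
#' @param duration_min_s truncation floor (s).
#' @param refractory_s minimum gap between the end of one seizure and the
#'   start of the next (s).
#' @export
seizure_process_params <- function(rate_per_min = 0.75,
                                   duration_family = "gamma",
                                   duration_mean_s = 16.1,
                                   duration_sd_s = 14.3,
                                   duration_min_s = 1, refractory_s = 5) {
  if (rate_per_min <= 0) stop("rate_per_min must be positive")
  if (!identical(duration_family, "gamma"))
    stop("only the gamma duration family is implemented")
  structure(list(rate_per_min = rate_per_min,
                 duration_family = duration_family,
                 duration_mean_s = duration_mean_s,
                 duration_sd_s = duration_sd_s,
                 duration_min_s = duration_min_s,
                 refractory_s = refractory_s),
            class = "seizure_process_params")
}

# mean of the truncated duration distribution
truncated_duration_mean <- function(process) {
  shape <- (process$duration_mean_s / process$duration_sd_s)^2
  scale <- process$duration_sd_s^2 / process$duration_mean_s
  a <- process$duration_min_s
  num <- process$duration_mean_s *
    stats::pgamma(a, shape + 1, scale = scale, lower.tail = FALSE)
  num / stats::pgamma(a, shape, scale = scale, lower.tail = FALSE)
}

draw_durations <- function(n, process) {
  shape <- (process$duration_mean_s / process$duration_sd_s)^2
  scale <- process$duration_sd_s^2 / process$duration_mean_s
  out <- stats::rgamma(n, shape, scale = scale)
  while (any(short <- out < process$duration_min_s))
    out[short] <- stats::rgamma(sum(short), shape, scale = scale)
  out
}

#' Parametric drug-effect model
#'
#' Injection-locked effect kinetics: every effect is zero before the
#' injection (t = 0), rises linearly over `onset_s`, and then stays on its
#' plateau (optionally decaying exponentially with time constant
#' `washout_s`). At plateau, the seizure initiation rate is multiplied by
#' `rate_multiplier`, sampled seizure durations by `duration_multiplier`,
#' the SWD cycle frequency is shifted by `cycle_freq_shift_hz`, and each
#' interictal background band amplitude is multiplied by its entry of
#' `band_amp_multipliers`.
#'
#' @param rate_multiplier,duration_multiplier plateau multipliers (>= 0).
#' @param cycle_freq_shift_hz plateau shift of the SWD cycle frequency (Hz).
#' @param band_amp_multipliers named numeric (delta..gamma) of plateau
#'   amplitude multipliers for the background band components.
#' @param onset_s linear onset time (s).
#' @param washout_s optional exponential washout time constant (s);
#'   `Inf` (default) keeps the plateau for the whole treatment period.
#' @export
drug_effect_model <- function(rate_multiplier = 1, duration_multiplier = 1,
                              cycle_freq_shift_hz = 0,
                              band_amp_multipliers = NULL,
                              onset_s = 300, washout_s = Inf) {
  if (is.null(band_amp_multipliers))
    band_amp_multipliers <- stats::setNames(rep(1, 5L), BAND_NAMES)
  band_amp_multipliers <- band_amp_multipliers[BAND_NAMES]
  names(band_amp_multipliers) <- BAND_NAMES
  band_amp_multipliers[is.na(band_amp_multipliers)] <- 1
  if (rate_multiplier < 0 || duration_multiplier < 0 ||
      any(band_amp_multipliers < 0))
    stop("multipliers must be >= 0")
  structure(list(rate_multiplier = rate_multiplier,
                 duration_multiplier = duration_multiplier,
                 cycle_freq_shift_hz = cycle_freq_shift_hz,
                 band_amp_multipliers = band_amp_multipliers,
                 onset_s = onset_s, washout_s = washout_s),
            class = "drug_effect_model")
}

#' @rdname drug_effect_model
#' @param model a `drug_effect_model`.
#' @param t numeric vector of session times (s).
#' @return `effect_envelope()`: the kinetic envelope in `[0, 1]` (0 before
#'   injection, plateau 1 after onset).
#' @export
effect_envelope <- function(model, t) {
  env <- pmin(pmax(t / model$onset_s, 0), 1)
  if (is.finite(model$washout_s)) {
    past <- t > model$onset_s
    env[past] <- exp(-(t[past] - model$onset_s) / model$washout_s)
  }
  env
}

multiplier_at <- function(model, t, m) 1 + (m - 1) * effect_envelope(model, t)

# ---- state schedule ----------------------------------------------------

#' Wake / non-REM state schedule
#'
#' Alternating wake and non-REM episodes with exponentially distributed
#' durations, giving a controllable non-REM fraction (default about 15%,
#' matching a mostly-awake daytime GAERS recording).
#'
#' @param duration_s schedule length (s).
#' @param t0 session time of schedule start (s).
#' @param nrem_fraction target long-run non-REM fraction; 0 gives pure wake.
#' @param mean_nrem_s mean non-REM episode length (s).
#' @return Data frame with `start_s`, `end_s`, `state` (`"wake"`/`"nrem"`).
#' @export
make_state_schedule <- function(duration_s, t0 = 0, nrem_fraction = 0.15,
                                mean_nrem_s = 70) {
  if (nrem_fraction <= 0)
    return(data.frame(start_s = t0, end_s = t0 + duration_s, state = "wake"))
  mean_wake_s <- mean_nrem_s * (1 - nrem_fraction) / nrem_fraction
  t <- t0; st <- "wake"
  starts <- numeric(); ends <- numeric(); states <- character()
  while (t < t0 + duration_s) {
    len <- stats::rexp(1L, 1 / if (st == "wake") mean_wake_s else mean_nrem_s)
    len <- max(len, 10)
    e <- min(t + len, t0 + duration_s)
    starts <- c(starts, t); ends <- c(ends, e); states <- c(states, st)
    t <- e
    st <- if (st == "wake") "nrem" else "wake"
  }
  data.frame(start_s = starts, end_s = ends, state = states)
}

# ---- background --------------------------------------------------------

#' Generate background EEG
#'
#' Produces 1/f-shaped background noise built from five band-limited
#' components (delta through gamma, see the package vignette), with
#' state-dependent modulation: during non-REM epochs the delta component is
#' amplified and 11--13 Hz sleep spindle bursts are inserted (and labeled).
#' A drug-effect model scales each band component's amplitude with the
#' injection-locked kinetics. Deterministic given the RNG state.
#'
#' @param duration_s length (s).
#' @param fs sampling rate (Hz).
#' @param t0 session time of the first sample (s).
#' @param state_schedule from [make_state_schedule()].
#' @param drug a [drug_effect_model()] (its `band_amp_multipliers` are
#'   applied with the onset kinetics); `NULL` for no drug.
#' @param band_sds named awake SDs (uV) per band; defaults to the package
#'   background model.
#' @param nrem_delta_mult delta amplitude multiplier during non-REM.
#' @param spindle_rate_per_min spindle rate within non-REM.
#' @param spindle_amp_uv spindle amplitude (uV).
#' @return List with `rec` (an `eeg_recording`) and `events` (spindle and
#'   sleep annotations as a `"swd_events"` data frame).
#' @export
generate_background <- function(duration_s, fs, t0 = 0,
                                state_schedule = NULL, drug = NULL,
                                band_sds = NULL, nrem_delta_mult = 2.5,
                                spindle_rate_per_min = 4,
                                spindle_amp_uv = 90) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (is.null(state_schedule))
    state_schedule <- data.frame(start_s = t0, end_s = t0 + duration_s,
                                 state = "wake")
  if (is.null(band_sds))
    band_sds <- vapply(GEN_BANDS, `[[`, 0, "sd_uv")
  if (is.null(drug)) drug <- drug_effect_model()
  n <- round(duration_s * fs)
  nfft <- stats::nextn(n, c(2, 3, 5))
  freqs <- (seq_len(nfft) - 1L) * fs / nfft
  freqs <- pmin(freqs, fs - freqs) # two-sided magnitude grid
  z <- stats::fft(stats::rnorm(nfft))
  tt <- t0 + (seq_len(n) - 1L) / fs
  nrem <- logical(n)
  for (k in which(state_schedule$state == "nrem")) {
    i0 <- max(1L, ceiling((state_schedule$start_s[k] - t0) * fs - 1e-9) + 1L)
    i1 <- min(n, ceiling((state_schedule$end_s[k] - t0) * fs - 1e-9))
    if (i0 <= i1) nrem[i0:i1] <- TRUE
  }
  bm <- drug$band_amp_multipliers
  # group band components that share the same time envelope to save FFTs:
  # delta is always separate (non-REM modulation); the rest group by
  # multiplier value
  groups <- split(setdiff(BAND_NAMES, "delta"), bm[setdiff(BAND_NAMES, "delta")])
  groups <- c(list(delta = "delta"), unname(groups))
  x <- numeric(n)
  for (bands in groups) {
    amp <- numeric(nfft)
    for (b in bands) {
      def <- GEN_BANDS[[b]]
      sel <- freqs >= def$lo & freqs < min(def$hi, fs / 2)
      a0 <- 1 / sqrt(pmax(freqs[sel], 0.5))
      # scale so the component's expected variance equals band_sds[b]^2
      amp[sel] <- a0 * band_sds[[b]] / sqrt(sum(a0^2) / nfft)
    }
    comp <- Re(stats::fft(z * amp, inverse = TRUE) / nfft)[seq_len(n)]
    env <- multiplier_at(drug, tt, bm[[bands[1L]]])
    if (identical(bands, "delta")) {
      state_env <- rep(1, n)
      state_env[nrem] <- nrem_delta_mult
      env <- env * state_env
    }
    x <- x + comp * env
  }
  # sleep spindles inside non-REM episodes (non-overlapping)
  sp_start <- numeric(); sp_end <- numeric()
  for (k in which(state_schedule$state == "nrem")) {
    len <- state_schedule$end_s[k] - state_schedule$start_s[k]
    n_sp <- stats::rpois(1L, spindle_rate_per_min / 60 * len)
    if (n_sp == 0L) next
    dur <- stats::runif(n_sp, 0.5, 1.5)
    st <- sort(stats::runif(n_sp, state_schedule$start_s[k],
                            max(state_schedule$start_s[k],
                                state_schedule$end_s[k] - max(dur))))
    f_sp <- stats::runif(n_sp, 11, 13)
    ph <- stats::runif(n_sp, 0, 2 * pi)
    prev_end <- if (length(sp_end)) sp_end[length(sp_end)] else -Inf
    for (s in seq_len(n_sp)) {
      if (st[s] < prev_end) next
      i0 <- max(1L, round((st[s] - t0) * fs) + 1L)
      i1 <- min(n, i0 + round(dur[s] * fs) - 1L)
      if (i1 <= i0) next
      ts <- (seq.int(i0, i1) - i0) / fs
      hann <- 0.5 - 0.5 * cos(2 * pi * ts / dur[s])
      x[i0:i1] <- x[i0:i1] +
        spindle_amp_uv * hann * sin(2 * pi * f_sp[s] * ts + ph[s])
      sp_start <- c(sp_start, st[s]); sp_end <- c(sp_end, st[s] + dur[s])
      prev_end <- st[s] + dur[s]
    }
  }
  sleep <- state_schedule[state_schedule$state == "nrem", , drop = FALSE]
  ev <- event_list(
    start_s = c(sp_start, sleep$start_s),
    end_s = c(sp_end, sleep$end_s),
    label = c(rep("spindle", length(sp_start)), rep("sleep", nrow(sleep))))
  list(rec = recording(x, fs = fs, channel_labels = "EEG", t0 = t0),
       events = ev)
}

# ---- seizure sampling --------------------------------------------------

#' Sample seizure intervals
#'
#' Draws seizure start times from an inhomogeneous Poisson process with
#' rate `rate_per_min x rate_multiplier(t)`, thinned so that each start
#' falls at least `refractory_s` after the end of the previous seizure;
#' durations come from the truncated gamma distribution scaled by
#' `duration_multiplier(t)`. Events are clipped at the session end (and
#' dropped if clipping leaves less than the truncation floor).
#'
#' @param process a [seizure_process_params()].
#' @param drug a [drug_effect_model()] (or `NULL` for vehicle).
#' @param design a [session_design()].
#' @return Data frame with `start_s`, `duration_s`, `end_s`, sorted.
#' @export
sample_seizure_intervals <- function(process, drug = NULL,
                                     design = session_design()) {
  if (is.null(drug)) drug <- drug_effect_model()
  lam0 <- process$rate_per_min / 60
  t_lo <- design$control_start_s
  t_hi <- design$treatment_end_s
  rmax <- max(1, drug$rate_multiplier)
  lam_max <- lam0 * rmax
  n_cand <- stats::rpois(1L, lam_max * (t_hi - t_lo))
  cand <- sort(stats::runif(n_cand, t_lo, t_hi))
  accept <- stats::runif(n_cand) <
    multiplier_at(drug, cand, drug$rate_multiplier) / rmax
  cand <- cand[accept]
  starts <- numeric(); durs <- numeric()
  prev_end <- -Inf
  for (s in cand) {
    if (s < prev_end + process$refractory_s) next
    d <- draw_durations(1L, process) *
      multiplier_at(drug, s, drug$duration_multiplier)
    if (s + d > t_hi) d <- t_hi - s
    if (d < process$duration_min_s) next
    starts <- c(starts, s); durs <- c(durs, d)
    prev_end <- s + d
  }
  data.frame(start_s = starts, duration_s = durs, end_s = starts + durs)
}

# ---- SWD waveform ------------------------------------------------------

#' Synthesize a spike-and-wave discharge waveform
#'
#' Concatenated spike-and-wave cycles at the cycle frequency: one sharp
#' Gaussian spike per cycle (FWHM = `spike_fraction` of the cycle) plus a
#' wave sinusoid at the fundamental with optional 2f/3f harmonics, mean-
#' centred per cycle, amplitude-ramped linearly at onset and offset.
#'
#' @param duration_s waveform length (s), >= the truncation floor.
#' @param shape a [swd_shape_params()].
#' @param fs sampling rate (Hz).
#' @param cycle_freq_hz overrides the shape's cycle frequency if given.
#' @return Numeric vector of length `round(duration_s * fs)`.
#' @export
synthesize_swd <- function(duration_s, shape = swd_shape_params(), fs,
                           cycle_freq_hz = NULL) {
  f <- if (is.null(cycle_freq_hz)) shape$cycle_freq_hz else cycle_freq_hz
  if (f <= 0) stop("cycle frequency must be positive")
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  p <- (t * f) %% 1 # cycle phase: spike at 0.5, wave trough at 0.7
  theta <- 2 * pi * (p - 0.7)
  wave <- -shape$wave_amp_uv * cos(theta)
  h <- shape$harmonics
  if (length(h) >= 1L && h[1L] != 0)
    wave <- wave - h[1L] * shape$wave_amp_uv * cos(2 * theta)
  if (length(h) >= 2L && h[2L] != 0)
    wave <- wave - h[2L] * shape$wave_amp_uv * cos(3 * theta)
  if (shape$spike_amp_uv != 0) {
    sigma_p <- shape$spike_fraction / (2 * sqrt(2 * log(2)))
    spike <- exp(-0.5 * ((p - 0.5) / sigma_p)^2)
    spike <- spike - sigma_p * sqrt(2 * pi) # remove per-cycle DC
    wave <- wave + shape$spike_amp_uv * spike
  }
  ramp <- pmin(1, t / shape$ramp_s, (duration_s - t) / shape$ramp_s)
  wave * pmax(ramp, 0)
}

# ---- artifacts ---------------------------------------------------------

sample_artifacts <- function(rate_per_min, design, amp_uv = 350) {
  span <- design$treatment_end_s - design$control_start_s
  n <- stats::rpois(1L, rate_per_min / 60 * span)
  if (n == 0L)
    return(data.frame(start_s = numeric(), end_s = numeric(),
                      amp_uv = numeric()))
  st <- sort(stats::runif(n, design$control_start_s, design$treatment_end_s))
  dur <- stats::runif(n, 0.2, 0.6)
  en <- pmin(st + dur, design$treatment_end_s)
  keep <- rep(TRUE, n) # drop overlapping transients
  if (n > 1L) for (k in 2L:n) if (st[k] < max(en[seq_len(k - 1L)][keep[seq_len(k - 1L)]]))
    keep[k] <- FALSE
  data.frame(start_s = st[keep], end_s = en[keep], amp_uv = amp_uv)
}

# ---- session assembly --------------------------------------------------

#' Assemble a complete synthetic session
#'
#' Generates a full GAERS-like EEG session: state-modulated background,
#' inserted SWDs from the seizure point process, movement artifacts, and
#' sleep spindles, with every inserted event recorded in the ground truth.
#' A drug-effect model (or named preset) engages after the injection at
#' t = 0 with linear onset kinetics.
#'
#' @param preset a preset name (see [swd_presets()]), a
#'   [drug_effect_model()], or `NULL` for vehicle.
#' @param design a [session_design()].
#' @param fs sampling rate (Hz).
#' @param seed integer seed; the session is byte-identical for equal seeds.
#' @param shape a [swd_shape_params()].
#' @param process a [seizure_process_params()].
#' @param nrem_fraction long-run non-REM fraction of the state schedule.
#' @param artifact_rate_per_min movement-artifact rate.
#' @return List with `rec` (the `eeg_recording`), `ground_truth` (a
#'   `"swd_events"` data frame with an extra `cycle_freq_hz` column on SWD
#'   rows), `drug` (the resolved effect model) and `design`.
#' @export
assemble_session <- function(preset = NULL, design = session_design(),
                             fs = 256, seed = 1L,
                             shape = swd_shape_params(),
                             process = seizure_process_params(),
                             nrem_fraction = 0.15,
                             artifact_rate_per_min = 0.2) {
  drug <- resolve_preset(preset)
  set.seed(seed)
  duration_s <- design$treatment_end_s - design$control_start_s
  t0 <- design$control_start_s
  sched <- make_state_schedule(duration_s, t0, nrem_fraction)
  bg <- generate_background(duration_s, fs, t0, sched, drug)
  x <- rec_channel(bg$rec)
  n <- length(x)
  seiz <- sample_seizure_intervals(process, drug, design)
  cyc <- shape$cycle_freq_hz +
    drug$cycle_freq_shift_hz * effect_envelope(drug, seiz$start_s)
  for (k in seq_len(nrow(seiz))) {
    w <- synthesize_swd(seiz$duration_s[k], shape, fs, cycle_freq_hz = cyc[k])
    i0 <- round((seiz$start_s[k] - t0) * fs) + 1L
    i1 <- min(n, i0 + length(w) - 1L)
    x[i0:i1] <- x[i0:i1] + w[seq_len(i1 - i0 + 1L)]
  }
  arts <- sample_artifacts(artifact_rate_per_min, design)
  for (k in seq_len(nrow(arts))) {
    i0 <- max(1L, round((arts$start_s[k] - t0) * fs) + 1L)
    i1 <- min(n, round((arts$end_s[k] - t0) * fs))
    if (i1 <= i0) next
    m <- i1 - i0 + 1L
    hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(m) - 1L) / (m - 1L))
    x[i0:i1] <- x[i0:i1] + arts$amp_uv[k] * hann * stats::rnorm(m)
  }
  gt <- rbind(
    as.data.frame(bg$events),
    event_list(start_s = seiz$start_s, end_s = seiz$end_s,
               label = rep("swd", nrow(seiz)), accepted = TRUE),
    event_list(start_s = arts$start_s, end_s = arts$end_s,
               label = rep("artifact", nrow(arts))))
  gt <- validate_events(gt)
  gt$cycle_freq_hz <- NA_real_
  if (nrow(seiz)) {
    ord <- match(paste(round(seiz$start_s, 3L)),
                 paste(gt$start_s)[gt$label == "swd"])
    gt$cycle_freq_hz[gt$label == "swd"][ord] <- cyc
  }
  list(rec = recording(x, fs = fs, channel_labels = "EEG", t0 = t0),
       ground_truth = gt, drug = drug, design = design)
}

resolve_preset <- function(preset) {
  if (is.null(preset)) return(drug_effect_model())
  if (inherits(preset, "drug_effect_model")) return(preset)
  if (is.character(preset)) {
    p <- swd_presets()[[preset]]
    if (is.null(p)) stop("unknown preset: ", preset)
    return(p)
  }
  stop("preset must be NULL, a name, or a drug_effect_model")
}
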