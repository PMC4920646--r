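#' Run an in-silico multi-arm experiment
#'
#' Simulates a cohort of animals per arm (one full session each), runs the
#' SWD detector on every session, and computes the requested downstream
#' analyses: per-epoch seizure metrics, masked interictal band powers,
#' and/or ictal wavelet peak frequencies. Sessions are processed one at a
#' time so that memory stays bounded; every session is reproducible from
#' the experiment seed.
#'
#' @param arms named integer vector: animals per arm, names being preset
#'   names (see [swd_presets()]), e.g. `c(vehicle = 9, tcb2_3 = 6)`.
#' @param what any of `"metrics"`, `"bands"`, `"ictal"`.
#' @param fs sampling rate of the simulated sessions (Hz).
#' @param seed experiment seed; animal `k` of the experiment uses
#'   `seed * 10000 + k`.
#' @param design a [session_design()].
#' @param shape,process generator parameters.
#' @param nrem_fraction,artifact_rate_per_min session composition.
#' @param detection a [detection_params()].
#' @param spectral a [spectral_params()].
#' @param wavelet a [wavelet_params()].
#' @param band_pad_s guard band around excluded intervals for the
#'   interictal analysis (s).
#' @return List with `metrics` (animal x epoch long data frame), `bands`
#'   (animal x epoch x band), `ictal` (per-animal mean peak frequency),
#'   `ictal_events` (per-SWD wavelet means), `detected` (all detected SWDs
#'   with animal/arm columns) and `truth` (ground-truth SWDs likewise).
#' @export
run_experiment <- function(arms, what = "metrics", fs = 256, seed = 1L,
                           design = session_design(),
                           shape = swd_shape_params(),
                           process = seizure_process_params(),
                           nrem_fraction = 0.15,
                           artifact_rate_per_min = 0.2,
                           detection = detection_params(),
                           spectral = spectral_params(),
                           wavelet = wavelet_params(),
                           band_pad_s = 0.5) {
  metrics <- list(); bands <- list(); ictal <- list()
  ictal_events <- list(); detected <- list(); truth <- list()
  k <- 0L
  for (arm in names(arms)) {
    for (a in seq_len(arms[[arm]])) {
      k <- k + 1L
      animal <- sprintf("%s_%02d", arm, a)
      ses <- assemble_session(preset = arm, design = design, fs = fs,
                              seed = seed * 10000 + k, shape = shape,
                              process = process,
                              nrem_fraction = nrem_fraction,
                              artifact_rate_per_min = artifact_rate_per_min)
      det <- detect_swds(ses$rec, detection, baseline = "auto",
                         events = ses$ground_truth)
      id <- function(df) {
        if (nrow(df)) {
          df$animal <- animal; df$arm <- arm
        } else {
          df$animal <- character(); df$arm <- character()
        }
        df
      }
      detected[[k]] <- id(as.data.frame(det))
      truth[[k]] <- id(as.data.frame(
        ses$ground_truth[ses$ground_truth$label == "swd", , drop = FALSE]))
      if ("metrics" %in% what)
        metrics[[k]] <- id(epoch_metrics(det, design))
      if ("bands" %in% what) {
        excl <- validate_events(rbind(
          as.data.frame(det)[EVENT_COLS],
          as.data.frame(ses$ground_truth[
            ses$ground_truth$label %in% c("artifact", "sleep"), EVENT_COLS])))
        bands[[k]] <- id(epoch_band_powers(ses$rec, excl,
                                           design = design, params = spectral,
                                           pad_s = band_pad_s))
      }
      if ("ictal" %in% what) {
        fr <- ictal_peak_frequencies(ses$rec, det, wavelet)
        apf <- animal_peak_frequency(fr$mean_wavelet_freq_hz)
        ictal[[k]] <- data.frame(animal = animal, arm = arm,
                                 mean_hz = apf$mean_hz, sem_hz = apf$sem_hz,
                                 n_swds = apf$n)
        ictal_events[[k]] <- id(as.data.frame(fr))
      }
      rm(ses, det)
    }
  }
  bind <- function(l) if (length(l)) do.call(rbind, l) else NULL
  list(metrics = bind(metrics), bands = bind(bands), ictal = bind(ictal),
       ictal_events = bind(ictal_events),
       detected = bind(detected), truth = bind(truth))
}

#' Overall effect of one arm from an experiment
#'
#' Convenience wrapper: normalizes the experiment's metrics (or band
#' powers) against the control period and the vehicle arm and returns the
#' overall percent change of one parameter or band for one arm.
#'
#' @param experiment output of [run_experiment()].
#' @param arm,parameter arm and parameter (`total_time`, `n_seizures`,
#'   `mean_duration`) or band name (`delta`..`gamma`).
#' @param design a [session_design()].
#' @return See [overall_effect()].
#' @export
experiment_overall_effect <- function(experiment, arm, parameter,
                                      design = session_design()) {
  if (parameter %in% c("total_time", "n_seizures", "mean_duration")) {
    nm <- normalize_metrics(experiment$metrics, design)
  } else {
    nm <- normalize_band_powers(experiment$bands, design)
  }
  overall_effect(nm, arm, parameter, design)
}
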