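#' Per-epoch seizure metrics
#'
#' Quantifies the three absence-seizure parameters in the session's 20-min
#' epochs: total time spent in seizures, number of seizures, and mean
#' duration of individual seizures. Total time is the summed overlap of
#' events with the epoch (events are split at epoch edges); count and mean
#' duration attribute an edge-spanning event to the epoch containing its
#' start, using its full duration, which keeps counts integral and time
#' conserved. Epochs with no seizure get a missing mean duration (never
#' zero). Events outside the session window are clipped with a warning.
#'
#' @param events event data frame; only `swd` rows are used.
#' @param design a [session_design()].
#' @return Data frame with `epoch_index`, `total_seizure_time_s`,
#'   `n_seizures`, `mean_seizure_duration_s`.
#' @export
epoch_metrics <- function(events, design = session_design()) {
  ev <- events[events$label == "swd", , drop = FALSE]
  lo <- design$control_start_s; hi <- design$treatment_end_s
  if (nrow(ev) && any(ev$start_s < lo | ev$end_s > hi)) {
    warning("events outside the session window were clipped")
    ev$start_s <- pmax(ev$start_s, lo)
    ev$end_s <- pmin(ev$end_s, hi)
    ev <- ev[ev$end_s > ev$start_s, , drop = FALSE]
  }
  epochs <- epoch_indices(design)
  out <- data.frame(epoch_index = epochs, total_seizure_time_s = 0,
                    n_seizures = 0L, mean_seizure_duration_s = NA_real_)
  for (i in seq_along(epochs)) {
    bd <- epoch_bounds(epochs[i], design)
    ov <- pmax(0, pmin(ev$end_s, bd[2L]) - pmax(ev$start_s, bd[1L]))
    out$total_seizure_time_s[i] <- sum(ov)
    own <- ev$start_s >= bd[1L] & ev$start_s < bd[2L]
    out$n_seizures[i] <- sum(own)
    if (any(own))
      out$mean_seizure_duration_s[i] <-
        mean(ev$end_s[own] - ev$start_s[own])
  }
  out
}

# Shared two-step normalization: per animal, epoch values as % of the mean
# over the animal's control epochs, then as % of the vehicle-group mean at
# the matching epoch (and, for band tables, band). Used by both the
# seizure metrics and the band-power table.
normalize_epoch_values <- function(table, value_col,
                                   design = session_design(),
                                   vehicle_arm = "vehicle") {
  stopifnot(all(c("animal", "arm", "epoch_index", value_col) %in%
                  names(table)))
  ctrl <- control_epochs(design)
  strat_cols <- intersect(c("band", "parameter"), names(table))
  key <- function(df) do.call(paste, c(df[c("animal", "arm", strat_cols)],
                                       sep = "\r"))
  table$pct_control <- NA_real_
  for (k in unique(key(table))) {
    rows <- key(table) == k
    sub <- table[rows, ]
    base <- mean(sub[[value_col]][sub$epoch_index %in% ctrl], na.rm = TRUE)
    if (!is.finite(base) || base <= 0) next
    table$pct_control[rows] <- sub[[value_col]] / base * 100
  }
  gkey <- function(df) do.call(paste, c(df[c("epoch_index", strat_cols)],
                                        sep = "\r"))
  veh <- table[table$arm == vehicle_arm, , drop = FALSE]
  gmeans <- tapply(veh$pct_control, gkey(veh), mean, na.rm = TRUE)
  table$pct_vehicle <- table$pct_control /
    as.numeric(gmeans[gkey(table)]) * 100
  table
}

#' Normalize per-epoch seizure metrics
#'
#' Applies the two-step normalization to each of the three seizure
#' parameters: per animal, every epoch value is expressed as a percentage
#' of the mean over the animal's two control epochs, and then as a
#' percentage of the vehicle group's mean at the matching epoch. Animals
#' with a zero control value for a parameter are excluded for that
#' parameter (missing), matching the requirement that GAERS express
#' frequent control-period seizures.
#'
#' @param metrics long data frame with columns `animal`, `arm`,
#'   `epoch_index`, `total_seizure_time_s`, `n_seizures`,
#'   `mean_seizure_duration_s` (one row per animal x epoch).
#' @param design a [session_design()].
#' @param vehicle_arm name of the vehicle arm.
#' @return Long data frame with columns `animal`, `arm`, `epoch_index`,
#'   `parameter` (`total_time`, `n_seizures`, `mean_duration`), `value`,
#'   `pct_control`, `pct_vehicle`.
#' @export
normalize_metrics <- function(metrics, design = session_design(),
                              vehicle_arm = "vehicle") {
  params <- c(total_time = "total_seizure_time_s",
              n_seizures = "n_seizures",
              mean_duration = "mean_seizure_duration_s")
  long <- do.call(rbind, lapply(names(params), function(p) {
    data.frame(animal = metrics$animal, arm = metrics$arm,
               epoch_index = metrics$epoch_index, parameter = p,
               value = as.numeric(metrics[[params[[p]]]]))
  }))
  normalize_epoch_values(long, "value", design, vehicle_arm)
}

#' Overall drug effect on one seizure parameter
#'
#' For each animal of the arm, the mean normalized value (% of vehicle)
#' across the treatment epochs (missing epochs omitted); the overall
#' effect is the group mean +- SEM of those animal means, reported as the
#' absolute percent change from 100% with its direction.
#'
#' @param normalized output of [normalize_metrics()] (or
#'   [normalize_band_powers()] with a `band` column selected upstream).
#' @param arm arm to summarize.
#' @param parameter which parameter (or band) to summarize.
#' @param design a [session_design()].
#' @return List with `arm`, `parameter`, `group_mean_pct`, `sem_pct`,
#'   `percent_change`, `direction`, `n_animals`, `animal_means`.
#' @export
overall_effect <- function(normalized, arm, parameter,
                           design = session_design()) {
  strat <- if ("parameter" %in% names(normalized)) "parameter" else "band"
  sub <- normalized[normalized$arm == arm & normalized[[strat]] == parameter &
                      normalized$epoch_index %in% treatment_epochs(design), ,
                    drop = FALSE]
  am <- tapply(sub$pct_vehicle, sub$animal, mean, na.rm = TRUE)
  am <- am[is.finite(am)]
  if (length(am) < 2L)
    stop("overall_effect requires >= 2 animals with data")
  gm <- mean(am)
  sem <- stats::sd(am) / sqrt(length(am))
  list(arm = arm, parameter = parameter, group_mean_pct = gm,
       sem_pct = sem, percent_change = abs(100 - gm),
       direction = if (gm < 100) "decrease" else "increase",
       n_animals = length(am), animal_means = am)
}

#' Two-way ANOVA with post-hoc contrasts for normalized seizure metrics
#'
#' Non-repeated-measures two-way analysis of variance with drug (arm) and
#' time (epoch) as factors on the normalized treatment-period values, with
#' a marginal (type-III-style) decomposition using sum-to-zero contrasts
#' (the arms are unbalanced). Post-hoc battery: Dunnett contrasts of each
#' drug arm against vehicle on the animal-level treatment means, and
#' Sidak-adjusted per-epoch drug-vs-vehicle contrasts (unpaired t-tests,
#' adjusted across the treatment epochs within each arm).
#'
#' @param normalized output of [normalize_metrics()].
#' @param parameter which parameter to analyze.
#' @param design a [session_design()].
#' @param vehicle_arm name of the reference arm.
#' @param value_col which normalized column to analyze (`pct_control` by
#'   default: the published analyses test the control-normalized values).
#' @return List of class `"swd_anova"` with elements `anova` (type-III
#'   table), `dunnett` (data frame of contrasts), `sidak` (per-epoch
#'   contrasts with adjusted p), `n_per_arm`.
#' @export
anova_two_way <- function(normalized, parameter, design = session_design(),
                          vehicle_arm = "vehicle",
                          value_col = "pct_control") {
  strat <- if ("parameter" %in% names(normalized)) "parameter" else "band"
  sub <- normalized[normalized[[strat]] == parameter &
                      normalized$epoch_index %in% treatment_epochs(design), ,
                    drop = FALSE]
  sub <- sub[is.finite(sub[[value_col]]), , drop = FALSE]
  sub$arm <- stats::relevel(factor(sub$arm), ref = vehicle_arm)
  sub$epoch <- factor(sub$epoch_index)
  if (nlevels(sub$arm) < 2L || nlevels(sub$epoch) < 2L)
    stop("two-way ANOVA needs >= 2 levels of both factors")
  sub$y <- sub[[value_col]]
  fit <- stats::lm(y ~ arm * epoch, data = sub,
                   contrasts = list(arm = "contr.sum", epoch = "contr.sum"))
  tab <- car::Anova(fit, type = 3)
  # Dunnett on animal-level treatment means
  am <- stats::aggregate(y ~ animal + arm, data = sub, FUN = mean)
  dn <- NULL
  if (min(table(am$arm)) >= 2L && nlevels(droplevels(am$arm)) >= 2L) {
    afit <- stats::aov(y ~ arm, data = am)
    gl <- summary(multcomp::glht(afit, linfct = multcomp::mcp(arm = "Dunnett")))
    dn <- data.frame(contrast = names(gl$test$coefficients),
                     estimate = as.numeric(gl$test$coefficients),
                     p_adj = as.numeric(gl$test$pvalues))
  }
  # Sidak per-epoch contrasts
  sk <- sidak_per_epoch(sub, value_col = "y", vehicle_arm = vehicle_arm)
  structure(list(anova = tab, dunnett = dn, sidak = sk,
                 n_per_arm = table(am$arm)), class = "swd_anova")
}

# per-epoch drug-vs-vehicle unpaired t-tests with Sidak adjustment across
# the epochs tested within each arm
sidak_per_epoch <- function(sub, value_col, vehicle_arm) {
  arms <- setdiff(unique(as.character(sub$arm)), vehicle_arm)
  out <- list()
  for (a in arms) {
    eps <- sort(unique(sub$epoch_index))
    m <- length(eps)
    for (e in eps) {
      x <- sub[[value_col]][sub$arm == a & sub$epoch_index == e]
      y <- sub[[value_col]][sub$arm == vehicle_arm & sub$epoch_index == e]
      if (length(x) < 2L || length(y) < 2L) next
      tt <- stats::t.test(x, y, var.equal = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        arm = a, epoch_index = e, estimate = mean(x) - mean(y),
        p = tt$p.value, p_sidak = 1 - (1 - tt$p.value)^m)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' @export
print.swd_anova <- function(x, ...) {
  cat("Two-way ANOVA (type III, drug x time):\n")
  print(x$anova)
  if (!is.null(x$dunnett)) {
    cat("\nDunnett contrasts vs vehicle (animal-level treatment means):\n")
    print(x$dunnett, row.names = FALSE)
  }
  invisible(x)
}

#' Unpaired t-test on per-animal SWD peak frequencies
#'
#' Compares the per-animal mean wavelet peak frequencies of two arms with
#' a pooled-variance unpaired two-sided t-test (set `var_equal = FALSE`
#' for Welch).
#'
#' @param freq_a,freq_b numeric vectors of per-animal mean frequencies.
#' @param var_equal pooled (default) vs Welch.
#' @return List with `mean_a`, `mean_b`, `t`, `df`, `p`.
#' @export
peak_freq_test <- function(freq_a, freq_b, var_equal = TRUE) {
  freq_a <- freq_a[is.finite(freq_a)]
  freq_b <- freq_b[is.finite(freq_b)]
  if (length(freq_a) < 2L || length(freq_b) < 2L)
    stop("peak_freq_test requires >= 2 animals per arm")
  tt <- stats::t.test(freq_a, freq_b, var.equal = var_equal)
  list(mean_a = mean(freq_a), mean_b = mean(freq_b),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
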