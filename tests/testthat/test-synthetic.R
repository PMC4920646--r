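test_that("sessions are byte-identical under a fixed seed", {
  a <- small_session(seed = 4)
  b <- small_session(seed = 4)
  expect_identical(a$rec$samples, b$rec$samples)
  expect_identical(a$ground_truth, b$ground_truth)
  c_ <- small_session(seed = 5)
  expect_false(identical(a$rec$samples, c_$rec$samples))
})

test_that("sampled durations match the truncated gamma moments", {
  set.seed(101)
  proc <- seizure_process_params()
  d <- swdquant:::draw_durations(5000, proc)
  expect_true(all(d >= 1))
  # sample mean within 2 SE of the truncated-distribution mean
  mu <- swdquant:::truncated_duration_mean(proc)
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - mu), 2 * se)
  # and the truncated mean itself is close to the nominal 16.1 s
  expect_lt(abs(mu - 16.1), 1)
})

test_that("stationary seizure rate matches the Poisson oracle", {
  proc <- seizure_process_params(rate_per_min = 0.5)
  # long horizon via many independent sessions
  set.seed(33)
  n_ev <- 0; horizon <- 0
  for (k in 1:12) {
    s <- sample_seizure_intervals(proc, NULL, session_design())
    n_ev <- n_ev + nrow(s)
    horizon <- horizon + 9600
  }
  # thinning-corrected expected rate: lambda / (1 + lambda (D + R))
  lam <- 0.5 / 60
  Dbar <- swdquant:::truncated_duration_mean(proc)
  expected <- lam / (1 + lam * (Dbar + proc$refractory_s)) * horizon
  expect_lt(abs(n_ev - expected), 3 * sqrt(expected))
})

test_that("rate multiplier zero suppresses treatment-period events", {
  set.seed(2)
  drug <- drug_effect_model(rate_multiplier = 0, onset_s = 1)
  s <- sample_seizure_intervals(seizure_process_params(rate_per_min = 2),
                                drug, session_design())
  expect_gt(sum(s$start_s < 0), 10)
  expect_equal(sum(s$start_s > 5), 0L)
})

test_that("seizure intervals respect refractory gaps and the session end", {
  set.seed(6)
  proc <- seizure_process_params(rate_per_min = 3, refractory_s = 5)
  s <- sample_seizure_intervals(proc, NULL, session_design())
  expect_true(all(diff(s$start_s) > 0))
  expect_true(all(s$start_s[-1] - s$end_s[-nrow(s)] >= 5 - 1e-9))
  expect_true(all(s$end_s <= 7200))
  expect_true(all(s$duration_s >= 1))
})

test_that("SWD waveforms have the right spectrum and cycle count", {
  fs <- 256
  w <- synthesize_swd(10, swd_shape_params(cycle_freq_hz = 7), fs)
  # FFT oracle: dominant peak at 7 Hz
  sp <- Mod(fft(w))[1:(5 * fs)]
  f_peak <- (which.max(sp[2:length(sp)])) / 10
  expect_lt(abs(f_peak - 7), 0.15)
  # cycle count oracle: 2 s at 7 Hz -> 14 +- 1 spikes
  w2 <- synthesize_swd(2, swd_shape_params(cycle_freq_hz = 7), fs)
  thr <- 0.25 * max(w2)
  n_spikes <- sum(diff(w2 > thr) == 1)
  expect_gte(n_spikes, 13); expect_lte(n_spikes, 15)
  # degenerate case: no spike, no harmonics -> pure sinusoid
  w3 <- synthesize_swd(4, swd_shape_params(spike_amp_uv = 0,
                                           wave_amp_uv = 1,
                                           harmonics = c(0, 0),
                                           ramp_s = 1e-9), fs)
  t <- (0:(4 * fs - 1)) / fs
  pure <- -cos(2 * pi * ((t * 6.9) %% 1 - 0.7))
  inner <- 2:(length(t) - 2) # the ramp touches only the end samples
  expect_lt(max(abs(w3[inner] - pure[inner])), 1e-9)
  expect_error(synthesize_swd(2, fs = fs, cycle_freq_hz = -1), "positive")
})

test_that("band amplitude multiplier scales band power by its square", {
  m <- 0.7
  drug <- drug_effect_model(band_amp_multipliers =
                              c(delta = 1, theta = 1, alpha = 1, beta = 1,
                                gamma = m), onset_s = 1)
  set.seed(12); ref <- generate_background(600, 256, 0)
  set.seed(12); mod <- generate_background(600, 256, 0, drug = drug)
  pw <- function(rec) {
    sp <- stft_power(rec_channel(antialias_resample(rec, 200)), 200)
    rowMeans(sp$power)
  }
  g_bins <- c(31:47, 53:80)
  ratio <- mean(pw(mod$rec)[g_bins]) / mean(pw(ref$rec)[g_bins])
  expect_lt(abs(ratio - m^2), 0.05 * m^2 + 0.01)
  expect_error(drug_effect_model(band_amp_multipliers =
                                   c(delta = -1, theta = 1, alpha = 1,
                                     beta = 1, gamma = 1)), ">= 0")
})

test_that("a pure-wake schedule yields no spindles or sleep", {
  set.seed(9)
  bg <- generate_background(300, 128, 0,
                            make_state_schedule(300, 0, nrem_fraction = 0))
  expect_equal(nrow(bg$events), 0L)
})

test_that("ground truth conserves every inserted seizure", {
  ses <- small_session(seed = 13)
  gt <- gt_swds(ses)
  expect_true(all(diff(gt$start_s) > 0))
  expect_true(all(gt$end_s > gt$start_s))
  expect_true(all(is.finite(gt$cycle_freq_hz)))
  # vehicle: all cycle frequencies at the baseline value
  expect_true(all(abs(gt$cycle_freq_hz - 6.90) < 1e-9))
})

test_that("vehicle sessions have matching control and treatment statistics", {
  # pooled over seeds to beat sampling noise; ground-truth level
  set.seed(55)
  rate <- function(s, lo, hi) sum(s$start_s >= lo & s$start_s < hi) / (hi - lo)
  r_ctrl <- 0; r_trt <- 0
  for (k in 1:10) {
    s <- sample_seizure_intervals(seizure_process_params(), NULL)
    r_ctrl <- r_ctrl + rate(s, -2400, 0)
    r_trt <- r_trt + rate(s, 0, 7200)
  }
  expect_lt(abs(r_trt / r_ctrl - 1), 0.15)
})

test_that("configured drug multipliers are recovered from ground truth", {
  # isolates generator correctness from the detector: rate and duration
  # multipliers read back from the ground-truth point process
  drug <- drug_effect_model(rate_multiplier = 0.5, duration_multiplier = 2,
                            onset_s = 1)
  proc <- seizure_process_params(rate_per_min = 1)
  set.seed(77)
  ctrl_d <- c(); trt_d <- c(); n_ctrl <- 0; n_trt <- 0
  for (k in 1:20) {
    s <- sample_seizure_intervals(proc, drug, session_design())
    ctrl_d <- c(ctrl_d, s$duration_s[s$start_s < 0])
    trt_d <- c(trt_d, s$duration_s[s$start_s > 60 & s$end_s < 7100])
    n_ctrl <- n_ctrl + sum(s$start_s < 0)
    n_trt <- n_trt + sum(s$start_s >= 0)
  }
  expect_lt(abs(mean(trt_d) / mean(ctrl_d) - 2), 0.25)
  # realized rates carry the refractory-thinning correction
  lam <- 1 / 60; Dbar <- swdquant:::truncated_duration_mean(proc)
  thin <- function(m, d) lam * m / (1 + lam * m * (Dbar * d + 5))
  expected_ratio <- thin(0.5, 2) / thin(1, 1) * 7200 / 2400
  expect_lt(abs(n_trt / n_ctrl - expected_ratio) / expected_ratio, 0.15)
})

test_that("presets embed the printed overall effects at expectation", {
  p <- swd_presets()
  expect_named(p, names(swdquant:::preset_targets()))
  fr <- swdquant:::expected_seizure_fractions(p$tcb2_3$rate_multiplier,
                                              p$tcb2_3$duration_multiplier)
  expect_lt(abs(fr[["count"]] - 0.063), 1e-4)
  expect_lt(abs(fr[["total"]] - 0.026), 1e-4)
  fr <- swdquant:::expected_seizure_fractions(p$lorcaserin_3$rate_multiplier,
                                              p$lorcaserin_3$duration_multiplier)
  expect_lt(abs(fr[["duration"]] - 3.01), 1e-3)
  fr_g <- swdquant:::expected_measured_band_fraction(
    p$tcb2_3$band_amp_multipliers, "gamma")
  expect_lt(abs(fr_g - 0.736), 1e-4)
  # the solved amplitude exceeds sqrt of the printed power fraction:
  # leakage from unscaled neighbours must be compensated
  expect_gt(p$cp_10$band_amp_multipliers[["delta"]], sqrt(1.645))
  # vehicle preset is the identity
  expect_equal(p$vehicle$rate_multiplier, 1)
  expect_equal(unname(p$vehicle$band_amp_multipliers), rep(1, 5))
})

test_that("the effect envelope is zero before injection and ramps linearly", {
  m <- drug_effect_model(onset_s = 300)
  expect_equal(effect_envelope(m, c(-2400, -1)), c(0, 0))
  expect_equal(effect_envelope(m, 150), 0.5)
  expect_equal(effect_envelope(m, c(300, 7200)), c(1, 1))
})
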