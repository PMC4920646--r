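test_that("DC removal rejects constants and preserves 10 Hz content", {
  fs <- 1000
  # constant input decays to ~0 within ~5 time constants
  y <- highpass_dc_remove(rep(5, fs), fs, tau_s = 0.1)
  expect_lt(max(abs(y[(0.5 * fs):fs])), 5 * exp(-4.9))
  # 10 Hz sinusoid: amplitude preserved within 5% (cutoff ~1.6 Hz)
  t <- (0:(4 * fs - 1)) / fs
  y <- highpass_dc_remove(sin(2 * pi * 10 * t), fs, 0.1)
  amp <- sqrt(2) * sd(y[fs:(4 * fs)])
  expect_gt(amp, 0.95)
  expect_lt(amp, 1.05)
  # linear ramp: bounded response ~ slope * tau
  slope <- 3
  y <- highpass_dc_remove(slope * t, fs, 0.1)
  expect_lt(abs(y[4 * fs] - slope * 0.1), 0.02)
  expect_error(highpass_dc_remove(1:10, fs, 0), "tau")
})

test_that("baseline statistics recover the noise SD and reject bad intervals", {
  set.seed(5)
  fs <- 500
  x <- rnorm(60 * fs)
  bl <- baseline_stats(x, fs, t0 = 0, interval = c(0, 60))
  expect_lt(abs(bl$sd_uv - 1), 0.05)
  expect_lt(abs(bl$mean_uv), 0.05)
  expect_error(baseline_stats(x, fs, 0, c(0, 5)), "10 s")
  expect_error(baseline_stats(x, fs, 0, c(30, 90)), "outside")
  expect_error(baseline_stats(rep(1, 60 * fs), fs, 0, c(0, 60)), "degenerate")
  gt <- event_list(start_s = 20, end_s = 30, label = "swd", accepted = TRUE)
  expect_warning(baseline_stats(x, fs, 0, c(15, 40), gt), "overlaps")
})

test_that("automatic baseline selection picks the longest clean control gap", {
  rec <- recording(numeric(9600 * 4), fs = 4, t0 = -2400)
  # eligible gaps of 30 s and 90 s -> the 90 s gap is chosen
  ev <- event_list(start_s = c(-2400, -2270, -2150),
                   end_s = c(-2300, -2240, 0),
                   label = c("swd", "artifact", "sleep"))
  expect_equal(auto_baseline(rec, ev), c(-2240, -2150))
  # fully clean control -> first 120 s
  expect_equal(auto_baseline(rec, event_list()), c(-2400, -2280))
  # all control excluded -> error
  all_cov <- event_list(start_s = -2400, end_s = 0, label = "sleep")
  expect_error(auto_baseline(rec, all_cov), "baseline")
})

test_that("threshold crossings match the Gaussian-tail and cycle-count oracles", {
  set.seed(8)
  fs <- 1000
  x <- rnorm(60 * fs)
  bl <- baseline_stats(x, fs, 0, c(0, 60))
  # P(|z| > 6) is ~2e-9 per sample: expect no events in 60 s
  expect_length(detect_crossings(x, fs, 0, bl, k = 6), 0L)
  # single 10-SD spike of 20 ms -> exactly one event
  x2 <- x
  x2[30000:30019] <- 10
  expect_length(detect_crossings(x2, fs, 0, bl, k = 6), 1L)
  # 7 Hz spike-and-wave train of 10 s -> ~70 collapsed events
  w <- synthesize_swd(10, swd_shape_params(cycle_freq_hz = 7,
                                           spike_amp_uv = 10,
                                           wave_amp_uv = 4), fs)
  n_pk <- length(detect_crossings(c(x, w), fs, 0, bl, 6))
  expect_gte(n_pk, 67)
  expect_lte(n_pk, 71)
})

test_that("raising the threshold never increases the crossing count", {
  set.seed(9)
  fs <- 500
  ses <- small_session(seed = 21)
  x <- highpass_dc_remove(rec_channel(ses$rec), ses$rec$fs, 0.1)
  bl <- baseline_stats(x, ses$rec$fs, ses$rec$t0,
                       auto_baseline(ses$rec, ses$ground_truth,
                                     small_design()))
  counts <- vapply(c(5, 6, 7, 8, 9), function(k)
    length(detect_crossings(x, ses$rec$fs, ses$rec$t0, bl, k)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("grouping follows the onset and continuation rules (hand-traced)", {
  # gaps 0.15 (<0.2 opens), 0.35, 0.35 (<0.4 continue): one event of four
  g <- group_crossings(c(0, 0.15, 0.50, 0.85), edge_pad_s = 0)
  expect_length(g, 1L)
  expect_equal(g[[1]]$peak_times_s, c(0, 0.15, 0.50, 0.85))
  # no pair closer than 0.2: nothing opens
  expect_length(group_crossings(c(0, 0.30, 0.60)), 0L)
  # gap 0.45 > 0.4 closes the first event; second pair opens a new one
  g <- group_crossings(c(0, 0.15, 0.60, 0.75), edge_pad_s = 0)
  expect_length(g, 2L)
  expect_equal(g[[1]]$end_s, 0.15)
  expect_equal(g[[2]]$start_s, 0.60)
})

test_that("amalgamation merges to a fixed point and is idempotent", {
  mk <- function(s, e) list(start_s = s, end_s = e, peak_times_s = c(s, e))
  # gaps 0.4 and 0.6: first two merge, third stays
  a <- amalgamate(list(mk(0, 1), mk(1.4, 2), mk(2.6, 3)))
  expect_length(a, 2L)
  expect_equal(a[[1]]$end_s, 2)
  # chain of 0.4 gaps collapses to one event only through iteration
  chain <- list(mk(0, 1), mk(1.4, 2.4), mk(2.8, 3.8), mk(4.2, 5.2))
  a <- amalgamate(chain)
  expect_length(a, 1L)
  expect_equal(a[[1]]$peak_times_s, c(0, 1, 1.4, 2.4, 2.8, 3.8, 4.2, 5.2))
  # identity on a single putative and idempotence on any output
  expect_equal(amalgamate(list(mk(0, 1))), list(mk(0, 1)))
  expect_equal(amalgamate(a), a)
})

test_that("duration filter keeps the 1.0 s boundary inclusive", {
  mk <- function(d) list(start_s = 0, end_s = d, peak_times_s = c(0, d))
  kept <- duration_filter(list(mk(0.8), mk(1.0), mk(16.1)))
  expect_equal(vapply(kept, `[[`, 0, "end_s"), c(1.0, 16.1))
  expect_length(duration_filter(list()), 0L)
  expect_length(duration_filter(list(mk(0.5), mk(0.9))), 0L)
})

test_that("frequency criterion computes in-band fractions and flags", {
  # peaks every 1/7 s: all instantaneous frequencies 7 Hz -> accepted
  p <- list(start_s = 0, end_s = 2, peak_times_s = seq(0, 2, by = 1 / 7))
  r <- frequency_criterion(p)
  expect_equal(r$frac_in_band, 1)
  expect_true(r$accepted)
  expect_equal(unique(round(r$instantaneous_freqs_hz, 6)), 7)
  # 8 intervals at 7 Hz + 2 at 20 Hz -> frac 0.8 >= 0.75 -> accepted
  pk <- c(cumsum(rep(1 / 7, 8)), cumsum(rep(1 / 7, 8))[8] + (1:2) / 20)
  r <- frequency_criterion(list(peak_times_s = c(0, pk)))
  expect_equal(r$frac_in_band, 0.8)
  expect_true(r$accepted)
  # 14 Hz spindle-like train: frac 0 -> rejected
  r <- frequency_criterion(list(peak_times_s = seq(0, 1, by = 1 / 14)))
  expect_equal(r$frac_in_band, 0)
  expect_false(r$accepted)
  # fewer than two peaks: rejected with frac 0
  r <- frequency_criterion(list(peak_times_s = 0.5))
  expect_false(r$accepted)
  expect_equal(r$frac_in_band, 0)
})

test_that("stage order matters: amalgamation must precede the duration filter", {
  # two 0.7 s putatives 0.4 s apart: amalgamate-then-filter keeps one
  # merged event; filter-then-amalgamate discards both
  mk <- function(s, e) list(start_s = s, end_s = e,
                            peak_times_s = seq(s, e, by = 1 / 7))
  puts <- list(mk(0, 0.7), mk(1.1, 1.8))
  spec_order <- duration_filter(amalgamate(puts))
  swapped <- amalgamate(duration_filter(puts))
  expect_length(spec_order, 1L)
  expect_length(swapped, 0L)
})

test_that("the full detector recovers ground truth on a synthetic session", {
  ses <- small_session(seed = 31)
  det <- detect_swds(ses$rec, baseline = "auto", events = ses$ground_truth)
  gt <- gt_swds(ses)
  expect_gt(nrow(gt), 5)
  m <- match_events(det, gt[gt$end_s - gt$start_s >= 1.2, ])
  expect_gte(m$precision, 0.95)
  expect_gte(m$recall, 0.95)
  # detected events never overlap and satisfy the event-list invariants
  expect_s3_class(det, "swd_events")
  if (nrow(det) > 1)
    expect_true(all(det$start_s[-1] >= det$end_s[-nrow(det)]))
  # report counts are monotone along the pipeline
  rp <- attr(det, "report")
  expect_true(rp$n_putative >= rp$n_amalgamated)
  expect_true(rp$n_amalgamated >= rp$n_min_duration)
  expect_true(rp$n_min_duration >= rp$n_accepted)
})

test_that("a spindle-only recording yields zero detections", {
  set.seed(77)
  sched <- data.frame(start_s = c(-600, -400, -200),
                      end_s = c(-400, -200, 0),
                      state = c("wake", "nrem", "wake"))
  bg <- generate_background(600, 128, -600, sched)
  expect_gt(sum(bg$events$label == "spindle"), 0)
  det <- detect_swds(bg$rec, baseline = "auto", events = bg$events,
                     params = detection_params())
  expect_equal(nrow(det), 0L)
})
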