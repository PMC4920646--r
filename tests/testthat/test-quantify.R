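test_that("epoch metrics follow the edge-splitting conventions", {
  ev <- event_list(start_s = c(100, 1190), end_s = c(130, 1230),
                   label = c("swd", "swd"), accepted = TRUE)
  em <- epoch_metrics(ev)
  e0 <- em[em$epoch_index == 0, ]
  e1 <- em[em$epoch_index == 1, ]
  # total time splits at the epoch edge: 30 + 10 in epoch 0, 30 in epoch 1
  expect_equal(e0$total_seizure_time_s, 40)
  expect_equal(e1$total_seizure_time_s, 30)
  # count and mean duration attribute the spanning event to its start epoch
  expect_equal(e0$n_seizures, 2L)
  expect_equal(e1$n_seizures, 0L)
  expect_equal(e0$mean_seizure_duration_s, 35)
  expect_true(is.na(e1$mean_seizure_duration_s))
  # no events: zero totals and counts, missing means
  em0 <- epoch_metrics(event_list())
  expect_true(all(em0$total_seizure_time_s == 0))
  expect_true(all(is.na(em0$mean_seizure_duration_s)))
  # events outside the session window are clipped with a warning
  out <- event_list(start_s = 7100, end_s = 7300, label = "swd")
  expect_warning(em2 <- epoch_metrics(out), "clipped")
  expect_equal(em2$total_seizure_time_s[em2$epoch_index == 5], 100)
})

test_that("seizure time is conserved between ground truth and epoch totals", {
  ses <- small_session(seed = 23)
  gt <- gt_swds(ses)
  em <- epoch_metrics(gt, small_design())
  expect_equal(sum(em$total_seizure_time_s),
               sum(pmin(gt$end_s, 1800) - pmax(gt$start_s, -600)))
  expect_equal(sum(em$n_seizures), nrow(gt))
})

test_that("metric normalization matches the worked arithmetic", {
  mk <- function(animal, arm, totals) {
    data.frame(animal = animal, arm = arm, epoch_index = -2:5,
               total_seizure_time_s = totals, n_seizures = 10L,
               mean_seizure_duration_s = 15)
  }
  metrics <- rbind(
    mk("v1", "vehicle", rep(250, 8)),
    mk("v2", "vehicle", rep(250, 8)),
    mk("d1", "drug", c(240, 260, rep(125, 6))),
    mk("d2", "drug", c(240, 260, rep(125, 6))))
  nm <- normalize_metrics(metrics)
  d_trt <- nm$arm == "drug" & nm$epoch_index >= 0 &
    nm$parameter == "total_time"
  # 125 / mean(240, 260) * 100 = 50% of control; vehicle stays at 100
  expect_true(all(abs(nm$pct_control[d_trt] - 50) < 1e-9))
  expect_true(all(abs(nm$pct_vehicle[d_trt] - 50) < 1e-9))
  veh <- nm$arm == "vehicle" & nm$parameter == "total_time"
  expect_true(all(abs(nm$pct_vehicle[veh] - 100) < 1e-9))
})

test_that("vehicle self-normalization is an exact fixed point", {
  ex <- run_experiment(c(vehicle = 3), what = "metrics", fs = 128,
                       seed = 3, design = small_design())
  nm <- normalize_metrics(ex$metrics, small_design())
  for (p in c("total_time", "n_seizures")) {
    sub <- nm[nm$parameter == p & nm$epoch_index >= 0, ]
    gm <- tapply(sub$pct_vehicle, sub$epoch_index, mean, na.rm = TRUE)
    expect_true(all(abs(gm - 100) < 1e-9))
  }
})

test_that("zero-seizure epochs yield missing mean duration downstream", {
  ev <- event_list(start_s = c(-2000, -800), end_s = c(-1980, -780),
                   label = c("swd", "swd"), accepted = TRUE)
  m <- epoch_metrics(ev)
  m$animal <- "a1"; m$arm <- "drug"
  nm <- normalize_metrics(rbind(m, within(m, animal <- "a2")))
  trt <- nm$parameter == "mean_duration" & nm$epoch_index >= 0
  expect_true(all(is.na(nm$value[trt])))
  expect_true(all(is.na(nm$pct_control[trt])))
})

test_that("overall effect averages animal means of treatment epochs", {
  nm <- expand.grid(animal = c("d1", "d2", "d3"), epoch_index = 0:5,
                    parameter = "total_time", stringsAsFactors = FALSE)
  nm$arm <- "drug"
  nm$pct_vehicle <- rep(c(30, 32, 28), 6)
  oe <- overall_effect(nm, "drug", "total_time")
  expect_equal(oe$group_mean_pct, 30)
  expect_equal(oe$percent_change, 70)
  expect_equal(oe$direction, "decrease")
  expect_equal(oe$sem_pct, sd(c(30, 32, 28)) / sqrt(3))
  expect_error(overall_effect(nm[nm$animal == "d1", ], "drug", "total_time"),
               "2 animals")
})

test_that("two-way ANOVA reports near-null statistics for identical groups", {
  set.seed(41)
  nm <- expand.grid(animal = sprintf("a%02d", 1:12), epoch_index = 0:5,
                    parameter = "total_time", stringsAsFactors = FALSE)
  nm$arm <- ifelse(as.integer(sub("a", "", nm$animal)) <= 6,
                   "vehicle", "drug")
  nm$pct_control <- 100 + rnorm(nrow(nm), 0, 5)
  res <- anova_two_way(nm, "total_time")
  p_drug <- res$anova[rownames(res$anova) == "arm", "Pr(>F)"]
  expect_gt(p_drug, 0.01)
  expect_true(all(res$sidak$p_sidak >= res$sidak$p))
  expect_true(all(res$sidak$p_sidak <= 1))
  expect_equal(nrow(res$dunnett), 1L)
})

test_that("a strong simulated drug effect is detected by the ANOVA battery", {
  set.seed(42)
  nm <- expand.grid(animal = sprintf("a%02d", 1:16), epoch_index = 0:5,
                    parameter = "total_time", stringsAsFactors = FALSE)
  drug <- as.integer(sub("a", "", nm$animal)) > 8
  nm$arm <- ifelse(drug, "drug", "vehicle")
  nm$pct_control <- ifelse(drug, 30, 100) + rnorm(nrow(nm), 0, 15)
  res <- anova_two_way(nm, "total_time")
  expect_lt(res$anova[rownames(res$anova) == "arm", "Pr(>F)"], 0.001)
  expect_true(all(res$dunnett$p_adj < 0.01))
  expect_true(all(res$sidak$p_sidak < 0.05))
})

test_that("peak-frequency comparison uses a pooled unpaired t-test", {
  r <- peak_freq_test(c(7, 7.1, 6.9), c(7.0, 7.1, 6.9))
  expect_gt(r$p, 0.9)
  r <- peak_freq_test(c(7.0, 7.1, 7.05, 7.2), c(7.6, 7.5, 7.7, 7.65))
  expect_lt(r$p, 0.001)
  # matches stats::t.test directly
  a <- c(6.8, 7.0, 7.2); b <- c(7.4, 7.6, 7.5)
  expect_equal(peak_freq_test(a, b)$p,
               t.test(a, b, var.equal = TRUE)$p.value)
  expect_error(peak_freq_test(7, c(7, 8)), "2 animals")
})
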