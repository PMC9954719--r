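sched <- make_schedule()

# events fixture: one recording, one shape, with chosen spikes in level 1 trial 1
events_with <- function(times, n_levels = 20, n_reps = 32) {
  data.frame(recording_id = "r1", shape_id = "s1",
             level_index = 1L, trial_index = 1L, spike_time_ms = times)
}

test_that("window counting follows the 9-45 ms evoked and 150-250 ms spontaneous rules", {
  cw <- count_windows(events_with(c(10, 20, 44)), sched)
  expect_equal(cw$evoked_rate_Hz[cw$level_index == 1 & cw$trial_index == 1],
               3 / 0.036)
  # spikes before the 9 ms latency floor are discarded from the evoked count
  cw <- count_windows(events_with(c(5, 8.9)), sched)
  expect_equal(cw$evoked_rate_Hz[1], 0)
  cw <- count_windows(events_with(c(150, 170, 200, 249.9)), sched)
  expect_equal(cw$spont_rate_Hz[1], 40)
  expect_equal(cw$evoked_rate_Hz[1], 0)
  # full zero-filled grid comes back
  expect_equal(nrow(cw), 20 * 32)
  expect_error(count_windows(events_with(c(10, 260)), sched), "input-format")
  expect_error(count_windows(events_with(-1), sched), "input-format")
  expect_error(count_windows(events_with(10), sched,
                             evoked_window = c(9, 200)), "disjoint")
})

test_that("growth functions average across repetitions and pool the baseline", {
  gt <- ground_truth(spont_rate_Hz = 8, Rmax_Hz = 60, Q50_nC = 14)
  ev <- simulate_recording(gt, schedule = sched, seed = 21)
  gf <- build_growth_function(count_windows(ev, sched), sched)
  expect_length(gf$mean_rate_Hz, 20)
  expect_equal(gf$subtracted_rate_Hz, gf$mean_rate_Hz - gf$spont_mean_Hz)
  # plateau of the sigmoid: top levels sit near Rmax above baseline
  expect_lt(abs(mean(tail(gf$subtracted_rate_Hz, 3)) - 60), 15)
  expect_lt(abs(gf$spont_mean_Hz - 8), 3 * sqrt(8 / 0.1 / 640))
  # missing levels are a protocol error
  part <- count_windows(ev, sched)
  part <- part[part$level_index <= 10, ]
  expect_error(build_growth_function(part, sched), "incomplete-protocol")
})

test_that("an empty-response recording yields a flat zero growth function", {
  ev <- data.frame(recording_id = "r1", shape_id = "s1", level_index = 1L,
                   trial_index = 1L, spike_time_ms = 100)  # one ignored spike
  gf <- build_growth_function(count_windows(ev, sched), sched)
  expect_equal(gf$mean_rate_Hz, rep(0, 20))
  expect_equal(gf$spont_mean_Hz, 0)
  expect_true(is.na(detect_threshold(gf)))
})

test_that("threshold detection applies the 3-SD criterion with two-successor confirmation", {
  # first significant run starts at level 4
  sig <- c(FALSE, FALSE, FALSE, rep(TRUE, 17))
  expect_equal(detect_threshold(gf_from_pattern(sig)), 4)
  # isolated significant levels never qualify
  sig <- rep(c(FALSE, TRUE), 10)
  expect_true(is.na(detect_threshold(gf_from_pattern(sig))))
  # a run at the top two levels has no two successors
  sig <- c(rep(FALSE, 18), TRUE, TRUE)
  expect_true(is.na(detect_threshold(gf_from_pattern(sig))))
  # ...but a run starting at level 18 does
  sig <- c(rep(FALSE, 17), TRUE, TRUE, TRUE)
  expect_equal(detect_threshold(gf_from_pattern(sig)), 18)
  expect_error(detect_threshold(make_gf(c(1, 2))), "at least 3")
  # the multiplier is configurable: with 1 SD the criterion line drops
  gf <- make_gf(c(2, 2, 2, rep(10, 17)), spont_mean_Hz = 0, spont_sd_Hz = 1)
  expect_equal(detect_threshold(gf, sd_multiplier = 1), 1)
  expect_equal(detect_threshold(gf, sd_multiplier = 3), 4)
})

test_that("threshold detection agrees with the exhaustive-scan oracle on random patterns", {
  set.seed(202)
  for (i in 1:200) {
    sig <- runif(20) < runif(1, 0.1, 0.9)
    gf <- gf_from_pattern(sig)
    expect_identical(detect_threshold(gf), threshold_oracle(sig))
  }
})

test_that("parameter extraction reproduces the worked example", {
  # subtracted rates {0,5,30,50,50} over {3,4.5,6,7.5,9} nC, baseline 0 +/- 2:
  # significant from level 3 on, so threshold 6 nC
  gf <- make_gf(c(0, 5, 30, 50, 50), levels_nC = c(3, 4.5, 6, 7.5, 9),
                spont_mean_Hz = 0, spont_sd_Hz = 2)
  q <- extract_params(gf)
  expect_equal(q$threshold_nC, 6)
  expect_equal(q$max_fr_Hz, 50)
  expect_equal(q$charge_at_max_nC, 7.5)    # ties broken toward lower charge
  expect_equal(q$dyn_range_nC, 1.5)
  expect_equal(q$dyn_range80_nC, 7.5 - 6)  # first level at 80% of MaxFR
  expect_true(q$significant)
})

test_that("flat and strictly increasing growth functions behave at the extremes", {
  q <- extract_params(make_gf(rep(0, 20)))
  expect_equal(q$max_fr_Hz, 0)
  expect_true(is.na(q$threshold_nC))
  expect_true(is.na(q$dyn_range_nC) && is.na(q$dyn_range80_nC))
  expect_false(q$significant)
  # strictly increasing: the 80% crossing precedes the max
  gf <- make_gf(seq(0, 95, by = 5), spont_mean_Hz = 0, spont_sd_Hz = 1)
  q <- extract_params(gf)
  expect_equal(q$charge_at_max_nC, 20)
  expect_lt(q$dyn_range80_nC, q$dyn_range_nC)
})

test_that("thresholds and ranges are invariant to a common rate offset", {
  base <- c(0, 0, 2, 8, 20, 35, 48, 55, 58, 59, rep(60, 10))
  gf0 <- make_gf(base, spont_mean_Hz = 5, spont_sd_Hz = 4)
  gf1 <- make_gf(base + 13, spont_mean_Hz = 18, spont_sd_Hz = 4)
  q0 <- extract_params(gf0)
  q1 <- extract_params(gf1)
  expect_equal(q1$threshold_nC, q0$threshold_nC)
  expect_equal(q1$dyn_range_nC, q0$dyn_range_nC)
  expect_equal(q1$dyn_range80_nC, q0$dyn_range80_nC)
  expect_equal(q1$max_fr_Hz, q0$max_fr_Hz)
})

test_that("MaxFR ignores level order; the tie-break does not", {
  set.seed(7)
  rates <- c(runif(18, 0, 40), 50, 50)
  gf <- make_gf(rates)
  q <- extract_params(gf)
  for (i in 1:10) {
    p <- sample(20)
    qp <- extract_params(make_gf(rates[p]))
    expect_equal(qp$max_fr_Hz, q$max_fr_Hz)
  }
  # tied maxima at levels 19 and 20: lowest charge wins
  expect_equal(q$charge_at_max_nC, 19)
  expect_equal(extract_params(make_gf(rev(rates)))$charge_at_max_nC, 1)
})

test_that("the vectorized cohort path matches the single-recording path", {
  eff <- default_shape_effects()[c("Rec-C", "FS80-C")]
  co <- simulate_cohort(3, eff, sched, seed = 31)
  q_fast <- quantify_recordings(co$events, sched)
  counts <- count_windows(co$events, sched)
  for (i in seq_len(nrow(q_fast))) {
    d <- counts[counts$recording_id == q_fast$recording_id[i] &
                  counts$shape_id == q_fast$shape_id[i], ]
    q_slow <- extract_params(build_growth_function(d, sched))
    expect_equal(q_fast$max_fr_Hz[i], q_slow$max_fr_Hz, tolerance = 1e-9)
    expect_equal(q_fast$threshold_nC[i], q_slow$threshold_nC)
    expect_equal(q_fast$dyn_range_nC[i], q_slow$dyn_range_nC)
  }
})

test_that("recording-level early-onset screening flags sub-9 ms responders", {
  gt_early <- ground_truth(spont_rate_Hz = 0, Rmax_Hz = 80, Q50_nC = 10,
                           latency_mean_ms = 9, latency_sd_ms = 0.1)
  gt_late <- ground_truth(spont_rate_Hz = 0, Rmax_Hz = 80, Q50_nC = 10,
                          latency_mean_ms = 20, latency_sd_ms = 1)
  ev <- rbind(
    simulate_recording(gt_early, schedule = sched, seed = 41,
                       recording_id = "early", evoked_window = c(5, 45)),
    simulate_recording(gt_late, schedule = sched, seed = 42,
                       recording_id = "late"))
  flagged <- early_onset_recordings(ev, sched)
  expect_true("early" %in% flagged)
  expect_false("late" %in% flagged)
})
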