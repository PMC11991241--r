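# Synthetic cohort generator.

tiny_cfg <- function(...) {
  args <- utils::modifyList(list(n_subjects = 2, n_older = 1,
                                 trial_seconds = 4, seed = 5), list(...))
  do.call(simulation_config, args)
}

test_that("all-zero amplitudes give an all-zero signal", {
  cfg <- tiny_cfg(band_amp_high = c(theta = 0, alpha = 0, beta = 0),
                  pink_rms = 0, line_amp = 0, muscle_amp = 0,
                  older_noise_rms = 0)
  rec <- simulate_eeg(cfg, "high", "optimal", "s01")
  expect_true(all(rec$data == 0))
  expect_equal(dim(rec$data), c(14, 4 * 128))
})

test_that("high class has larger beta and smaller alpha power than low in every channel", {
  cfg <- tiny_cfg(trial_seconds = 8)
  hi <- simulate_eeg(cfg, "high", "optimal", "s02")
  lo <- simulate_eeg(cfg, "low", "optimal", "s02")
  beta_hi <- apply(hi$data, 1, periodogram_band_power, fs = 128, lo = 13, hi = 30)
  beta_lo <- apply(lo$data, 1, periodogram_band_power, fs = 128, lo = 13, hi = 30)
  alpha_hi <- apply(hi$data, 1, periodogram_band_power, fs = 128, lo = 8, hi = 13)
  alpha_lo <- apply(lo$data, 1, periodogram_band_power, fs = 128, lo = 8, hi = 13)
  expect_true(all(beta_hi > beta_lo))
  expect_true(all(alpha_hi < alpha_lo))
})

test_that("a pure alpha oscillation concentrates its power in the alpha band", {
  cfg <- tiny_cfg(band_amp_high = c(theta = 0, alpha = 5, beta = 0),
                  pink_rms = 0, line_amp = 0, muscle_amp = 0,
                  older_noise_rms = 0, band_centers = c(theta = 6, alpha = 10,
                                                        beta = 21.5))
  rec <- simulate_eeg(cfg, "high", "optimal", "s02")
  x <- rec$data[1, ]
  in_alpha <- periodogram_band_power(x, 128, 8, 13)
  total <- periodogram_band_power(x, 128, 4, 30)
  expect_gte(in_alpha / total, 0.99)
})

test_that("oscillation-only configs leak < 1% of broadband power outside the bands", {
  cfg <- tiny_cfg(pink_rms = 0, line_amp = 0, muscle_amp = 0,
                  older_noise_rms = 0, trial_seconds = 8)
  rec <- simulate_eeg(cfg, "low", "hard", "s02")
  for (ch in c(1, 7, 14)) {
    x <- rec$data[ch, ]
    inside <- periodogram_band_power(x, 128, 4, 8) +
      periodogram_band_power(x, 128, 8, 13) +
      periodogram_band_power(x, 128, 13, 30)
    total <- periodogram_band_power(x, 128, 0.5, 45)
    expect_lt(1 - inside / total, 0.01)
  }
})

test_that("generators are bit-deterministic and substreams are independent", {
  cfg <- tiny_cfg()
  expect_identical(simulate_eeg(cfg, "high", "easy", "s01")$data,
                   simulate_eeg(cfg, "high", "easy", "s01")$data)
  expect_identical(simulate_game_metrics(cfg, "s01"),
                   simulate_game_metrics(cfg, "s01"))
  expect_identical(simulate_flow_responses(cfg, "hard", "s01")$items,
                   simulate_flow_responses(cfg, "hard", "s01")$items)
  # different sessions draw from different substreams
  expect_false(identical(simulate_eeg(cfg, "high", "easy", "s01")$data,
                         simulate_eeg(cfg, "high", "hard", "s01")$data))
})

test_that("simulated metrics are non-negative, non-decreasing, and recover the configured peak", {
  for (p in c(1, 2, 4, 6, 9)) {
    cfg <- simulation_config(metric_peak_level = p, seed = 2)
    tab <- simulate_game_metrics(cfg)
    expect_true(all(tab$TC >= 0 & tab$TM >= 0 & tab$OH >= 0))
    expect_true(all(diff(tab$TC) >= 0))
    expect_true(all(diff(tab$TM) >= 0))
    expect_true(all(diff(tab$OH) >= 0))
    expect_identical(suppressWarnings(calibrate_levels(tab))$optimal_level,
                     as.integer(p))
  }
  expect_error(simulation_config(metric_peak_level = 10), "1..9")
})

test_that("metric jitter keeps invariants and different seeds differ", {
  a <- simulate_game_metrics(simulation_config(metric_noise_sd = 3, seed = 1))
  b <- simulate_game_metrics(simulation_config(metric_noise_sd = 3, seed = 2))
  expect_false(identical(a, b))
  for (tab in list(a, b)) {
    expect_true(all(diff(tab$TM) >= 0) && all(tab$TM >= 0))
  }
})

test_that("flow responses hit ceiling/floor under extreme effects and order optimal > hard on average", {
  up <- tiny_cfg(flow_effect = c(easy = 50, optimal = 50, hard = 50))
  expect_equal(rated_score(simulate_flow_responses(up, "easy", "s01")), 7)
  down <- tiny_cfg(flow_effect = c(easy = -50, optimal = -50, hard = -50))
  expect_equal(rated_score(simulate_flow_responses(down, "easy", "s01")), 0)
  cfg <- simulation_config(n_subjects = 300, seed = 9)
  ids <- sprintf("s%02d", 1:300)
  opt <- vapply(ids, function(s)
    rated_score(simulate_flow_responses(cfg, "optimal", s)), 0)
  hrd <- vapply(ids, function(s)
    rated_score(simulate_flow_responses(cfg, "hard", s)), 0)
  esy <- vapply(ids, function(s)
    rated_score(simulate_flow_responses(cfg, "easy", s)), 0)
  expect_gt(mean(opt), mean(esy))
  expect_gt(mean(esy), mean(hrd))
})

test_that("cohorts assemble consistently", {
  cfg <- tiny_cfg()
  coh <- simulate_cohort(cfg)
  expect_length(coh$recordings, 6)
  expect_identical(coh$subjects$age_group, c("older", "young"))
  expect_identical(nrow(coh$labels), 6L)
  # labels and recordings agree on keys
  expect_setequal(names(coh$recordings),
                  paste(coh$labels$subject_id, coh$labels$session, sep = "/"))
})
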