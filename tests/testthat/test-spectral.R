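# Multitaper PSD, band powers and engagement indices.

test_that("multitaper PSD satisfies Parseval and is zero for a null signal", {
  expect_true(all(multitaper_psd(numeric(128), 128)$psd == 0))
  # deterministic broadband signal: integral within 5% of mean-square power
  t <- (0:127) / 128
  x <- 1.5 * sin(2 * pi * 5.3 * t) + sin(2 * pi * 10.2 * t + 1) +
    0.8 * sin(2 * pi * 22.7 * t + 2)
  psd <- multitaper_psd(x, 128)
  expect_equal(band_power(psd, c(0, 64)), sum(x^2) / 128, tolerance = 0.05)
  # stochastic signal: ratio centered on 1 across realisations
  set.seed(41)
  ratios <- vapply(1:200, function(i) {
    z <- rnorm(128)
    band_power(multitaper_psd(z, 128), c(0, 64)) / (sum(z^2) / 128)
  }, 0)
  expect_equal(mean(ratios), 1, tolerance = 0.05)
})

test_that("a 10 Hz sinusoid concentrates in alpha with power near A^2/2", {
  t <- (0:127) / 128
  for (amp in c(1, 3)) {
    x <- amp * sin(2 * pi * 10 * t)
    psd <- multitaper_psd(x, 128)
    a <- band_power(psd, c(8, 13))
    expect_gte(a / band_power(psd, c(0.5, 45)), 0.90)
    expect_equal(a, amp^2 / 2, tolerance = 0.10)
  }
})

test_that("white-noise PSD is flat within 10% across 4-30 Hz on average", {
  set.seed(42)
  n_ep <- 1000
  acc <- 0
  for (i in seq_len(n_ep)) acc <- acc + multitaper_psd(rnorm(128), 128)$psd
  mean_psd <- acc / n_ep
  f <- multitaper_psd(rnorm(128), 128)$freq
  band <- mean_psd[f >= 4 & f <= 30]
  expect_lt(max(band) / mean(band), 1.10)
  expect_gt(min(band) / mean(band), 0.90)
})

test_that("band powers are additive over contiguous bands and scale quadratically", {
  set.seed(43)
  x <- rnorm(128)
  psd <- multitaper_psd(x, 128)
  parts <- band_power(psd, c(0.5, 4)) + band_power(psd, c(4, 8)) +
    band_power(psd, c(8, 13)) + band_power(psd, c(13, 30)) +
    band_power(psd, c(30, 45))
  expect_equal(parts, band_power(psd, c(0.5, 45)), tolerance = 1e-10)
  psd2 <- multitaper_psd(2 * x, 128)
  expect_equal(band_power(psd2, c(8, 13)), 4 * band_power(psd, c(8, 13)),
               tolerance = 1e-10)
  expect_error(band_power(psd, c(100, 110)), "empty")
})

test_that("engagement indices follow their definitions and the eps floor", {
  ei <- engagement_indices(1, 1, 2)
  expect_equal(c(ei$E1, ei$E2, ei$E3), c(1, 2, 1))
  expect_false(ei$floored)
  fl <- engagement_indices(0, 0, 1, eps = 1e-12)
  expect_true(all(is.finite(c(fl$E1, fl$E2, fl$E3))))
  expect_true(fl$floored)
  expect_error(engagement_indices(-1, 1, 1), ">= 0")
})

test_that("E1/E2 are invariant to amplitude scaling; E3 scales inverse-square", {
  set.seed(44)
  x <- rnorm(128) + 2 * sin(2 * pi * 10 * (0:127) / 128)
  p1 <- multitaper_psd(x, 128); p3 <- multitaper_psd(3 * x, 128)
  bp <- function(p, b) band_power(p, b)
  e1 <- engagement_indices(bp(p1, c(4, 8)), bp(p1, c(8, 13)), bp(p1, c(13, 30)))
  e3 <- engagement_indices(bp(p3, c(4, 8)), bp(p3, c(8, 13)), bp(p3, c(13, 30)))
  expect_equal(e3$E1, e1$E1, tolerance = 1e-9)
  expect_equal(e3$E2, e1$E2, tolerance = 1e-9)
  expect_equal(e3$E3, e1$E3 / 9, tolerance = 1e-9)
})

test_that("high-engagement epochs show larger mean E1/E2 and larger E3 than low", {
  cfg <- simulation_config(n_subjects = 1, n_older = 0, trial_seconds = 20,
                           seed = 45)
  fhi <- build_feature_table(list(
    epoch_recording(bandpass_filter(simulate_eeg(cfg, "high", "optimal", "s01")),
                    label = "high")), channel_mode = "channel-mean")
  flo <- build_feature_table(list(
    epoch_recording(bandpass_filter(simulate_eeg(cfg, "low", "hard", "s01")),
                    label = "low")), channel_mode = "channel-mean")
  expect_gt(mean(fhi$E1_mean), mean(flo$E1_mean))
  expect_gt(mean(fhi$E2_mean), mean(flo$E2_mean))
  # high engagement = smaller alpha power = larger inverse-alpha index
  expect_gt(mean(fhi$E3_mean), mean(flo$E3_mean))
})

test_that("feature table geometry: per-channel vs channel-mean, neutral exclusion", {
  cfg <- simulation_config(n_subjects = 1, n_older = 0, trial_seconds = 5,
                           seed = 46)
  rec <- bandpass_filter(simulate_eeg(cfg, "high", "optimal", "s01"))
  eps <- list(epoch_recording(rec, label = "high"),
              epoch_recording(simulate_eeg(cfg, "low", "hard", "s01"),
                              label = "low"),
              epoch_recording(rec, label = "neutral"))
  expect_message(ft <- build_feature_table(eps), "excluding 5 epochs")
  expect_equal(nrow(ft), 10)
  expect_length(attr(ft, "feature_cols"), 42)
  ft1 <- build_feature_table(eps[1:2], feature_set = "e3",
                             channel_mode = "channel-mean")
  expect_identical(attr(ft1, "feature_cols"), "E3_mean")
  expect_error(build_feature_table(list(epoch_recording(rec))), "label")
})
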