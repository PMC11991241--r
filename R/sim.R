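# Synthetic cohort generator.
#
# No raw recordings from the gameplay study are publicly available, so every
# downstream stage is exercised on generated data that carries the statistical
# structure the analysis assumes: band-limited neural oscillations riding on
# 1/f background noise with class-dependent alpha/beta power, optional 60 Hz
# line and 30-45 Hz muscle-burst contamination; per-level gameplay metrics
# whose Performance Index peaks at a configurable interior level; and
# flow-scale responses whose mean rated score is highest at the optimal level.

epocx_channels <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1", "O2",
                    "P8", "T8", "FC6", "F4", "F8", "AF4")

#' Simulation configuration
#'
#' Holds every knob of the synthetic cohort generator. Identical config plus
#' seed gives bit-identical output; each (subject, session, generator) triple
#' draws from its own deterministic substream, so adding one generator never
#' perturbs another.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param n_older how many subjects (the first ones) are flagged older-adult.
#' @param fs sampling rate, Hz.
#' @param n_channels channel count; defaults to the 14-electrode saline
#'   headset montage (AF3 ... AF4).
#' @param channel_names channel labels, length `n_channels`.
#' @param trial_seconds recording duration per session, s.
#' @param band_amp_high,band_amp_low named numeric `(theta, alpha, beta)`
#'   oscillation amplitudes (uV) for the high- and low-engagement classes.
#'   Defaults encode the assumed physiology: high engagement has larger beta
#'   and smaller alpha power than low engagement.
#' @param band_centers oscillation centre frequencies, Hz.
#' @param pink_exponent 1/f spectral slope of the background noise.
#' @param pink_rms RMS amplitude (uV) of the background noise.
#' @param line_hz powerline frequency, Hz.
#' @param line_amp powerline sinusoid amplitude, uV.
#' @param muscle_burst_rate muscle bursts per minute.
#' @param muscle_amp burst amplitude (uV) in the 30-45 Hz band.
#' @param older_gain global amplitude factor applied to older-adult signals.
#' @param older_noise_rms extra white-noise floor (uV) for older adults.
#' @param metric_peak_level level in 1..9 where the simulated Performance
#'   Index peaks (an interior peak at level 10 is impossible: with
#'   non-decreasing metrics the normalised columns are all 1 there, which
#'   pins PI(10) at its minimum bound).
#' @param metric_noise_sd SD of integer jitter on the gameplay counts
#'   (0 = deterministic).
#' @param flow_effect named `(easy, optimal, hard)` mean item scores of the
#'   flow responses; defaults are the study-condition means 4.91/5.51/4.59.
#' @param flow_subject_sd between-subject SD of the flow offset.
#' @param flow_session_sd named `(easy, optimal, hard)` SDs of the
#'   subject-by-level interaction (a player's flow response to a specific
#'   difficulty); defaults chosen so the simulated per-level rated-score SDs
#'   match the study conditions (about 0.8/0.65/1.15).
#' @param flow_item_sd within-response item SD.
#' @param seed master integer RNG seed.
#' @return An object of class `simulation_config` (validated list).
#' @export
simulation_config <- function(n_subjects = 16, n_older = 3, fs = 128,
                              n_channels = 14, channel_names = epocx_channels,
                              trial_seconds = 120,
                              band_amp_high = c(theta = 4, alpha = 3, beta = 8),
                              band_amp_low = c(theta = 4, alpha = 8, beta = 3),
                              band_centers = c(theta = 6, alpha = 10.5, beta = 21.5),
                              pink_exponent = 1, pink_rms = 4,
                              line_hz = 60, line_amp = 1,
                              muscle_burst_rate = 2, muscle_amp = 2,
                              older_gain = 0.8, older_noise_rms = 1,
                              metric_peak_level = 4, metric_noise_sd = 0,
                              flow_effect = c(easy = 4.91, optimal = 5.51, hard = 4.59),
                              flow_subject_sd = 0.55,
                              flow_session_sd = c(easy = 0.5, optimal = 0.25, hard = 1),
                              flow_item_sd = 1,
                              seed = 1L) {
  assert_that(fs > 0, "fs must be > 0")
  assert_that(trial_seconds > 0, "trial_seconds must be > 0")
  assert_that(n_subjects >= 1 && n_older >= 0 && n_older <= n_subjects,
              "need 0 <= n_older <= n_subjects")
  assert_that(length(channel_names) == n_channels,
              "channel_names must have length n_channels")
  for (v in list(band_amp_high, band_amp_low))
    assert_that(all(c("theta", "alpha", "beta") %in% names(v)) && all(v >= 0),
                "band amplitudes must be named (theta, alpha, beta) and >= 0")
  assert_that(pink_rms >= 0 && line_amp >= 0 && muscle_amp >= 0 &&
              muscle_burst_rate >= 0, "all amplitudes/rates must be >= 0")
  assert_that(metric_peak_level == round(metric_peak_level) &&
              metric_peak_level >= 1 && metric_peak_level <= 9,
              "metric_peak_level must be an integer in 1..9")
  assert_that(all(c("easy", "optimal", "hard") %in% names(flow_effect)),
              "flow_effect must be named (easy, optimal, hard)")
  assert_that(all(c("easy", "optimal", "hard") %in% names(flow_session_sd)) &&
              all(flow_session_sd >= 0),
              "flow_session_sd must be named (easy, optimal, hard) and >= 0")
  cfg <- as.list(environment())
  structure(cfg, class = "simulation_config")
}

subject_ids <- function(cfg) sprintf("s%02d", seq_len(cfg$n_subjects))

age_groups <- function(cfg) {
  ifelse(seq_len(cfg$n_subjects) <= cfg$n_older, "older", "young")
}

# 1/f noise by spectral shaping of white Gaussian noise (DC removed), scaled
# to a target RMS.
pink_noise <- function(n, exponent, rms) {
  if (rms == 0) return(numeric(n))
  spec <- fft(rnorm(n))
  f <- c(1, seq_len(n - 1))                    # avoid 0; DC zeroed below
  f <- pmin(f, n - f)                          # two-sided frequency index
  shape <- f^(-exponent / 2)
  shape[1] <- 0
  x <- Re(fft(spec * shape, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

# Amplitude-modulated sinusoid with unit mean-square envelope, so the
# expected power of amp * osc is amp^2 / 2.
am_oscillation <- function(n, fs, f_center, amp) {
  if (amp == 0) return(numeric(n))
  t <- (0:(n - 1)) / fs
  m <- 0.5
  f_mod <- runif(1, 0.1, 0.4)
  env <- (1 + m * sin(2 * pi * f_mod * t + runif(1, 0, 2 * pi))) /
    sqrt(1 + m^2 / 2)
  amp * env * sin(2 * pi * f_center * t + runif(1, 0, 2 * pi))
}

muscle_bursts <- function(n, fs, rate_per_min, amp) {
  x <- numeric(n)
  if (rate_per_min == 0 || amp == 0) return(x)
  n_bursts <- rbinom(1, max(1, round(rate_per_min * n / fs / 60 * 2)), 0.5) +
    round(rate_per_min * n / fs / 60 / 2)
  if (n_bursts == 0) return(x)
  len <- round(0.5 * fs)
  win <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = len)))
  t <- (0:(len - 1)) / fs
  for (b in seq_len(n_bursts)) {
    start <- sample.int(max(1, n - len), 1)
    burst <- rowSums(vapply(c(32, 37, 42), function(fb)
      sin(2 * pi * fb * t + runif(1, 0, 2 * pi)), numeric(len)))
    x[start:(start + len - 1)] <- x[start:(start + len - 1)] + amp * win * burst
  }
  x
}

#' Simulate one EEG recording
#'
#' Generates a `trial_seconds x fs`-sample, `n_channels`-channel recording for
#' one engagement class: per-band amplitude-modulated oscillations (class
#' amplitudes from `band_amp_high`/`band_amp_low`, jittered +/-20% per
#' channel) over 1/f noise, plus optional powerline and muscle-burst
#' contamination. With all amplitudes zero the output is identically zero.
#' The noise substream depends only on (seed, subject, session), so the same
#' configuration compared across classes shares its noise realisation.
#'
#' @param cfg a [simulation_config()].
#' @param class_label `"high"` or `"low"` engagement.
#' @param session level tag (`"easy"`, `"optimal"`, `"hard"`).
#' @param subject_id subject key; also selects the older-adult attenuation
#'   when the subject index is `<= n_older`.
#' @return An [eeg_recording()].
#' @export
simulate_eeg <- function(cfg, class_label = c("high", "low"),
                         session = c("easy", "optimal", "hard"),
                         subject_id = "s01") {
  assert_that(inherits(cfg, "simulation_config"), "cfg must be a simulation_config")
  class_label <- match.arg(class_label)
  session <- match.arg(session)
  n <- round(cfg$trial_seconds * cfg$fs)
  amps <- if (class_label == "high") cfg$band_amp_high else cfg$band_amp_low
  older <- subject_id %in% subject_ids(cfg)[seq_len(cfg$n_older)]

  # electrode-gain jitter is a subject-level property: stable across the
  # subject's sessions, so sessions differ only through class and noise
  gains <- with_seed(substream_seed(cfg$seed, subject_id, "chan_gain"),
                     matrix(runif(cfg$n_channels * 3, 0.8, 1.2),
                            cfg$n_channels, 3,
                            dimnames = list(NULL, c("theta", "alpha", "beta"))))

  data <- with_seed(substream_seed(cfg$seed, subject_id, session, "eeg", class_label), {
    mat <- matrix(0, cfg$n_channels, n)
    for (ch in seq_len(cfg$n_channels)) {
      x <- numeric(n)
      for (b in c("theta", "alpha", "beta")) {
        x <- x + am_oscillation(n, cfg$fs, cfg$band_centers[[b]],
                                amps[[b]] * gains[ch, b])
      }
      mat[ch, ] <- x
    }
    mat
  })
  noise <- with_seed(substream_seed(cfg$seed, subject_id, session, "noise"), {
    mat <- matrix(0, cfg$n_channels, n)
    t <- (0:(n - 1)) / cfg$fs
    for (ch in seq_len(cfg$n_channels)) {
      x <- pink_noise(n, cfg$pink_exponent, cfg$pink_rms)
      if (cfg$line_amp > 0)
        x <- x + cfg$line_amp * sin(2 * pi * cfg$line_hz * t + runif(1, 0, 2 * pi))
      x <- x + muscle_bursts(n, cfg$fs, cfg$muscle_burst_rate, cfg$muscle_amp)
      if (older && cfg$older_noise_rms > 0)
        x <- x + rnorm(n, sd = cfg$older_noise_rms)
      mat[ch, ] <- x
    }
    mat
  })
  gain <- if (older) cfg$older_gain else 1
  eeg_recording(gain * data + noise, channel_names = cfg$channel_names,
                fs = cfg$fs, subject_id = subject_id, session = session)
}

#' Simulate a per-level gameplay metric table
#'
#' Builds ten levels of non-negative, non-decreasing integer counts (TC
#' collected, TM missed, OH obstacle hits) constructed so that, noise-free,
#' the calibrated Performance Index attains its maximum exactly at
#' `metric_peak_level`: collected items grow linearly with level while misses
#' and obstacle hits grow slowly up to the peak level and steeply after it.
#' Optional integer jitter (`metric_noise_sd`) preserves monotonicity via a
#' running maximum.
#'
#' @param cfg a [simulation_config()].
#' @param subject_id subject key (selects the jitter substream).
#' @return A data frame with columns `level`, `TC`, `TM`, `OH` (levels 1..10).
#' @export
simulate_game_metrics <- function(cfg, subject_id = "s01") {
  assert_that(inherits(cfg, "simulation_config"), "cfg must be a simulation_config")
  p <- cfg$metric_peak_level
  levels <- 1:10
  tc_n <- (levels - 1) / 9
  # penalty increments: slow (0.03/level) through the peak, then steep
  s <- 0.03
  inc <- rep(s, 9)
  if (p < 9) {
    large <- (1 - s * (p - 1)) / (10 - p)
    inc[p:9] <- large
  } else {
    inc[9] <- 1 - s * 8
  }
  pen_n <- c(0, cumsum(inc))
  pen_n <- pen_n / max(pen_n)
  tab <- data.frame(level = levels,
                    TC = 30L + as.integer(round(100 * tc_n)),
                    TM = as.integer(round(150 * pen_n)),
                    OH = 3L + as.integer(round(54 * pen_n)))
  if (cfg$metric_noise_sd > 0) {
    tab <- with_seed(substream_seed(cfg$seed, subject_id, "metrics"), {
      for (col in c("TC", "TM", "OH")) {
        x <- tab[[col]] + as.integer(round(rnorm(10, sd = cfg$metric_noise_sd)))
        tab[[col]] <- as.integer(cummax(pmax(x, 0)))
      }
      tab
    })
  }
  tab
}

#' Simulate one flow-scale response
#'
#' Draws 14 integer items in 0..7 around the session's mean item score
#' (`flow_effect`) plus a persistent subject-level offset, so that with the
#' default effects the expected rated score orders optimal > easy > hard.
#'
#' @param cfg a [simulation_config()].
#' @param session level tag.
#' @param subject_id subject key.
#' @return A [flow_response()].
#' @export
simulate_flow_responses <- function(cfg, session = c("easy", "optimal", "hard"),
                                    subject_id = "s01") {
  assert_that(inherits(cfg, "simulation_config"), "cfg must be a simulation_config")
  session <- match.arg(session)
  offset <- with_seed(substream_seed(cfg$seed, subject_id, "flow_subject"),
                      rnorm(1, sd = cfg$flow_subject_sd))
  lvl <- with_seed(substream_seed(cfg$seed, subject_id, session, "flow_level"),
                   rnorm(1, sd = cfg$flow_session_sd[[session]]))
  items <- with_seed(substream_seed(cfg$seed, subject_id, session, "flow"), {
    raw <- rnorm(14, mean = cfg$flow_effect[[session]] + offset + lvl,
                 sd = cfg$flow_item_sd)
    pmin(7L, pmax(0L, as.integer(round(raw))))
  })
  flow_response(items, subject_id = subject_id, session = session)
}

#' Simulate a full cohort
#'
#' For every subject: a gameplay metric table plus calibration, three
#' flow-scale responses (easy/optimal/hard) with their engagement labels, and
#' one EEG recording per session whose spectral class follows the session's
#' rated score (>= 4.5 points generates the high-engagement spectrum).
#'
#' @param cfg a [simulation_config()].
#' @param eeg generate EEG recordings (set `FALSE` for metric/flow-only runs).
#' @return A list of class `eeg_cohort`: `config`, `subjects` (tibble with
#'   `subject_id`, `age_group`), `metrics` (named list of data frames),
#'   `calibrations`, `responses` (list of [flow_response()]), `labels`
#'   (tibble from [label_sessions()]), `recordings` (named
#'   `subject_id/session` list of [eeg_recording()]).
#' @export
simulate_cohort <- function(cfg = simulation_config(), eeg = TRUE) {
  ids <- subject_ids(cfg)
  sessions <- c("easy", "optimal", "hard")
  metrics <- lapply(ids, function(s) simulate_game_metrics(cfg, s))
  names(metrics) <- ids
  calibs <- lapply(metrics, calibrate_levels)
  responses <- list()
  for (s in ids) for (ses in sessions)
    responses[[paste(s, ses, sep = "/")]] <- simulate_flow_responses(cfg, ses, s)
  labels <- label_sessions(responses)
  recordings <- NULL
  if (eeg) {
    recordings <- list()
    for (i in seq_len(nrow(labels))) {
      s <- labels$subject_id[i]; ses <- labels$session[i]
      cls <- if (labels$rated_score[i] >= 4.5) "high" else "low"
      recordings[[paste(s, ses, sep = "/")]] <-
        simulate_eeg(cfg, cls, ses, s)
    }
  }
  structure(list(config = cfg,
                 subjects = tibble::tibble(subject_id = ids,
                                           age_group = age_groups(cfg)),
                 metrics = metrics, calibrations = calibs,
                 responses = responses, labels = labels,
                 recordings = recordings),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf("<eeg_cohort> %d subjects (%d older), %d recordings, seed %d\n",
              x$config$n_subjects, x$config$n_older,
              length(x$recordings), x$config$seed))
  invisible(x)
}
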