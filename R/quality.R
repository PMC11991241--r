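# SNR-based signal quality index.
#
# Per channel, signal power is the theta + alpha + beta band power of the
# trial-averaged PSD; noise power is the 30-45 Hz muscle band plus a +/-1 Hz
# window around the powerline frequency, measured on the unfiltered signal
# (after the 45 Hz band-pass the line component would be gone). SNR in dB;
# a channel-mean at or below 0 dB marks a bad recording.

#' Per-channel SNR of a recording
#'
#' Averages 1-s multitaper PSDs across the trial, then returns
#' `10*log10(signal/noise)` per channel, where signal = theta + alpha + beta
#' band power and noise = 30-45 Hz power plus the power within +/-1 Hz of the
#' line frequency. Apply to the raw (pre-filter) recording.
#'
#' @param rec an [eeg_recording()] at least 2 s long.
#' @param bands a [band_definition()].
#' @param nw multitaper time-bandwidth product.
#' @param ceiling_db cap applied when the noise power is zero or negligible
#'   (SNR beyond the ceiling).
#' @return Named numeric vector of SNRs (dB) per channel; attribute
#'   `"capped"` flags channels that hit the ceiling.
#' @export
channel_snr <- function(rec, bands = band_definition(), nw = 2,
                        ceiling_db = 60) {
  assert_that(inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  assert_that(ncol(rec$data) >= 2 * rec$fs, "recording must be at least 2 s")
  ep <- epoch_recording(rec, seconds = 1)
  n <- ep$epoch_len
  k <- 2 * nw - 1
  tap <- dpss_tapers(n, nw, k)
  nf <- floor(n / 2) + 1
  freq <- (0:(nf - 1)) * rec$fs / n
  line_band <- c(bands$line_hz - 1, bands$line_hz + 1)
  trap <- function(spec, b) {
    idx <- which(freq >= b[1] - 1e-9 & freq <= b[2] + 1e-9)
    if (length(idx) < 2) return(0)
    f <- freq[idx]; p <- spec[idx]
    sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
  }
  n_ch <- dim(ep$data)[1]
  snr <- numeric(n_ch)
  capped <- logical(n_ch)
  for (ch in seq_len(n_ch)) {
    xs <- t(ep$data[ch, , , drop = TRUE])
    spec <- numeric(nf)
    for (j in seq_len(k)) {
      p <- Mod(stats::mvfft(xs * tap[, j])[1:nf, , drop = FALSE])^2 / rec$fs
      p[2:(nf - 1), ] <- 2 * p[2:(nf - 1), ]
      spec <- spec + rowMeans(p) / k
    }
    sig <- trap(spec, bands$theta) + trap(spec, bands$alpha) +
      trap(spec, bands$beta)
    noise <- trap(spec, bands$noise_muscle) + trap(spec, line_band)
    db <- if (noise <= 0) Inf else 10 * log10(sig / noise)
    if (db > ceiling_db) {        # zero or negligible noise power
      snr[ch] <- ceiling_db
      capped[ch] <- TRUE
    } else snr[ch] <- db
  }
  names(snr) <- rec$channel_names
  attr(snr, "capped") <- capped
  snr
}

sqi_flag <- function(db) {
  ifelse(db <= 0, "bad", ifelse(db < 3, "marginal",
                                ifelse(db > 10, "excellent", "good")))
}

#' Cohort signal-quality report
#'
#' Per subject, each channel's SNR is averaged across the easy/optimal/hard
#' session recordings; the subject average is the arithmetic mean of the 14
#' channel values; flags follow the dB thresholds (bad <= 0, marginal < 3,
#' excellent > 10, good otherwise).
#'
#' @param recordings named list: one element per subject, each itself a list
#'   of that subject's [eeg_recording()]s across sessions.
#' @param bands a [band_definition()].
#' @param nw multitaper time-bandwidth product.
#' @return An object of class `sqi_report`: list with `table` (tibble, one
#'   row per subject: channel columns + `avg_eeg_db` + `quality_flag`) and
#'   `channel_names`.
#' @export
sqi_report <- function(recordings, bands = band_definition(), nw = 2) {
  assert_that(length(recordings) >= 1, "need at least one subject")
  rows <- lapply(names(recordings), function(sid) {
    recs <- recordings[[sid]]
    assert_that(length(recs) >= 1, "need at least one recording per subject")
    ch_names <- recs[[1]]$channel_names
    for (r in recs)
      if (!identical(r$channel_names, ch_names))
        stop_input("structural error: channel sets differ across recordings")
    snrs <- vapply(recs, channel_snr, numeric(length(ch_names)),
                   bands = bands, nw = nw)
    per_ch <- rowMeans(snrs)
    avg <- mean(per_ch)
    c(as.list(per_ch), list(avg_eeg_db = avg))
  })
  tab <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  tab <- dplyr::bind_cols(tibble::tibble(subject_id = names(recordings)), tab)
  tab$quality_flag <- sqi_flag(tab$avg_eeg_db)
  structure(list(table = tab,
                 channel_names = recordings[[1]][[1]]$channel_names),
            class = "sqi_report")
}

#' @export
print.sqi_report <- function(x, ...) {
  cat("<sqi_report>\n")
  print(as.data.frame(x$table), digits = 3)
  invisible(x)
}
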