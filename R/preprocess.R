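# EEG preprocessing: container, band-pass filtering, optional ICA-based
# muscle-artifact removal, and 1-s non-overlapping epoching.

#' EEG recording container
#'
#' @param data numeric matrix, channels x samples, uV.
#' @param channel_names channel labels (length = nrow(data)).
#' @param fs sampling rate, Hz; must exceed twice the 45 Hz analysis edge.
#' @param subject_id,session provenance keys.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channel_names = epocx_channels, fs = 128,
                          subject_id = "s01", session = "optimal") {
  data <- as.matrix(data)
  dimnames(data) <- NULL
  assert_that(is.numeric(data) && !anyNA(data), "data must be numeric with no missing samples")
  assert_that(nrow(data) == length(channel_names),
              "channel count must match channel_names")
  assert_that(fs > 2 * 45, "fs must exceed twice the 45 Hz analysis band edge")
  structure(list(data = data, channel_names = channel_names, fs = fs,
                 subject_id = subject_id, session = session),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s/%s: %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$session, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Fourth-order Butterworth band-pass (default 0.5-45 Hz) applied
#' forward-backward (`signal::filtfilt`), i.e. zero-phase with the magnitude
#' response squared. This suppresses slow drift below 0.5 Hz and both muscle
#' noise above 45 Hz and the 60 Hz powerline component, while leaving the
#' 4-30 Hz analysis bands essentially untouched.
#'
#' @param rec an [eeg_recording()].
#' @param lo,hi band edges, Hz (`hi` must be below Nyquist).
#' @param order filter order of the underlying low/high-pass prototypes.
#' @return A filtered [eeg_recording()] of the same shape.
#' @export
bandpass_filter <- function(rec, lo = 0.5, hi = 45, order = 4) {
  assert_that(inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  assert_that(lo > 0 && lo < hi, "need 0 < lo < hi")
  if (hi >= rec$fs / 2)
    stop_input("upper band edge must be below the Nyquist frequency")
  bf <- signal::butter(order, c(lo, hi) / (rec$fs / 2), type = "pass")
  out <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  eeg_recording(out, rec$channel_names, rec$fs, rec$subject_id, rec$session)
}

# Extended-infomax-style ICA (natural gradient, tanh nonlinearity with
# kurtosis-sign switching) on PCA-whitened data. Small and self-contained:
# recordings here are 14 channels at most, and the muscle test mixtures are
# rank 2.
infomax_ica <- function(x, n_comp = NULL, max_iter = 200, lr = 0.01,
                        tol = 1e-6, seed = 42) {
  n_ch <- nrow(x)
  ctr <- rowMeans(x)
  xc <- x - ctr
  cv <- tcrossprod(xc) / ncol(xc)
  ev <- eigen(cv, symmetric = TRUE)
  keep <- which(ev$values > max(ev$values) * 1e-8)
  if (length(keep) < 2)
    stop_input("ICA decomposition error: data rank < 2 (rank-deficient input)")
  n_comp <- min(n_comp %||% n_ch, length(keep))
  keep <- keep[seq_len(n_comp)]
  wh <- diag(1 / sqrt(ev$values[keep]), n_comp) %*% t(ev$vectors[, keep, drop = FALSE])
  dewh <- ev$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev$values[keep]), n_comp)
  z <- wh %*% xc

  w <- with_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(n_comp^2), n_comp)))
    q
  })
  n_s <- ncol(z)
  block <- min(512L, n_s)
  for (it in seq_len(max_iter)) {
    w_old <- w
    idx <- seq(1, n_s - block + 1, by = block)
    for (st in idx) {
      u <- w %*% z[, st:(st + block - 1), drop = FALSE]
      k <- sign(rowMeans(u^4) - 3 * rowMeans(u^2)^2)   # sub/super-Gaussian switch
      g <- tanh(u)
      grad <- (diag(n_comp) - (k * g) %*% t(u) / block - u %*% t(u) / block) %*% w
      w <- w + lr * grad
    }
    if (max(abs(w - w_old)) < tol) break
  }
  unmix <- w %*% wh              # components = unmix %*% xc
  mix <- dewh %*% solve(w)       # xc ~= mix %*% components
  list(sources = unmix %*% xc, mixing = mix, unmixing = unmix, center = ctr,
       n_comp = n_comp)
}

comp_spectral_ratio <- function(src, fs) {
  apply(src, 1, function(s) {
    n <- length(s)
    p <- Mod(fft(s - mean(s))[1:(floor(n / 2) + 1)])^2
    f <- (0:floor(n / 2)) * fs / n
    hi <- sum(p[f >= 20 & f <= 45])
    lo <- sum(p[f >= 0.5 & f < 20])
    if (lo <= 0) Inf else hi / lo
  })
}

#' Remove muscle-artifact components by ICA
#'
#' With `method = "none"` this is the identity. With `method = "ica-infomax"`
#' the recording is decomposed into at most `n_channels` independent
#' components (extended-infomax on whitened data); components whose
#' high-frequency spectral ratio -- power in 20-45 Hz over power in
#' 0.5-20 Hz -- exceeds `ratio_threshold` are flagged as muscle when
#' `auto_flag` is on, zeroed together with any `manual_exclude` indices, and
#' the channel data are reconstructed from the remaining components.
#'
#' @param rec a filtered [eeg_recording()] with at least 2 channels.
#' @param method `"none"` or `"ica-infomax"`.
#' @param auto_flag automatically flag high-ratio components (default TRUE).
#' @param manual_exclude integer component indices to remove regardless of
#'   the automatic rule.
#' @param ratio_threshold spectral ratio above which a component is flagged.
#' @return The cleaned [eeg_recording()], with an attribute `"ica_report"`:
#'   a list with `flagged`, `manual`, `removed`, and `ratio` per component.
#' @export
remove_artifact_components <- function(rec, method = c("none", "ica-infomax"),
                                       auto_flag = TRUE,
                                       manual_exclude = integer(),
                                       ratio_threshold = 1.0) {
  assert_that(inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  method <- match.arg(method)
  if (method == "none") {
    attr(rec, "ica_report") <- list(method = "none", flagged = integer(),
                                    manual = integer(), removed = integer(),
                                    ratio = numeric())
    return(rec)
  }
  assert_that(nrow(rec$data) >= 2, "ICA needs at least 2 channels")
  dec <- infomax_ica(rec$data)
  ratio <- comp_spectral_ratio(dec$sources, rec$fs)
  flagged <- if (auto_flag) which(ratio > ratio_threshold) else integer()
  manual <- intersect(as.integer(manual_exclude), seq_len(dec$n_comp))
  removed <- sort(union(flagged, manual))
  keep <- setdiff(seq_len(dec$n_comp), removed)
  clean <- dec$mixing[, keep, drop = FALSE] %*%
    dec$sources[keep, , drop = FALSE] + dec$center
  out <- eeg_recording(clean, rec$channel_names, rec$fs, rec$subject_id,
                       rec$session)
  attr(out, "ica_report") <- list(method = "ica-infomax", flagged = flagged,
                                  manual = manual, removed = removed,
                                  ratio = ratio)
  out
}

#' Segment a recording into non-overlapping epochs
#'
#' Cuts the continuous record into contiguous, non-overlapping windows of
#' `seconds` (default 1 s, i.e. 128 samples at 128 Hz). Epoch `k` covers the
#' half-open sample range `[k*len, (k+1)*len)`; a trailing remainder shorter
#' than one epoch is dropped and its sample count recorded.
#'
#' @param rec an [eeg_recording()] at least one epoch long.
#' @param seconds epoch duration, s.
#' @param label optional engagement label inherited from the session
#'   (`"high"`, `"low"`, `"neutral"`).
#' @return An object of class `eeg_epochs`: list with `data` (array
#'   channels x epochs x samples), `epoch_len`, `fs`, `channel_names`,
#'   `subject_id`, `session`, `label`, `n_dropped_samples`.
#' @export
epoch_recording <- function(rec, seconds = 1, label = NULL) {
  assert_that(inherits(rec, "eeg_recording"), "rec must be an eeg_recording")
  len <- round(seconds * rec$fs)
  n <- ncol(rec$data)
  if (n < len) stop_input("recording shorter than one epoch")
  n_ep <- n %/% len
  dropped <- n - n_ep * len
  arr <- array(0, dim = c(nrow(rec$data), n_ep, len))
  for (k in seq_len(n_ep))
    arr[, k, ] <- rec$data[, ((k - 1) * len + 1):(k * len)]
  structure(list(data = arr, epoch_len = len, epoch_seconds = seconds,
                 fs = rec$fs, channel_names = rec$channel_names,
                 subject_id = rec$subject_id, session = rec$session,
                 label = label, n_dropped_samples = dropped),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %s/%s: %d ch x %d epochs x %d samples%s\n",
              x$subject_id, x$session, dim(x$data)[1], dim(x$data)[2],
              dim(x$data)[3],
              if (!is.null(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}
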