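# Multitaper band-power estimation and the EEG engagement indices.
#
# Per 1-s epoch and channel the power spectral density is estimated with
# DPSS (Slepian) tapers, integrated over the theta (4-8 Hz), alpha (8-13 Hz)
# and beta (13-30 Hz) bands, and combined into the three classical
# engagement indices: E1 = beta/(theta+alpha), E2 = beta/alpha, E3 = 1/alpha.

#' Frequency band definition
#'
#' @param theta,alpha,beta,noise_muscle length-2 `c(lo, hi)` intervals, Hz.
#' @param line_hz powerline frequency, Hz.
#' @return An object of class `band_definition`.
#' @export
band_definition <- function(theta = c(4, 8), alpha = c(8, 13),
                            beta = c(13, 30), noise_muscle = c(30, 45),
                            line_hz = 60) {
  for (b in list(theta, alpha, beta, noise_muscle))
    assert_that(length(b) == 2 && b[1] < b[2] && b[1] > 0,
                "bands must be c(lo, hi) with 0 < lo < hi")
  assert_that(theta[2] <= alpha[1] && alpha[2] <= beta[1] &&
              beta[2] <= noise_muscle[1], "bands must not overlap")
  structure(list(theta = theta, alpha = alpha, beta = beta,
                 noise_muscle = noise_muscle, line_hz = line_hz),
            class = "band_definition")
}

# DPSS (Slepian) tapers via the symmetric tridiagonal commuting matrix,
# unit-energy normalised; symmetric tapers oriented to positive mean.
dpss_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw, k) {
  key <- sprintf("%d_%g_%d", n, nw, k)
  if (!is.null(dpss_cache[[key]])) return(dpss_cache[[key]])
  w <- nw / n
  dg <- ((n - 1 - 2 * (0:(n - 1))) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  m <- diag(dg)
  m[cbind(1:(n - 1), 2:n)] <- off
  m[cbind(2:n, 1:(n - 1))] <- off
  ev <- eigen(m, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
  }
  dpss_cache[[key]] <- tap
  tap
}

#' Multitaper power spectral density
#'
#' One-sided PSD of a single-channel epoch, averaging the eigenspectra of
#' `2*nw - 1` unit-energy DPSS tapers. The default time-bandwidth product
#' `nw = 2` gives a +/-2 Hz spectral window on a 1-s epoch, matched to the
#' 4-5 Hz widths of the theta and alpha bands. Satisfies Parseval: the
#' integral of the density over 0..fs/2 equals the signal variance (within a
#' few percent of taper edge bias).
#'
#' @param x numeric epoch (>= 8 samples).
#' @param fs sampling rate, Hz.
#' @param nw time-bandwidth product.
#' @param k number of tapers (default `2*nw - 1`).
#' @return List of class `psd_estimate` with `freq` (0..fs/2 grid, Hz),
#'   `psd` (density, uV^2/Hz), `nw`, `k`.
#' @export
multitaper_psd <- function(x, fs, nw = 2, k = 2 * nw - 1) {
  assert_that(length(x) >= 8, "epoch must have at least 8 samples")
  n <- length(x)
  tap <- dpss_tapers(n, nw, k)
  nf <- floor(n / 2) + 1
  spec <- numeric(nf)
  for (j in seq_len(k)) {
    p <- Mod(fft(tap[, j] * x)[1:nf])^2 / fs
    p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]   # one-sided fold
    spec <- spec + p / k
  }
  structure(list(freq = (0:(nf - 1)) * fs / n, psd = spec, nw = nw, k = k),
            class = "psd_estimate")
}

#' Band power from a PSD estimate
#'
#' Trapezoidal integral of the density over the band, in uV^2. Bands sharing
#' an endpoint integrate additively, so theta + alpha + beta plus the
#' residual intervals reconstruct the total power exactly.
#'
#' @param psd a [multitaper_psd()] result (or any list with `freq`, `psd`).
#' @param band length-2 `c(lo, hi)` interval, Hz.
#' @return Band power, uV^2.
#' @export
band_power <- function(psd, band) {
  assert_that(length(band) == 2 && band[1] < band[2], "band must be c(lo, hi)")
  idx <- which(psd$freq >= band[1] - 1e-9 & psd$freq <= band[2] + 1e-9)
  if (length(idx) < 2)
    stop_input("band has empty intersection with the frequency grid")
  f <- psd$freq[idx]; p <- psd$psd[idx]
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}

#' Engagement indices from band powers
#'
#' E1 = beta/(theta+alpha), E2 = beta/alpha, E3 = 1/alpha, with denominators
#' floored at `eps` so degenerate (near-silent) epochs stay finite; floored
#' epochs are flagged.
#'
#' @param p_theta,p_alpha,p_beta band powers, uV^2 (vectorised).
#' @param eps denominator floor, uV^2.
#' @return A tibble with columns `E1`, `E2`, `E3`, `floored`.
#' @examples
#' engagement_indices(1, 1, 2)  # E1 = 1, E2 = 2, E3 = 1
#' @export
engagement_indices <- function(p_theta, p_alpha, p_beta, eps = 1e-12) {
  assert_that(all(p_theta >= 0) && all(p_alpha >= 0) && all(p_beta >= 0),
              "band powers must be >= 0")
  floored <- (p_theta + p_alpha) < eps | p_alpha < eps
  tibble::tibble(
    E1 = p_beta / pmax(p_theta + p_alpha, eps),
    E2 = p_beta / pmax(p_alpha, eps),
    E3 = 1 / pmax(p_alpha, eps),
    floored = floored)
}

# Per-epoch, per-channel band powers for one eeg_epochs object, vectorised
# over epochs: for each channel and taper, one multi-column FFT.
epoch_band_powers <- function(ep, bands = band_definition(), nw = 2) {
  k <- 2 * nw - 1
  n <- ep$epoch_len
  n_ep <- dim(ep$data)[2]
  n_ch <- dim(ep$data)[1]
  tap <- dpss_tapers(n, nw, k)
  nf <- floor(n / 2) + 1
  freq <- (0:(nf - 1)) * ep$fs / n
  bp_idx <- lapply(bands[c("theta", "alpha", "beta")], function(b)
    which(freq >= b[1] - 1e-9 & freq <= b[2] + 1e-9))
  trap_w <- function(idx) {     # trapezoid weights on the band's grid points
    f <- freq[idx]
    w <- numeric(length(idx))
    d <- diff(f)
    w[-1] <- w[-1] + d / 2
    w[-length(w)] <- w[-length(w)] + d / 2
    w
  }
  wts <- lapply(bp_idx, trap_w)
  out <- vector("list", n_ch)
  for (ch in seq_len(n_ch)) {
    xs <- t(ep$data[ch, , , drop = TRUE])          # samples x epochs
    if (n_ep == 1) xs <- matrix(ep$data[ch, 1, ], ncol = 1)
    spec <- matrix(0, nf, n_ep)
    for (j in seq_len(k)) {
      ftd <- stats::mvfft(xs * tap[, j])[1:nf, , drop = FALSE]
      p <- Mod(ftd)^2 / ep$fs
      p[2:(nf - 1), ] <- 2 * p[2:(nf - 1), ]
      spec <- spec + p / k
    }
    out[[ch]] <- tibble::tibble(
      channel = ep$channel_names[ch], epoch = seq_len(n_ep),
      p_theta = as.numeric(crossprod(wts$theta, spec[bp_idx$theta, , drop = FALSE])),
      p_alpha = as.numeric(crossprod(wts$alpha, spec[bp_idx$alpha, , drop = FALSE])),
      p_beta = as.numeric(crossprod(wts$beta, spec[bp_idx$beta, , drop = FALSE])))
  }
  dplyr::bind_rows(out)
}

#' Build the engagement feature table
#'
#' Computes per-epoch, per-channel multitaper band powers and engagement
#' indices for a set of labeled epoch arrays, and assembles the classifier
#' feature table. Epochs from neutral-labeled sessions are excluded (their
#' count is reported via a message). In `"per-channel"` mode each index
#' contributes one feature per channel (42 features for the combined set on
#' a 14-channel montage); in `"channel-mean"` mode each index is averaged
#' across channels first (used by the group statistics).
#'
#' @param epoch_list list of [epoch_recording()] results, each with a
#'   non-NULL `label`.
#' @param bands a [band_definition()].
#' @param feature_set `"combined"` (all three indices), `"e1"`, `"e2"`, `"e3"`.
#' @param channel_mode `"per-channel"` or `"channel-mean"`.
#' @param nw multitaper time-bandwidth product.
#' @return A tibble of class `engagement_features`: key columns `subject_id`,
#'   `session`, `epoch`, `label`, then one numeric column per feature
#'   (`E<i>_<channel>` or `E<i>_mean`). Attributes `feature_cols`, `bands`,
#'   `nw`, `n_excluded_neutral` carry the metadata.
#' @export
build_feature_table <- function(epoch_list, bands = band_definition(),
                                feature_set = c("combined", "e1", "e2", "e3"),
                                channel_mode = c("per-channel", "channel-mean"),
                                nw = 2) {
  feature_set <- match.arg(feature_set)
  channel_mode <- match.arg(channel_mode)
  labs <- vapply(epoch_list, function(e) e$label %||% NA_character_, "")
  if (anyNA(labs))
    stop_input("labeling error: every epoch array needs a session label")
  neutral <- labs == "neutral"
  n_excl <- sum(vapply(epoch_list[neutral], function(e) dim(e$data)[2], 0))
  if (n_excl > 0)
    message(sprintf("excluding %d epochs from %d neutral session(s)",
                    n_excl, sum(neutral)))
  epoch_list <- epoch_list[!neutral]
  assert_that(length(epoch_list) > 0, "no labeled non-neutral sessions")

  long <- dplyr::bind_rows(lapply(epoch_list, function(ep) {
    bp <- epoch_band_powers(ep, bands, nw)
    ei <- engagement_indices(bp$p_theta, bp$p_alpha, bp$p_beta)
    dplyr::bind_cols(
      tibble::tibble(subject_id = ep$subject_id, session = ep$session,
                     label = ep$label),
      bp, ei[, c("E1", "E2", "E3")])
  }))

  idx_cols <- switch(feature_set, combined = c("E1", "E2", "E3"),
                     e1 = "E1", e2 = "E2", e3 = "E3")
  if (channel_mode == "channel-mean") {
    wide <- dplyr::summarise(
      dplyr::group_by(long, subject_id, session, label, epoch),
      dplyr::across(dplyr::all_of(idx_cols), mean), .groups = "drop")
    names(wide)[names(wide) %in% idx_cols] <- paste0(idx_cols, "_mean")
    feat_cols <- paste0(idx_cols, "_mean")
  } else {
    pieces <- lapply(idx_cols, function(ic) {
      w <- stats::reshape(
        as.data.frame(long[, c("subject_id", "session", "label", "epoch",
                               "channel", ic)]),
        direction = "wide", timevar = "channel",
        idvar = c("subject_id", "session", "label", "epoch"), v.names = ic)
      names(w) <- sub(paste0("^", ic, "\\."), paste0(ic, "_"), names(w))
      w
    })
    wide <- pieces[[1]]
    if (length(pieces) > 1)
      for (p in pieces[-1])
        wide <- merge(wide, p, by = c("subject_id", "session", "label", "epoch"),
                      sort = FALSE)
    feat_cols <- setdiff(names(wide), c("subject_id", "session", "label", "epoch"))
    wide <- tibble::as_tibble(wide)
  }
  wide <- wide[order(wide$subject_id, wide$session, wide$epoch), ]
  out <- structure(wide, class = c("engagement_features", class(wide)))
  attr(out, "feature_cols") <- feat_cols
  attr(out, "bands") <- bands
  attr(out, "nw") <- nw
  attr(out, "n_excluded_neutral") <- n_excl
  out
}

feature_cols <- function(features) {
  attr(features, "feature_cols") %||%
    setdiff(names(features),
            c("subject_id", "session", "label", "epoch", "age_group"))
}
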