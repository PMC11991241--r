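# Shared fixtures and independent oracles.

# Worked-example gameplay datasheet (raw per-level counts) and its published
# PI / %PI' columns.
worked_example <- function() {
  data.frame(
    level = 1:10,
    TC = c(29, 54, 76, 91, 98, 115, 115, 111, 128, 131),
    TM = c(0, 6, 10, 27, 44, 57, 89, 119, 139, 161),
    OH = c(3, 3, 8, 11, 20, 21, 31, 34, 42, 57))
}

worked_example_pi <- c(0, 0.086603, 0.150701, 0.158725, 0.115556, 0.148275,
                       0.0346, -0.068642, -0.075638, -0.1666)

worked_example_pct <- c(51.21027, 77.83074, 97.5334, 100, 86.73052, 96.7876,
                        61.8459, 30.11069, 27.9604, 0)

# Periodogram band power: independent single-taper oracle for spectral tests.
periodogram_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(fft(x)[1:(floor(n / 2) + 1)])^2 / (n * fs)
  p[2:(floor(n / 2))] <- 2 * p[2:(floor(n / 2))]
  f <- (0:floor(n / 2)) * fs / n
  sum(p[f >= lo & f <= hi]) * fs / n
}

# Classical (tie-free) Friedman statistic, written independently of the
# package implementation.
friedman_stat_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  12 / (n * k * (k + 1)) * sum(colSums(r)^2) - 3 * n * (k + 1)
}

# Exact permutation p-value for tie-free k = 3 matrices: under the null each
# row's ranks are an independent uniform permutation of (1,2,3); the column
# rank-sum distribution follows by dynamic-programming convolution over the
# 6 per-row permutations, and p = P(statistic >= observed).
friedman_exact_p <- function(m) {
  n <- nrow(m); k <- ncol(m)
  stopifnot(k == 3)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  # state: probability over (R1, R2) rank sums after i rows
  probs <- new.env(parent = emptyenv())
  assign("0_0", 1, probs)
  for (i in seq_len(n)) {
    nxt <- new.env(parent = emptyenv())
    for (key in ls(probs)) {
      rs <- as.integer(strsplit(key, "_")[[1]])
      p0 <- get(key, probs)
      for (j in 1:6) {
        nk <- sprintf("%d_%d", rs[1] + perms[j, 1], rs[2] + perms[j, 2])
        assign(nk, (if (exists(nk, nxt)) get(nk, nxt) else 0) + p0 / 6, nxt)
      }
    }
    probs <- nxt
  }
  stat_of <- function(r1, r2) {
    r3 <- 6 * n - r1 - r2
    12 / (n * k * (k + 1)) * (r1^2 + r2^2 + r3^2) - 3 * n * (k + 1)
  }
  obs <- friedman_stat_oracle(m)
  p <- 0
  for (key in ls(probs)) {
    rs <- as.integer(strsplit(key, "_")[[1]])
    if (stat_of(rs[1], rs[2]) >= obs - 1e-9) p <- p + get(key, probs)
  }
  p
}

# F1 of the always-majority classifier with "high" positive.
majority_f1 <- function(labels) {
  p_high <- mean(labels == "high")
  if (p_high >= 0.5) 2 * p_high / (p_high + 1) else 0
}

# Small synthetic cohort feature table built directly (fast path for ML
# tests): n_sub subjects x n_ep epochs per class (high epochs scaled by
# `imbalance`), feature columns carry a class separation of `sep` SDs.
fake_features <- function(n_sub = 4, n_ep = 40, n_feat = 6, sep = 3,
                          seed = 1, age_split = 1, imbalance = 1) {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_sub)) {
    for (cls in c("high", "low")) {
      mu <- if (cls == "high") sep / 2 else -sep / 2
      n_cls <- if (cls == "high") n_ep * imbalance else n_ep
      x <- matrix(rnorm(n_cls * n_feat, mean = mu), n_cls, n_feat)
      colnames(x) <- paste0("f", seq_len(n_feat))
      rows[[paste(s, cls)]] <- dplyr::bind_cols(
        tibble::tibble(subject_id = sprintf("s%02d", s),
                       session = if (cls == "high") "optimal" else "hard",
                       epoch = seq_len(n_cls), label = cls,
                       age_group = if (s <= age_split) "older" else "young"),
        tibble::as_tibble(x))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "feature_cols") <- paste0("f", seq_len(n_feat))
  out
}

# Reduced SVM/RF specs used where the full tuning grid is not itself under
# test, to keep model fitting light.
small_svm <- function() model_spec("svm", grid = list(C = c(1, 10),
                                                      gamma = "scale",
                                                      kernel = "rbf"))
small_rf <- function() model_spec("random-forest",
                                  grid = list(ntree = 100, nodesize = 2,
                                              maxnodes = NA, replace = TRUE))

fast_scheme <- function(mode = "within-subject", seed = 1)
  cv_scheme(mode, tuning_folds = 3, seed = seed)
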