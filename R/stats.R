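# Nonparametric group statistics across the three difficulty levels:
# Shapiro-Wilk normality screening, the Friedman rank test (tie-corrected)
# and Dunn-type pairwise post hoc comparisons with Bonferroni adjustment.

#' Friedman test of related samples
#'
#' Within-subject ranks (average ranks on ties), tie-corrected chi-square
#' statistic with `k - 1` degrees of freedom. Equivalent to
#' `stats::friedman.test` on tie-free data; with ties the correction factor
#' `1 - sum(t^3 - t) / (n k (k^2 - 1))` divides the classical statistic.
#'
#' @param scores numeric matrix, subjects x conditions (no missing cells);
#'   column names are used as condition labels.
#' @return An object of class `friedman_result`: `chi2`, `df`, `p`,
#'   `mean_ranks`, `n`, `k`.
#' @export
friedman_test <- function(scores) {
  scores <- as.matrix(scores)
  assert_that(is.numeric(scores) && !anyNA(scores),
              "scores must be a numeric matrix with no missing cells")
  n <- nrow(scores); k <- ncol(scores)
  assert_that(n >= 2 && k >= 2, "need >= 2 subjects and >= 2 conditions")
  if (is.null(colnames(scores))) colnames(scores) <- paste0("c", seq_len(k))
  r <- t(apply(scores, 1, rank))
  rj <- colSums(r)
  stat <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  # tie correction over within-subject tie groups
  tie_sum <- sum(apply(scores, 1, function(row) {
    t <- table(row); sum(t^3 - t)
  }))
  corr <- 1 - tie_sum / (n * k * (k^2 - 1))
  if (corr > 0) stat <- stat / corr else stat <- 0
  stat <- max(stat, 0)
  df <- k - 1
  structure(list(chi2 = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE),
                 mean_ranks = colMeans(r), n = n, k = k),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman chi-square(%d, N = %d) = %.3f, p = %.4f\n",
              x$df, x$n, x$chi2, x$p))
  cat("mean ranks:", paste(sprintf("%s = %.2f", names(x$mean_ranks),
                                   x$mean_ranks), collapse = ", "), "\n")
  invisible(x)
}

#' Dunn-type pairwise post hoc comparisons after a Friedman test
#'
#' For each condition pair, the standardised mean-rank difference
#' `z = (Ri - Rj) / sqrt(k (k + 1) / (6 n))` with a two-sided normal p-value
#' and Bonferroni adjustment over all `k (k - 1) / 2` pairs (capped at 1).
#'
#' @param result a [friedman_test()] result.
#' @return A tibble with columns `pair`, `z`, `p_raw`, `p_adjusted`.
#' @export
posthoc_pairwise <- function(result) {
  assert_that(inherits(result, "friedman_result"),
              "result must come from friedman_test()")
  k <- result$k; n <- result$n
  se <- sqrt(k * (k + 1) / (6 * n))
  m <- k * (k - 1) / 2
  conds <- names(result$mean_ranks)
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    z <- (result$mean_ranks[[i]] - result$mean_ranks[[j]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    out[[length(out) + 1]] <- tibble::tibble(
      pair = paste(conds[i], conds[j], sep = " vs "),
      z = z, p_raw = p, p_adjusted = min(1, m * p))
  }
  dplyr::bind_rows(out)
}

#' Shapiro-Wilk normality screen per condition
#'
#' Reports the decision path only: the pipeline proceeds nonparametrically
#' regardless (Likert-derived scores are not assumed normal), but the screen
#' documents which conditions would have passed.
#'
#' @param scores numeric matrix (subjects x conditions) or list of
#'   per-condition vectors, each with 3..5000 observations.
#' @return A tibble with columns `condition`, `W`, `p`.
#' @export
normality_screen <- function(scores) {
  if (is.matrix(scores) || is.data.frame(scores)) {
    m <- as.matrix(scores)
    if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
    scores <- lapply(seq_len(ncol(m)), function(j) m[, j])
    names(scores) <- colnames(m)
  }
  assert_that(is.list(scores), "scores must be a matrix or list of vectors")
  if (is.null(names(scores))) names(scores) <- paste0("c", seq_along(scores))
  for (v in scores)
    assert_that(length(v) >= 3 && length(v) <= 5000,
                "each condition needs 3..5000 observations")
  res <- lapply(scores, shapiro.test)
  tibble::tibble(condition = names(scores),
                 W = vapply(res, function(r) unname(r$statistic), 0),
                 p = vapply(res, function(r) r$p.value, 0))
}
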