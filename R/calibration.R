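# Game-difficulty calibration from in-game metrics.
#
# Players differ widely in skill, so a fixed "medium" level is meaningless;
# instead each player's ten-level play-through is scored with a weighted
# Performance Index (PI) over three in-game metrics -- rings collected (TC),
# rings missed (TM) and obstacle hits (OH) -- and the level where the
# percent-normalised PI reaches 100% becomes that player's optimal level.

#' Weight scheme for the Performance Index
#'
#' Raw importance weights for the three in-game metrics (collected, missed,
#' obstacle hits) and the corresponding adjusted (normalised) weights. Two
#' rounding modes are supported: `"paper-rounded-4dp"` uses the adjusted
#' weights rounded to four decimals with the last weight balanced so the set
#' sums to exactly 1 (5/5/2 gives 0.4167, 0.4167, 0.1666), which is what
#' reproduces the published worked example bit-for-bit; `"exact-fraction"`
#' uses the exact fractions 5/12, 5/12, 2/12, which sum to one and make the
#' index invariant to rescaling all raw weights.
#'
#' @param w_tc,w_tm,w_oh positive raw weights (defaults 5, 5, 2).
#' @param rounding_mode `"paper-rounded-4dp"` (default) or `"exact-fraction"`.
#' @return An object of class `weight_scheme` with elements `w_tc`, `w_tm`,
#'   `w_oh`, `a_tc`, `a_tm`, `a_oh`, `rounding_mode`.
#' @examples
#' weight_scheme()
#' weight_scheme(rounding_mode = "exact-fraction")
#' @export
weight_scheme <- function(w_tc = 5, w_tm = 5, w_oh = 2,
                          rounding_mode = c("paper-rounded-4dp", "exact-fraction")) {
  rounding_mode <- match.arg(rounding_mode)
  assert_that(w_tc > 0 && w_tm > 0 && w_oh > 0, "raw weights must be > 0")
  tot <- w_tc + w_tm + w_oh
  a <- c(w_tc, w_tm, w_oh) / tot
  if (rounding_mode == "paper-rounded-4dp") {
    # round to 4 decimals, balancing the last weight so the set sums to 1
    # exactly (5/5/2 -> 0.4167, 0.4167, 0.1666)
    a <- round(a, 4)
    a[3] <- round(1 - a[1] - a[2], 4)
  }
  structure(
    list(w_tc = w_tc, w_tm = w_tm, w_oh = w_oh,
         a_tc = a[1], a_tm = a[2], a_oh = a[3],
         rounding_mode = rounding_mode),
    class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat(sprintf("<weight_scheme> raw %g/%g/%g -> adjusted %.4f/%.4f/%.4f (%s)\n",
              x$w_tc, x$w_tm, x$w_oh, x$a_tc, x$a_tm, x$a_oh, x$rounding_mode))
  invisible(x)
}

#' Min-max normalisation
#'
#' Maps `x` in `[lo, hi]` onto the unit interval. A degenerate range
#' (`hi == lo`) returns 0 rather than NaN so that a single constant metric
#' does not poison the Performance Index.
#'
#' @param x value(s) to normalise.
#' @param lo,hi range minimum and maximum; default to `range(x)`.
#' @return `(x - lo) / (hi - lo)`, or 0 where `hi == lo`.
#' @examples
#' min_max_normalize(54, 29, 131)   # 0.245098
#' @export
min_max_normalize <- function(x, lo = min(x), hi = max(x)) {
  assert_that(all(x >= lo - 1e-12) && all(x <= hi + 1e-12),
              "x outside [lo, hi] in min_max_normalize()")
  if (hi == lo) return(rep(0, length(x)))
  (x - lo) / (hi - lo)
}

#' Weighted Performance Index
#'
#' Combines min-max-normalised in-game metrics into a single score: collected
#' items reward performance while misses and obstacle hits penalise it,
#' so `PI = a_tc * TC' - a_tm * TM' - a_oh * OH'`. Bounded in
#' `[-(a_tm + a_oh), a_tc]`.
#'
#' @param tc_n,tm_n,oh_n normalised metrics in `[0, 1]` (vectorised).
#' @param w a [weight_scheme()].
#' @return Numeric PI value(s).
#' @examples
#' performance_index(0.460784, 0.062112, 0.092593)  # 0.150701
#' @export
performance_index <- function(tc_n, tm_n, oh_n, w = weight_scheme()) {
  assert_that(all(tc_n >= 0 & tc_n <= 1) && all(tm_n >= 0 & tm_n <= 1) &&
              all(oh_n >= 0 & oh_n <= 1),
              "normalised metrics must lie in [0, 1]")
  w$a_tc * tc_n - w$a_tm * tm_n - w$a_oh * oh_n
}

#' Calibrate easy/optimal/hard levels from a player's metric table
#'
#' Normalises each metric across levels, computes the PI per level, rescales
#' the PI column to a 0-100 percentage (%PI'), and assigns the three session
#' levels: easy is always level 1, optimal is the level whose %PI' is 100
#' (lowest such level on ties), and hard is four levels above optimal, capped
#' at `max_level` with a warning.
#'
#' @param records data frame with columns `level`, `TC`, `TM`, `OH`
#'   (non-negative counts, one row per level).
#' @param w a [weight_scheme()].
#' @param max_level highest playable level (default 10).
#' @return An object of class `level_calibration`: a list with `table`
#'   (tibble: level, TC, TM, OH, tc_n, tm_n, oh_n, pi, pct_pi), `easy_level`,
#'   `optimal_level`, `hard_level`, `capped`, and the weight scheme used.
#' @examples
#' rec <- data.frame(level = 1:3, TC = c(10, 20, 25), TM = c(0, 5, 20),
#'                   OH = c(1, 2, 8))
#' calibrate_levels(rec)
#' @export
calibrate_levels <- function(records, w = weight_scheme(), max_level = 10L) {
  assert_that(is.data.frame(records) &&
              all(c("level", "TC", "TM", "OH") %in% names(records)),
              "records must have columns level, TC, TM, OH")
  assert_that(nrow(records) >= 2, "need at least 2 levels to calibrate")
  assert_that(!anyDuplicated(records$level), "duplicate level in records")
  assert_that(all(records$TC >= 0 & records$TM >= 0 & records$OH >= 0),
              "metric counts must be non-negative")
  records <- records[order(records$level), , drop = FALSE]
  rng <- function(x) diff(range(x))
  if (rng(records$TC) == 0 && rng(records$TM) == 0 && rng(records$OH) == 0)
    stop_input("degenerate calibration: all three metrics constant across levels")

  tc_n <- min_max_normalize(records$TC)
  tm_n <- min_max_normalize(records$TM)
  oh_n <- min_max_normalize(records$OH)
  pi <- performance_index(tc_n, tm_n, oh_n, w)
  pct_pi <- 100 * min_max_normalize(pi)

  optimal <- records$level[which(pct_pi == max(pct_pi))[1]]
  hard <- optimal + 4L
  capped <- FALSE
  if (hard > max_level) {
    warning(sprintf("hard level %d capped at max_level %d", hard, max_level),
            call. = FALSE)
    hard <- max_level
    capped <- TRUE
  }
  structure(
    list(table = tibble::tibble(level = records$level,
                                TC = records$TC, TM = records$TM, OH = records$OH,
                                tc_n = tc_n, tm_n = tm_n, oh_n = oh_n,
                                pi = pi, pct_pi = pct_pi),
         easy_level = 1L, optimal_level = as.integer(optimal),
         hard_level = as.integer(hard), capped = capped, weights = w),
    class = "level_calibration")
}

#' @export
print.level_calibration <- function(x, ...) {
  cat("<level_calibration>\n")
  print(as.data.frame(x$table), digits = 6)
  cat(sprintf("easy = %d, optimal = %d, hard = %d%s\n", x$easy_level,
              x$optimal_level, x$hard_level, if (x$capped) " (capped)" else ""))
  invisible(x)
}
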