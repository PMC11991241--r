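# Flow-state-scale scoring and engagement labeling.
#
# The 14-item flow state scale for occupational tasks is answered on a 0-7
# Likert range after each gameplay session. The rated score is the raw sum
# divided by 14 (so also 0-7); sessions at or above 4.5 points are labeled
# high engagement, below 4.5 low, with a configurable neutral band around the
# undecided midpoint 4 whose sessions are excluded from classification.

#' Construct and validate a flow-scale response
#'
#' @param items integer vector of exactly 14 item ratings, each in 0..7.
#' @param subject_id subject key (string).
#' @param session session tag, one of `"easy"`, `"optimal"`, `"hard"`.
#' @return An object of class `flow_response`.
#' @export
flow_response <- function(items, subject_id = "s1",
                          session = c("easy", "optimal", "hard")) {
  session <- match.arg(session)
  assert_that(length(items) == 14, "a flow-scale response has exactly 14 items")
  assert_that(all(items == round(items)) && all(items >= 0 & items <= 7),
              "flow-scale items must be integers in 0..7")
  structure(list(items = as.integer(items), subject_id = subject_id,
                 session = session),
            class = "flow_response")
}

#' Rated flow score
#'
#' Total raw score divided by the 14 items, giving a score in points on the
#' same 0-7 range as the individual items.
#'
#' @param r a [flow_response()].
#' @return Rated score in `[0, 7]`.
#' @examples
#' rated_score(flow_response(rep(7, 14)))  # 7
#' @export
rated_score <- function(r) {
  assert_that(inherits(r, "flow_response"), "r must be a flow_response")
  sum(r$items) / 14
}

#' Score a response and assign an engagement label
#'
#' High engagement if the rated score is >= 4.5 points, low if < 4.5 --
#' unless the score falls in the neutral band around the undecided midpoint
#' (default `[3.75, 4.25]`, i.e. 4 +/- 0.25), which yields `"neutral"`.
#' Neutral sessions are excluded from classifier labeling downstream.
#'
#' @param r a [flow_response()].
#' @param neutral_band numeric length-2 `c(lo, hi)` score interval treated as
#'   neutral, or `NULL` to disable the band.
#' @param threshold high/low cutoff in points (default 4.5, inclusive for high).
#' @return An object of class `engagement_label`: list with `rated_score`,
#'   `label` (`"high"`, `"low"` or `"neutral"`), `subject_id`, `session`.
#' @examples
#' score_and_label(flow_response(rep(5, 14)))$label   # "high"
#' score_and_label(flow_response(rep(4, 14)))$label   # "neutral"
#' @export
score_and_label <- function(r, neutral_band = c(3.75, 4.25), threshold = 4.5) {
  sc <- rated_score(r)
  label <- if (!is.null(neutral_band) && sc >= neutral_band[1] && sc <= neutral_band[2])
    "neutral"
  else if (sc >= threshold) "high" else "low"
  structure(list(rated_score = sc, label = label,
                 subject_id = r$subject_id, session = r$session),
            class = "engagement_label")
}

#' Label all sessions of a cohort and find retained subjects
#'
#' Applies [score_and_label()] to every response, then marks the subjects
#' retained for within-subject classification: a subject is retained only if,
#' after removing neutral sessions, they have at least one high and one low
#' session (a binary classifier is undefined otherwise).
#'
#' @param responses list of [flow_response()] objects.
#' @param neutral_band,threshold passed to [score_and_label()].
#' @return A tibble with columns `subject_id`, `session`, `rated_score`,
#'   `label`, `retained` (logical, subject-level).
#' @export
label_sessions <- function(responses, neutral_band = c(3.75, 4.25),
                           threshold = 4.5) {
  labs <- lapply(responses, score_and_label,
                 neutral_band = neutral_band, threshold = threshold)
  out <- tibble::tibble(
    subject_id = vapply(labs, `[[`, "", "subject_id"),
    session = vapply(labs, `[[`, "", "session"),
    rated_score = vapply(labs, `[[`, 0, "rated_score"),
    label = vapply(labs, `[[`, "", "label"))
  keep <- vapply(split(out$label, out$subject_id), function(l) {
    l <- l[l != "neutral"]
    any(l == "high") && any(l == "low")
  }, TRUE)
  out$retained <- keep[out$subject_id]
  out
}
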