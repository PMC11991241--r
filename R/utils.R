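#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft var sd rnorm runif rbinom pchisq pnorm shapiro.test
#'   predict quantile median
#' @importFrom utils head read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_input(msg)
  invisible(TRUE)
}

#' Deterministic substream seed
#'
#' Derives a reproducible child seed from a master seed and a set of string
#' keys (subject, session, generator name), so that adding one generator never
#' perturbs the random draws of another. Plain 32-bit multiplicative hash.
#'
#' @param seed master integer seed.
#' @param ... character or numeric keys identifying the substream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, ...) {
  keys <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (cc in utf8ToInt(keys)) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
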