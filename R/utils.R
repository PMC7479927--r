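#' @importFrom rlang abort warn .data %||%
#' @importFrom stats quantile rnorm rbinom rpois rnbinom runif rlnorm
#'   lm glm binomial coef vcov logLik qnorm setNames complete.cases
#' @importFrom utils head
NULL

stop_config <- function(msg) abort(msg, class = "dyadhealth_config_error")
stop_validation <- function(msg) abort(msg, class = "dyadhealth_validation_error")

#' Derive a child seed from a master seed
#'
#' Each record stream of the generator is drawn under its own seed derived
#' deterministically from the master seed, so a stream can be regenerated
#' without replaying the draws that precede it.
#'
#' @param seed master integer seed
#' @param offset small non-negative integer identifying the stream
#' @return an integer seed in `[1, 2^31 - 2]`
#' @export
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(offset))
  as.integer((abs(seed) + 77003 * (offset + 1)) %% 2147483646L + 1L)
}

as_date_scalar <- function(x, what) {
  d <- tryCatch(as.Date(x), error = function(e) NA)
  if (length(d) != 1 || is.na(d)) stop_config(paste0("`", what, "` is not a valid date"))
  d
}

check_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop_config(paste0("`", what, "` must be a probability in [0, 1]"))
  x
}
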