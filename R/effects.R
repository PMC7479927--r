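#' Group summary for effect-size computation
#'
#' A continuous outcome is summarised by n, mean and sd. A binary outcome
#' (reported as a percentage) is summarised on the 0/1 scale: mean = p and
#' sd = sqrt(p(1-p) n/(n-1)), the sample standard deviation of the
#' indicator variable.
#'
#' @param n group size (>= 2)
#' @param mean group mean (or proportion for binary outcomes)
#' @param sd group standard deviation; omit and supply `proportion` instead
#'   for a binary outcome
#' @param proportion optional proportion in `[0, 1]`
#' @return object of class `group_summary`
#' @export
group_summary <- function(n, mean = NULL, sd = NULL, proportion = NULL) {
  if (!is.null(proportion)) {
    check_prob(proportion, "proportion")
    mean <- proportion
    sd <- sqrt(proportion * (1 - proportion) * n / (n - 1))
  }
  if (is.null(mean) || is.null(sd))
    stop_config("supply either `mean` and `sd`, or `proportion`")
  if (n < 2) stop_config("group size must be at least 2")
  if (!is.finite(sd) || sd < 0) stop_config("`sd` must be finite and non-negative")
  structure(list(n = n, mean = mean, sd = sd), class = "group_summary")
}

#' Standardized mean difference (Cohen's d) with pooled SD
#'
#' d = (mean_a - mean_b) / s_p with
#' s_p = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2)), classified
#' into trivial/small/medium/large/very large at |d| boundaries
#' 0.2, 0.5, 0.8 and 1.2.
#'
#' @param a,b [group_summary()] objects
#' @return list with `d`, `category` and the pooled SD
#' @export
cohens_d <- function(a, b) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  sp <- sqrt(((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2))
  if (sp == 0) {
    if (a$mean == b$mean) {
      d <- 0
    } else {
      abort("pooled SD is zero with unequal means: effect size undefined",
            class = "dyadhealth_effect_error")
    }
  } else {
    d <- (a$mean - b$mean) / sp
  }
  list(d = d, category = classify_effect(d), pooled_sd = sp)
}

#' Effect-size category from |d|
#'
#' Left-closed bins: |d| < 0.2 trivial, [0.2, 0.5) small, [0.5, 0.8) medium,
#' [0.8, 1.2) large, >= 1.2 very large.
#'
#' @param d numeric vector of standardized mean differences
#' @return character vector of categories
#' @export
classify_effect <- function(d) {
  if (any(!is.finite(d))) stop_validation("effect size must be finite")
  cut(abs(d), breaks = c(-Inf, 0.2, 0.5, 0.8, 1.2, Inf), right = FALSE,
      labels = c("trivial", "small", "medium", "large", "very_large")) |>
    as.character()
}

# superscript shorthand used in the rendered tables
effect_superscript <- function(category) {
  c(trivial = "", small = "S", medium = "M", large = "L", very_large = "XL")[category]
}
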