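#' Covariate design shared by all four regression models
#'
#' Joins dyads to maternal outcomes and builds the analysis frame: maternal
#' age (years), lowest-income-quintile flag, premium-subsidy flag, child age
#' (years), child-female flag and the four-level child health category with
#' Neither as reference.
#'
#' @param dyads dyad tibble
#' @param outcomes maternal outcomes tibble (person_id = mother_id)
#' @return model frame tibble
#' @export
regression_frame <- function(dyads, outcomes) {
  dplyr::inner_join(dyads, outcomes, by = c(mother_id = "person_id")) |>
    dplyr::mutate(
      child_female = .data$child_sex == "F",
      child_group = factor(as.character(.data$child_group), levels = group_levels())
    )
}

#' The standard covariate set used by all four models
#' @return character vector of covariate names
#' @export
standard_covariates <- function() {
  c("mother_age", "income_quintile_lowest", "premium_subsidy",
    "child_age", "child_female", "child_group")
}

model_formula <- function(outcome, covariates = standard_covariates()) {
  stats::reformulate(covariates, response = outcome)
}

#' Linear regression for a count outcome
#'
#' Ordinary least squares of the outcome on the standard covariate set.
#'
#' @param outcome name of the outcome column (e.g. `"n_physician_visits"`)
#' @param data model frame from [regression_frame()]
#' @param covariates covariate names; defaults to [standard_covariates()]
#' @return object of class `dyad_regression`: per-term estimates and SEs,
#'   R-squared (with adjusted R-squared alongside) and n
#' @export
fit_linear <- function(outcome, data, covariates = standard_covariates()) {
  fit <- lm(model_formula(outcome, covariates), data = data)
  if (anyNA(coef(fit)))
    abort(paste0("rank-deficient design; collinear terms: ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
          class = "dyadhealth_fit_error")
  sm <- summary(fit)
  structure(list(
    outcome = outcome, model = "linear",
    terms = tibble::tibble(
      term = rownames(sm$coefficients),
      estimate = sm$coefficients[, "Estimate"],
      se = sm$coefficients[, "Std. Error"],
      p_value = sm$coefficients[, "Pr(>|t|)"]
    ),
    reference = "child_group = NEITHER",
    r2 = unname(sm$r.squared), adj_r2 = unname(sm$adj.r.squared),
    n = stats::nobs(fit), fit = fit
  ), class = "dyad_regression")
}

#' Logistic regression for a binary outcome
#'
#' Maximum-likelihood odds ratios with Wald 95% confidence intervals
#' (normal quantiles on the log-odds scale, exponentiated) and the
#' Nagelkerke pseudo R-squared.
#'
#' @inheritParams fit_linear
#' @param epsilon IRLS convergence tolerance passed to [stats::glm()]
#' @return object of class `dyad_regression` with OR columns
#' @export
fit_logistic <- function(outcome, data, covariates = standard_covariates(),
                         epsilon = 1e-10) {
  y <- data[[outcome]]
  p <- mean(y)
  if (!(p > 0 && p < 1))
    abort(paste0("outcome `", outcome, "` has prevalence ", p,
                 "; logistic model needs both classes present"),
          class = "dyadhealth_fit_error")
  saw_extreme <- FALSE
  fit <- withCallingHandlers(
    glm(model_formula(outcome, covariates), data = data, family = binomial(),
        control = stats::glm.control(epsilon = epsilon, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        saw_extreme <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    abort(paste0("logistic fit for `", outcome, "` did not converge"),
          class = "dyadhealth_fit_error")
  if (saw_extreme && any(abs(coef(fit)[-1]) > 15, na.rm = TRUE))
    abort(paste0("separation detected while fitting `", outcome,
                 "`: a covariate pattern predicts the outcome perfectly ",
                 "(divergent log-odds estimate)"),
          class = "dyadhealth_fit_error")
  sm <- summary(fit)
  est <- sm$coefficients[, "Estimate"]
  se <- sm$coefficients[, "Std. Error"]
  z <- qnorm(0.975)
  ll_full <- as.numeric(logLik(fit))
  ll_null <- as.numeric(logLik(stats::update(fit, . ~ 1)))
  structure(list(
    outcome = outcome, model = "logistic",
    terms = tibble::tibble(
      term = rownames(sm$coefficients),
      estimate = est, se = se,
      or = exp(est), ci_lower = exp(est - z * se), ci_upper = exp(est + z * se),
      p_value = sm$coefficients[, "Pr(>|z|)"]
    ),
    reference = "child_group = NEITHER",
    r2 = nagelkerke_r2(ll_null, ll_full, stats::nobs(fit)),
    loglik_null = ll_null, loglik_full = ll_full,
    n = stats::nobs(fit), fit = fit
  ), class = "dyad_regression")
}

#' Nagelkerke pseudo R-squared
#'
#' The Cox-Snell R-squared, 1 - exp(2 (ll0 - ll1)/n), rescaled by its
#' maximum attainable value 1 - exp(2 ll0 / n) so the statistic reaches 1
#' at a perfect fit.
#'
#' @param loglik_null,loglik_full log-likelihoods of the intercept-only and
#'   full models (`loglik_full >= loglik_null`)
#' @param n number of observations
#' @return numeric in `[0, 1]`
#' @export
nagelkerke_r2 <- function(loglik_null, loglik_full, n) {
  if (n < 1) stop_config("`n` must be at least 1")
  if (loglik_full < loglik_null - 1e-8)
    stop_validation("`loglik_full` must be at least `loglik_null`")
  r2_cs <- 1 - exp(2 * (loglik_null - loglik_full) / n)
  denom <- 1 - exp(2 * loglik_null / n)
  if (denom <= 0) return(0)
  min(max(r2_cs / denom, 0), 1)
}

#' @export
print.dyad_regression <- function(x, ...) {
  cat("<dyad_regression> ", x$model, " model for ", x$outcome,
      "  (n = ", x$n, ")\n", sep = "")
  print(x$terms, n = Inf)
  lab <- if (x$model == "linear") "R-squared" else "Nagelkerke R-squared"
  cat(sprintf("%s: %.4f\n", lab, x$r2))
  invisible(x)
}

#' Fit the four standard maternal-outcome models
#'
#' Linear regression for the maternal physician-visit count; logistic
#' regression for any chronic condition, mood or anxiety disorder, and
#' hospitalization.
#'
#' Rare outcomes in small cohorts can leave a child-group cell without any
#' events, in which case the maximum-likelihood odds ratio diverges
#' (quasi-separation). Such a model is skipped with a warning and recorded
#' as a `failed_fit` rather than aborting the whole analysis.
#'
#' @param dyads dyad tibble
#' @param outcomes maternal outcomes tibble
#' @return named list of `dyad_regression` (or `failed_fit`) objects
#' @export
fit_maternal_models <- function(dyads, outcomes) {
  frame <- regression_frame(dyads, outcomes)
  try_fit <- function(nm, expr) {
    tryCatch(expr, dyadhealth_fit_error = function(e) {
      warn(paste0("model for `", nm, "` could not be fit and was skipped: ",
                  conditionMessage(e)))
      structure(list(outcome = nm, error = conditionMessage(e)),
                class = "failed_fit")
    })
  }
  list(
    physician_visits = try_fit("n_physician_visits",
                               fit_linear("n_physician_visits", frame)),
    any_chronic = try_fit("any_chronic", fit_logistic("any_chronic", frame)),
    mood_anxiety = try_fit("mood_anxiety", fit_logistic("mood_anxiety", frame)),
    hospitalization = try_fit("any_hospitalization",
                              fit_logistic("any_hospitalization", frame))
  )
}
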