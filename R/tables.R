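child_outcome_vars <- function() {
  list(continuous = c("n_physician_visits", "n_lab_visits", "n_xray_visits",
                      "n_distinct_specialists", "n_rx_days", "n_prescriptions",
                      "days_hospitalized"),
       binary = character())
}

mother_outcome_vars <- function() {
  list(continuous = c("n_physician_visits", "n_lab_visits", "n_xray_visits",
                      "n_distinct_specialists", "days_hospitalized",
                      "n_rx_days", "n_prescriptions", "n_distinct_atc3"),
       binary = c("any_hospitalization", "received_pain_med",
                  "received_insomnia_med", "mood_anxiety", "any_chronic"))
}

#' Outcome comparison table across the three child groupings
#'
#' For each outcome and each grouping (High Service Use yes/no, Diagnosis
#' yes/no, Both/Neither) reports group summaries, the pooled-SD Cohen's d
#' and its category. Binary outcomes are compared as standardized mean
#' differences of the 0/1 indicator.
#'
#' @param dyads dyad tibble carrying `child_group`
#' @param outcomes person-outcomes tibble
#' @param person_col dyad column naming the person the outcomes belong to
#'   (`"mother_id"` or `"child_id"`)
#' @param vars list with `continuous` and `binary` outcome names
#' @return long tibble: one row per outcome x grouping
#' @export
outcome_comparison_table <- function(dyads, outcomes, person_col = "mother_id",
                                     vars = mother_outcome_vars()) {
  missing_cols <- setdiff(c(vars$continuous, vars$binary), names(outcomes))
  if (length(missing_cols))
    stop_validation(paste0("outcome columns missing: ",
                           paste(missing_cols, collapse = ", ")))
  df <- dplyr::inner_join(
    dplyr::select(dyads, person_id = dplyr::all_of(person_col), "child_group"),
    outcomes, by = "person_id")
  cols <- grouping_columns(df)
  pairs <- list(hsu = c("hsu_yes", "hsu_no"), dx = c("dx_yes", "dx_no"),
                both = c("both", "neither"))
  rows <- list()
  for (v in c(vars$continuous, vars$binary)) {
    binary <- v %in% vars$binary
    for (p in names(pairs)) {
      iy <- cols[[pairs[[p]][1]]]; ino <- cols[[pairs[[p]][2]]]
      xy <- df[[v]][iy]; xn <- df[[v]][ino]
      sy <- summarize_group(xy, binary); sn <- summarize_group(xn, binary)
      es <- if (length(xy) >= 2 && length(xn) >= 2) {
        gy <- if (binary) group_summary(length(xy), proportion = mean(xy))
              else group_summary(length(xy), mean(xy), stats::sd(xy))
        gn <- if (binary) group_summary(length(xn), proportion = mean(xn))
              else group_summary(length(xn), mean(xn), stats::sd(xn))
        tryCatch(cohens_d(gy, gn), dyadhealth_effect_error = function(e) NULL)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        outcome = v, grouping = p, type = if (binary) "binary" else "continuous",
        n_yes = length(xy), mean_yes = sy$mean, sd_yes = sy$sd,
        n_no = length(xn), mean_no = sn$mean, sd_no = sn$sd,
        d = if (is.null(es)) NA_real_ else es$d,
        category = if (is.null(es)) NA_character_ else es$category,
        superscript = if (is.null(es)) NA_character_
                      else unname(effect_superscript(es$category))
      )
    }
  }
  dplyr::bind_rows(rows)
}

summarize_group <- function(x, binary) {
  if (!length(x)) return(list(mean = NA_real_, sd = NA_real_))
  list(mean = mean(x),
       sd = if (binary) NA_real_ else if (length(x) > 1) stats::sd(x) else NA_real_)
}

#' Tidy regression table for the four maternal models
#'
#' @param fits named list from [fit_maternal_models()]
#' @return long tibble with per-term estimates (beta and SE for the linear
#'   model; OR and 95% CI for the logistic models) and the per-model
#'   R-squared (adjusted R-squared alongside for the linear model,
#'   Nagelkerke pseudo R-squared for the logistic ones)
#' @export
regression_table <- function(fits) {
  purrr::imap_dfr(fits, function(f, nm) {
    if (inherits(f, "failed_fit"))
      return(tibble::tibble(outcome = nm, model = "unfit", term = NA_character_,
                            estimate = NA_real_, se = NA_real_, or = NA_real_,
                            ci_lower = NA_real_, ci_upper = NA_real_,
                            p_value = NA_real_, r2 = NA_real_, n = NA_integer_))
    tt <- f$terms
    tibble::tibble(
      outcome = nm, model = f$model, term = tt$term,
      estimate = tt$estimate, se = tt$se,
      or = if (f$model == "logistic") tt$or else NA_real_,
      ci_lower = if (f$model == "logistic") tt$ci_lower else NA_real_,
      ci_upper = if (f$model == "logistic") tt$ci_upper else NA_real_,
      p_value = tt$p_value, r2 = f$r2, n = f$n
    )
  })
}

#' Render the four standard analysis tables
#'
#' Produces machine-readable analogues of the report's tables: cohort
#' characteristics, child-outcome validation, maternal outcomes (all with
#' effect-size categories), and the regression results.
#'
#' @param dyads dyad tibble
#' @param child_outcomes,mother_outcomes person-outcomes tibbles
#' @param fits named list from [fit_maternal_models()]
#' @return named list `table1` .. `table4`
#' @export
render_tables <- function(dyads, child_outcomes, mother_outcomes, fits) {
  if (!nrow(dyads)) stop_validation("cannot render tables for an empty cohort")
  list(
    table1 = cohort_characteristics(dyads),
    table2 = outcome_comparison_table(dyads, child_outcomes, "child_id",
                                      child_outcome_vars()),
    table3 = outcome_comparison_table(dyads, mother_outcomes, "mother_id",
                                      mother_outcome_vars()),
    table4 = regression_table(fits)
  )
}

#' Write rendered tables as CSV plus a formatted text report
#'
#' @param tables list from [render_tables()]
#' @param directory output directory
#' @return file paths, invisibly
#' @export
write_report <- function(tables, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(directory, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], p)
    paths <- c(paths, p)
  }
  txt <- file.path(directory, "report.txt")
  lines <- c("Dyad analysis report", strrep("=", 60))
  t3 <- tables$table3
  lines <- c(lines, "", "Maternal outcomes (mean or proportion, yes vs no, d [category]):")
  for (i in seq_len(nrow(t3))) {
    lines <- c(lines, sprintf(
      "  %-24s %-5s %8.3f vs %8.3f  d=%6.3f %s",
      t3$outcome[i], t3$grouping[i], t3$mean_yes[i], t3$mean_no[i],
      t3$d[i], t3$superscript[i] %||% ""))
  }
  t4 <- tables$table4
  lines <- c(lines, "", "Regression models:")
  for (o in unique(t4$outcome)) {
    sub <- t4[t4$outcome == o, ]
    lines <- c(lines, sprintf("  %s (%s), R2 = %.4f", o, sub$model[1], sub$r2[1]))
    for (i in seq_len(nrow(sub))) {
      lines <- c(lines, if (sub$model[1] == "logistic") {
        sprintf("    %-28s OR %6.3f (%5.3f-%5.3f)", sub$term[i], sub$or[i],
                sub$ci_lower[i], sub$ci_upper[i])
      } else {
        sprintf("    %-28s b %7.3f (%5.3f)", sub$term[i], sub$estimate[i], sub$se[i])
      })
    }
  }
  writeLines(lines, txt)
  invisible(c(paths, txt))
}
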