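toy_claims <- function() {
  tibble::tibble(
    person_id = "P1",
    service_date = as.Date(c("2006-01-10", "2006-02-11", "2006-03-12",
                             "2006-04-13", "2006-05-14", "2006-06-15",
                             "2005-07-01")),
    service_class = c("visit", "visit", "visit", "visit", "visit", "lab", "visit"),
    specialty_code = c("GP", "GP", "DERM", "OBGYN", "GP", "LAB", "GP"),
    icd9_code = c("786", "724", "692", "650", "780", "786", "786"),
    pregnancy_related = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  )
}

test_that("visit counts apply class, year and maternal pregnancy exclusions", {
  cl <- toy_claims()
  # 5 in-year visit claims, one pregnancy-flagged: maternal mode counts 4
  expect_identical(count_visits(cl, "visit", 2006, exclude_pregnancy = TRUE), 4L)
  expect_identical(count_visits(cl, "visit", 2006, exclude_pregnancy = FALSE), 5L)
  expect_identical(count_visits(cl, "lab", 2006), 1L)
  expect_identical(count_visits(cl[0, ], "visit", 2006), 0L)
  expect_error(count_visits(cl, "surgery", 2006),
               class = "dyadhealth_validation_error")
})

test_that("visit counting matches a naive filter-then-count oracle", {
  set.seed(7)
  cl <- tibble::tibble(
    person_id = "P1",
    service_date = as.Date("2006-01-01") + sample(0:400, 50, replace = TRUE),
    service_class = sample(c("visit", "lab", "xray"), 50, replace = TRUE),
    specialty_code = sample(c("GP", "INT"), 50, replace = TRUE),
    icd9_code = sample(c("786", "V22", "650"), 50, replace = TRUE),
    pregnancy_related = FALSE)
  for (sc in c("visit", "lab", "xray")) {
    oracle <- sum(cl$service_class == sc &
                    format(cl$service_date, "%Y") == "2006")
    expect_identical(count_visits(cl, sc, 2006), oracle)
  }
  oracle_m <- sum(cl$service_class == "visit" &
                    format(cl$service_date, "%Y") == "2006" &
                    !cl$icd9_code %in% c("V22", "650"))
  expect_identical(count_visits(cl, "visit", 2006, exclude_pregnancy = TRUE),
                   oracle_m)
})

test_that("distinct-specialist count is order-invariant", {
  cl <- toy_claims()
  expect_identical(count_distinct_specialists(cl, 2006), 3L)  # GP, DERM, OBGYN
  expect_identical(count_distinct_specialists(cl, 2006, exclude_pregnancy = TRUE), 2L)
  expect_identical(count_distinct_specialists(cl[0, ], 2006), 0L)
  set.seed(3)
  expect_identical(count_distinct_specialists(cl[sample(nrow(cl)), ], 2006), 3L)
})

test_that("prescription summaries aggregate at ATC level 3", {
  d <- tibble::tibble(
    person_id = "P1",
    fill_date = as.Date(c("2006-03-01", "2006-06-01")),
    days_supplied = c(30L, 30L), din = c("1", "2"),
    atc_code = c("N02BE01", "N02BA01"), is_birth_control = FALSE)
  s <- rx_summaries(d, 2006)
  expect_identical(s$n_distinct_atc3, 1L)    # both are N02B
  expect_identical(s$n_prescriptions, 2L)
  expect_identical(s$n_rx_days, 60L)
  expect_true(s$received_pain_med)
  d2 <- d; d2$atc_code <- c("N02BE01", "A10BA02")
  expect_identical(rx_summaries(d2, 2006)$n_distinct_atc3, 2L)
  bad <- d; bad$atc_code[1] <- "N2"
  expect_error(rx_summaries(bad, 2006), class = "dyadhealth_validation_error")
})

test_that("ATC summaries match a set-of-prefixes oracle on random fills", {
  set.seed(41)
  form <- c("N02BE01", "N02BA01", "M01AE01", "N05CF01", "A10BA02", "J01CA04",
            "G03AA07")
  d <- tibble::tibble(
    person_id = "P1",
    fill_date = as.Date("2005-06-01") + sample(0:900, 100, replace = TRUE),
    days_supplied = sample(1:60, 100, replace = TRUE),
    din = "x", atc_code = sample(form, 100, replace = TRUE),
    is_birth_control = FALSE)
  d$is_birth_control <- d$atc_code == "G03AA07"
  s <- rx_summaries(d, 2006, exclude_birth_control = TRUE)
  keep <- !d$is_birth_control & format(d$fill_date, "%Y") == "2006"
  expect_identical(s$n_prescriptions, sum(keep))
  expect_identical(s$n_distinct_atc3,
                   length(unique(substr(d$atc_code[keep], 1, 4))))
  expect_identical(s$received_pain_med,
                   any(substr(d$atc_code[keep], 1, 3) == "N02" |
                         substr(d$atc_code[keep], 1, 4) == "M01A"))
  expect_identical(s$received_insomnia_med,
                   any(substr(d$atc_code[keep], 1, 4) == "N05C"))
})

test_that("hospital days are nights clipped to the year", {
  h <- function(a, d, birth = FALSE)
    tibble::tibble(person_id = "P1", admit_date = as.Date(a),
                   discharge_date = as.Date(d), icd_codes = "786",
                   birth_related = birth)
  s <- hospitalization_summary(h("2006-02-01", "2006-02-04"), 2006)
  expect_identical(s$days_hospitalized, 3L)
  expect_true(s$any_hospitalization)
  # a stay spanning the year boundary contributes only its 2006 nights
  s2 <- hospitalization_summary(h("2005-12-30", "2006-01-02"), 2006)
  expect_identical(s2$days_hospitalized, 1L)
  # day-enumeration cross-check for the boundary stay
  nights <- seq(as.Date("2005-12-30"), as.Date("2006-01-01"), by = "day")
  expect_identical(s2$days_hospitalized,
                   sum(format(nights, "%Y") == "2006") |> as.integer())
  # same-day stay: flag without days
  s3 <- hospitalization_summary(h("2006-05-01", "2006-05-01"), 2006)
  expect_true(s3$any_hospitalization)
  expect_identical(s3$days_hospitalized, 0L)
  # birth stays excluded entirely
  s4 <- hospitalization_summary(h("2006-03-01", "2006-03-05", birth = TRUE),
                                2006, exclude_birth = TRUE)
  expect_false(s4$any_hospitalization)
  expect_identical(s4$days_hospitalized, 0L)
  expect_error(hospitalization_summary(h("2006-03-05", "2006-03-01"), 2006),
               class = "dyadhealth_validation_error")
})

test_that("condition flags match the prefix lists and any_chronic is their OR", {
  f <- condition_flags(c("3000", "786"), default_condition_codesets())
  expect_true(f$mood_anxiety)
  expect_true(f$any_chronic)
  f2 <- condition_flags(c("786", "724"), default_condition_codesets())
  expect_false(any(unlist(f2)))
  expect_error(condition_flags("786", list(mood_anxiety = character())),
               class = "dyadhealth_config_error")
})

test_that("the batch outcome engine agrees with the per-person operations", {
  b <- shared_bundle()
  cfg <- outcome_config(year = 2006)
  moms <- b$truth$person_id[b$truth$role == "mother"]
  out <- compute_outcomes(moms, b$claims, b$dispensings, b$hospital, cfg, "mother")
  expect_identical(nrow(out), length(moms))
  set.seed(10)
  for (p in sample(moms, 30)) {
    cl <- b$claims[b$claims$person_id == p, ]
    dd <- b$dispensings[b$dispensings$person_id == p, ]
    hh <- b$hospital[b$hospital$person_id == p, ]
    row <- out[out$person_id == p, ]
    expect_identical(row$n_physician_visits,
                     count_visits(cl, "visit", 2006, exclude_pregnancy = TRUE,
                                  cfg$pregnancy_exclusion_codes))
    expect_identical(row$n_lab_visits, count_visits(cl, "lab", 2006))
    expect_identical(row$n_distinct_specialists,
                     count_distinct_specialists(cl, 2006, TRUE,
                                                cfg$pregnancy_exclusion_codes))
    rs <- rx_summaries(dd, 2006, TRUE, cfg$pain_atc_prefixes,
                       cfg$insomnia_atc_prefixes)
    expect_identical(row$n_rx_days, rs$n_rx_days)
    expect_identical(row$n_prescriptions, rs$n_prescriptions)
    expect_identical(row$n_distinct_atc3, rs$n_distinct_atc3)
    expect_identical(row$received_pain_med, rs$received_pain_med)
    hs <- hospitalization_summary(hh, 2006, exclude_birth = TRUE)
    expect_identical(row$any_hospitalization, hs$any_hospitalization)
    expect_identical(row$days_hospitalized, hs$days_hospitalized)
    codes <- c(cl$icd9_code, unlist(strsplit(hh$icd_codes[
      as.integer(format(hh$admit_date, "%Y")) <= 2006 &
        as.integer(format(hh$discharge_date, "%Y")) >= 2006 &
        !hh$birth_related], ";")))
    cf <- condition_flags(codes, cfg$chronic_condition_codesets)
    expect_identical(row$mood_anxiety, cf$mood_anxiety)
    expect_identical(row$any_chronic, cf$any_chronic)
  }
})

test_that("outcome construction respects hard bounds and identities", {
  b <- shared_bundle()
  out <- compute_outcomes(b$truth$person_id[b$truth$role == "mother"],
                          b$claims, b$dispensings, b$hospital,
                          outcome_config(year = 2006), "mother")
  expect_true(all(out$n_rx_days <= 365))
  expect_true(all(out$n_distinct_atc3 <= out$n_prescriptions))
  cond_cols <- grep("^cond_", names(out), value = TRUE)
  expect_identical(out$any_chronic,
                   Reduce(`|`, lapply(cond_cols, function(cc) out[[cc]])))
  num <- c("n_physician_visits", "n_lab_visits", "n_xray_visits",
           "n_distinct_specialists", "n_rx_days", "n_prescriptions",
           "n_distinct_atc3", "days_hospitalized")
  for (v in num) expect_true(all(out[[v]] >= 0))
})
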