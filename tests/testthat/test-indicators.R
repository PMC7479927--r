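test_that("covered_days counts the union of dispensing intervals once", {
  expect_identical(covered_days("2005-03-01", 30, "2005-01-01", "2005-12-31"), 30L)
  # overlapping fills: union, not sum
  expect_identical(
    covered_days(c("2005-03-01", "2005-03-15"), c(30, 30),
                 "2005-01-01", "2005-12-31"), 44L)
  expect_identical(covered_days(as.Date(character()), integer(),
                                "2005-01-01", "2005-12-31"), 0L)
  # clipping at the window edges
  expect_identical(covered_days("2004-12-25", 10, "2005-01-01", "2005-12-31"), 3L)
  expect_error(covered_days("2005-01-01", 0, "2005-01-01", "2005-12-31"),
               class = "dyadhealth_validation_error")
})

test_that("interval engine matches the day-enumeration oracle on random fills", {
  set.seed(4821)
  for (rep in 1:150) {
    d <- random_dispensing_set()
    expect_identical(
      covered_days(d$fill_dates, d$days_supplied, "2005-01-01", "2007-12-31"),
      as.integer(oracle_covered_days(d$fill_dates, d$days_supplied,
                                     "2005-01-01", "2007-12-31")))
    expect_identical(
      max_window_coverage(d$fill_dates, d$days_supplied,
                          "2005-01-01", "2007-12-31", 365L),
      as.integer(oracle_max_window(d$fill_dates, d$days_supplied,
                                   "2005-01-01", "2007-12-31", 365L)))
  }
})

test_that("max_window_coverage finds a 274-day spell anywhere in the span", {
  # continuous coverage of exactly 274 days meets the nine-month threshold
  expect_identical(
    max_window_coverage("2006-05-15", 274, "2005-01-01", "2007-12-31"), 274L)
  expect_identical(
    max_window_coverage(as.Date(character()), integer(),
                        "2005-01-01", "2007-12-31"), 0L)
  expect_error(
    max_window_coverage("2005-02-01", 30, "2005-01-01", "2005-06-30", 365L),
    class = "dyadhealth_config_error")
})

test_that("adding a dispensing never decreases the window maximum", {
  set.seed(911)
  for (rep in 1:40) {
    d <- random_dispensing_set(8)
    base <- max_window_coverage(d$fill_dates, d$days_supplied,
                                "2005-01-01", "2007-12-31")
    extra <- random_dispensing_set(1)
    if (!length(extra$fill_dates)) next
    grown <- max_window_coverage(c(d$fill_dates, extra$fill_dates),
                                 c(d$days_supplied, extra$days_supplied),
                                 "2005-01-01", "2007-12-31")
    expect_gte(grown, base)
  }
})

test_that("batch window coverage agrees with the scalar engine", {
  set.seed(2718)
  disp <- purrr::map_dfr(1:25, function(i) {
    d <- random_dispensing_set(6)
    if (!length(d$fill_dates)) return(NULL)
    tibble::tibble(person_id = sprintf("P%02d", i), fill_date = d$fill_dates,
                   days_supplied = d$days_supplied)
  })
  batch <- max_window_coverage_by_person(disp, "2005-01-01", "2007-12-31")
  for (p in unique(disp$person_id)) {
    one <- disp[disp$person_id == p, ]
    expect_identical(batch$max_covered_days[batch$person_id == p],
                     max_window_coverage(one$fill_date, one$days_supplied,
                                         "2005-01-01", "2007-12-31"))
  }
})

test_that("visit cut-offs use the nearest-rank percentile, inclusive at the cut", {
  counts <- sample(1:100)                       # a permutation, all distinct
  cuts <- visit_cutoffs(counts, rep(8L, 100), 0.95)
  expect_identical(cuts$cutoff, 95L)
  expect_identical(sum(counts >= cuts$cutoff), 6L)

  # degenerate tie case: everyone at the cut-off
  cuts2 <- visit_cutoffs(rep(3L, 50), rep(7L, 50), 0.95)
  expect_identical(cuts2$cutoff, 3L)
  expect_true(all(rep(3L, 50) >= cuts2$cutoff))

  set.seed(55)
  for (rep in 1:30) {
    x <- rnbinom(sample(50:400, 1), mu = 3, size = 0.8)
    cc <- visit_cutoffs(x, rep(6L, length(x)), 0.95)
    expect_identical(cc$cutoff, as.integer(oracle_nearest_rank(x, 0.95)))
    frac <- mean(x >= cc$cutoff)
    expect_gte(frac, 1 - 0.95)
  }
  expect_error(visit_cutoffs(integer(), integer()),
               class = "dyadhealth_config_error")
})

test_that("the High Service Use flag is the OR of its two components", {
  tt <- expand.grid(med = c(FALSE, TRUE), vis = c(FALSE, TRUE))
  expect_identical(flag_high_service_use(tt$med, tt$vis), tt$med | tt$vis)
  expect_error(flag_high_service_use(1, TRUE),
               class = "dyadhealth_validation_error")
})

test_that("group assignment is a bijection from the flag pairs", {
  tt <- expand.grid(hsu = c(FALSE, TRUE), dx = c(FALSE, TRUE))
  g <- assign_group(tt$hsu, tt$dx)
  expect_identical(as.character(g),
                   c("NEITHER", "HSU_ONLY", "DIAGNOSIS_ONLY", "BOTH"))
  expect_identical(severity_rank(g), c(0L, 2L, 1L, 3L))
  expect_identical(length(unique(g)), 4L)
})

test_that("Diagnosis flag depends on the major/chronic ADG mapping", {
  cfg <- indicator_config()
  expect_true(flag_diagnosis("493", cfg))            # chronic ADG
  expect_true(flag_diagnosis(c("460", "250.1"), cfg))  # dotted code still maps
  expect_false(flag_diagnosis(c("460", "786"), cfg))   # minor ADGs only
  expect_false(flag_diagnosis(character(), cfg))
  expect_warning(flag_diagnosis("999", cfg), "not in adg_map")
  cfg_err <- indicator_config(unmapped_policy = "error")
  expect_error(flag_diagnosis("999", cfg_err),
               class = "dyadhealth_validation_error")
})

test_that("raising the medication threshold never raises HSU prevalence", {
  b <- shared_bundle()
  prev <- vapply(c(180L, 274L, 320L), function(th) {
    cfg <- indicator_config(med_days_threshold = th)
    g <- classify_children(b$registry, b$claims, b$dispensings, b$hospital,
                           cfg, 2006)
    mean(g$high_service_use)
  }, numeric(1))
  expect_true(all(diff(prev) <= 0))
})

test_that("classification is consistent between flags and groups", {
  b <- shared_bundle()
  g <- classify_children(b$registry, b$claims, b$dispensings, b$hospital,
                         indicator_config(), 2006)
  expect_identical(g$high_service_use, g$high_medication | g$high_visits)
  expect_identical(as.character(g$group),
                   as.character(assign_group(g$high_service_use,
                                             g$has_major_chronic_dx)))
  expect_true(all(g$age >= 6 & g$age <= 10))
})
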