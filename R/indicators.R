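#' Days of medication coverage within a date range
#'
#' A day of medicine use is any calendar day covered by at least one
#' dispensing interval `[fill_date, fill_date + days_supplied - 1]`; a day
#' covered by several concurrent drugs counts once. Returns the number of
#' such days falling inside `[start, end]`.
#'
#' @param fill_dates vector of fill dates
#' @param days_supplied positive integer vector, same length
#' @param start,end closed date range to count within
#' @return integer count of covered days
#' @export
covered_days <- function(fill_dates, days_supplied, start, end) {
  start <- as_date_scalar(start, "start"); end <- as_date_scalar(end, "end")
  if (start > end) stop_config("`start` must not be after `end`")
  if (!length(fill_dates)) return(0L)
  iv <- clip_intervals(as.integer(as.Date(fill_dates)),
                       as.integer(days_supplied),
                       as.integer(start), as.integer(end))
  if (!nrow(iv)) return(0L)
  m <- merge_intervals(iv$s, iv$e)
  sum(m$e - m$s + 1L)
}

# clip raw dispensing intervals to [lo, hi]; drop empties
clip_intervals <- function(fill_int, days, lo, hi) {
  if (any(is.na(days)) || any(days < 1)) stop_validation("`days_supplied` must be >= 1")
  s <- pmax(fill_int, lo)
  e <- pmin(fill_int + days - 1L, hi)
  keep <- s <= e
  data.frame(s = s[keep], e = e[keep])
}

# union of closed integer intervals, returned sorted and disjoint
merge_intervals <- function(s, e) {
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  emax <- cummax(e)
  new_run <- c(TRUE, s[-1] > emax[-length(emax)] + 1L)
  grp <- cumsum(new_run)
  data.frame(s = s[new_run], e = unname(as.vector(tapply(emax, grp, max))))
}

#' Maximum medication coverage over all sliding windows
#'
#' Scans every window of `window_len` days whose start lies in
#' `[obs_start, obs_end - window_len + 1]` and returns the largest number of
#' covered days in any one window. Because coverage is piecewise linear in
#' the window start, only starts aligned with merged-interval endpoints need
#' inspection; a brute-force day-enumeration oracle backs this in the tests.
#'
#' @inheritParams covered_days
#' @param obs_start,obs_end observation span the windows must fit inside
#' @param window_len window length in days (default 365)
#' @return integer, the maximum covered days in any single window
#' @export
max_window_coverage <- function(fill_dates, days_supplied,
                                obs_start, obs_end, window_len = 365L) {
  obs_start <- as_date_scalar(obs_start, "obs_start")
  obs_end <- as_date_scalar(obs_end, "obs_end")
  window_len <- as.integer(window_len)
  lo <- as.integer(obs_start); hi <- as.integer(obs_end)
  if (hi - lo + 1L < window_len)
    stop_config("observation span is shorter than `window_len`")
  if (!length(fill_dates)) return(0L)
  iv <- clip_intervals(as.integer(as.Date(fill_dates)),
                       as.integer(days_supplied), lo, hi)
  if (!nrow(iv)) return(0L)
  m <- merge_intervals(iv$s, iv$e)
  max_window_merged(m$s, m$e, lo, hi, window_len)
}

# core sweep on merged intervals; s/e/lo/hi are integer days
max_window_merged <- function(ms, me, lo, hi, window_len) {
  last_start <- hi - window_len + 1L
  cand <- unique(pmin(pmax(c(lo, ms, me - window_len + 1L), lo), last_start))
  we <- cand + window_len - 1L
  cov <- vapply(seq_along(cand), function(i) {
    sum(pmax(0L, pmin(me, we[i]) - pmax(ms, cand[i]) + 1L))
  }, integer(1))
  as.integer(max(cov))
}

#' Per-person maximum window coverage
#'
#' Batch version of [max_window_coverage()] over a dispensing table with a
#' `person_id` column. Persons absent from `dispensings` are absent from the
#' result (their coverage is 0).
#'
#' @param dispensings tibble with `person_id`, `fill_date`, `days_supplied`
#' @inheritParams max_window_coverage
#' @return tibble with `person_id` and `max_covered_days`
#' @export
max_window_coverage_by_person <- function(dispensings, obs_start, obs_end,
                                          window_len = 365L) {
  obs_start <- as_date_scalar(obs_start, "obs_start")
  obs_end <- as_date_scalar(obs_end, "obs_end")
  window_len <- as.integer(window_len)
  lo <- as.integer(obs_start); hi <- as.integer(obs_end)
  if (hi - lo + 1L < window_len)
    stop_config("observation span is shorter than `window_len`")
  if (!nrow(dispensings))
    return(tibble::tibble(person_id = character(), max_covered_days = integer()))
  fill_int <- as.integer(as.Date(dispensings$fill_date))
  days <- as.integer(dispensings$days_supplied)
  if (any(is.na(days)) || any(days < 1)) stop_validation("`days_supplied` must be >= 1")
  s <- pmax(fill_int, lo)
  e <- pmin(fill_int + days - 1L, hi)
  keep <- s <= e
  iv <- data.frame(s = s[keep], e = e[keep])
  pid <- dispensings$person_id[keep]
  if (!length(pid))
    return(tibble::tibble(person_id = character(), max_covered_days = integer()))
  idx <- split(seq_along(pid), pid)
  vals <- vapply(idx, function(i) {
    m <- merge_intervals(iv$s[i], iv$e[i])
    max_window_merged(m$s, m$e, lo, hi, window_len)
  }, integer(1))
  tibble::tibble(person_id = names(idx), max_covered_days = unname(vals))
}

#' Age-specific empirical visit cut-offs
#'
#' For each age stratum the cut-off is the nearest-rank empirical percentile
#' of the visit-count distribution: the value at order statistic
#' `ceiling(p * n)`. Children *at or above* the cut-off are flagged, so the
#' flagged fraction is at least `1 - p` and ties can only enlarge it.
#'
#' @param counts integer visit counts, one per child
#' @param ages integer ages, same length
#' @param percentile percentile in (0, 1), default 0.95
#' @return tibble with `age`, `n`, `cutoff`
#' @export
visit_cutoffs <- function(counts, ages, percentile = 0.95) {
  if (length(counts) != length(ages))
    stop_validation("`counts` and `ages` must have equal length")
  if (percentile <= 0 || percentile >= 1)
    stop_config("`percentile` must lie strictly in (0, 1)")
  uages <- sort(unique(ages))
  if (!length(uages)) stop_config("no age strata present")
  rows <- lapply(uages, function(a) {
    x <- counts[ages == a]
    if (!length(x)) stop_config(paste0("empty visit-count stratum for age ", a))
    xs <- sort(x)
    k <- ceiling(percentile * length(xs))
    tibble::tibble(age = a, n = length(xs), cutoff = as.integer(xs[k]))
  })
  dplyr::bind_rows(rows)
}

#' High Service Use component and combined flags
#'
#' A child has High Service Use when either component criterion is met:
#' elevated medication use (maximum window coverage at or above the
#' configured threshold) or elevated physician visits (count at or above the
#' age-specific cut-off).
#'
#' @param high_medication,high_visits logical vectors
#' @return logical vector, the element-wise OR
#' @export
flag_high_service_use <- function(high_medication, high_visits) {
  if (!is.logical(high_medication) || !is.logical(high_visits))
    stop_validation("component flags must be logical")
  high_medication | high_visits
}

# map dot-stripped diagnosis codes to ADG ids by longest prefix match
map_codes_to_adg <- function(codes, config) {
  codes <- gsub(".", "", as.character(codes), fixed = TRUE)
  ucodes <- unique(codes)
  map <- config$adg_map[order(-nchar(config$adg_map$code)), ]
  adg <- rep(NA_integer_, length(ucodes))
  for (i in seq_len(nrow(map))) {
    hit <- is.na(adg) & startsWith(ucodes, map$code[i])
    adg[hit] <- map$adg[i]
  }
  if (anyNA(adg)) {
    bad <- ucodes[is.na(adg)]
    msg <- paste0("diagnosis codes not in adg_map: ",
                  paste(head(bad, 5), collapse = ", "),
                  if (length(bad) > 5) ", ...")
    switch(config$unmapped_policy,
           warn = warn(msg), error = stop_validation(msg), ignore = NULL)
  }
  adg[match(codes, ucodes)]
}

#' Diagnosis indicator from claim and hospital diagnosis codes
#'
#' TRUE when any diagnosis code maps (via the configured ADG mapping) to a
#' major and/or chronic ADG.
#'
#' @param codes character vector of ICD-9 codes observed for one child
#'   during the study year
#' @param config an [indicator_config()]
#' @return logical scalar
#' @export
flag_diagnosis <- function(codes, config = indicator_config()) {
  if (!length(codes)) return(FALSE)
  adg <- map_codes_to_adg(codes, config)
  any(adg %in% config$major_chronic_adgs)
}

#' Classify every child by the two indicators and the combined grouping
#'
#' Runs the full indicator computation over linked record streams: medication
#' coverage over the configured multi-year span, study-year visit counts with
#' age-specific nearest-rank cut-offs computed on the full child sample, and
#' the ADG-based Diagnosis flag from study-year physician-claim (and
#' optionally hospital) diagnoses.
#'
#' @param registry registry tibble (one row per person-year)
#' @param claims physician claims tibble
#' @param dispensings dispensing tibble
#' @param hospital hospital abstracts tibble or NULL
#' @param config an [indicator_config()]
#' @param study_year calendar year of classification
#' @return tibble with one row per child aged 6-10: component measures,
#'   flags and the four-level `group`
#' @export
classify_children <- function(registry, claims, dispensings, hospital = NULL,
                              config = indicator_config(), study_year = 2006) {
  kids <- dplyr::filter(registry, .data$role == "child")
  kids <- dplyr::mutate(kids, age = study_year - .data$birth_year)
  kids <- dplyr::filter(kids, .data$age >= 6, .data$age <= 10)
  kids <- dplyr::distinct(kids, .data$person_id, .data$age)
  if (!nrow(kids)) stop_validation("registry contains no children aged 6-10")

  yr <- function(d) as.integer(format(as.Date(d), "%Y"))
  kid_claims <- dplyr::filter(claims, .data$person_id %in% kids$person_id,
                              yr(.data$service_date) == study_year)

  visits <- kid_claims |>
    dplyr::filter(.data$service_class == "visit") |>
    dplyr::count(.data$person_id, name = "visit_count")
  kids <- dplyr::left_join(kids, visits, by = "person_id")
  kids$visit_count[is.na(kids$visit_count)] <- 0L

  cuts <- visit_cutoffs(kids$visit_count, kids$age, config$visit_percentile)
  kids <- dplyr::left_join(kids, dplyr::select(cuts, "age", cutoff = "cutoff"),
                           by = "age")

  kid_disp <- dplyr::filter(dispensings, .data$person_id %in% kids$person_id)
  cov <- max_window_coverage_by_person(kid_disp, config$med_obs_start,
                                       config$med_obs_end, config$window_len)
  kids <- dplyr::left_join(kids, cov, by = "person_id")
  kids$max_covered_days[is.na(kids$max_covered_days)] <- 0L

  dx_codes <- dplyr::select(kid_claims, "person_id", code = "icd9_code")
  if (config$include_hospital_dx && !is.null(hospital) && nrow(hospital)) {
    hs <- dplyr::filter(hospital, .data$person_id %in% kids$person_id,
                        yr(.data$admit_date) <= study_year,
                        yr(.data$discharge_date) >= study_year)
    if (nrow(hs)) {
      hx <- tibble::tibble(
        person_id = rep(hs$person_id, lengths(strsplit(hs$icd_codes, ";", fixed = TRUE))),
        code = unlist(strsplit(hs$icd_codes, ";", fixed = TRUE))
      )
      dx_codes <- dplyr::bind_rows(dx_codes, hx)
    }
  }
  dx_codes <- dplyr::filter(dx_codes, !is.na(.data$code), .data$code != "")
  if (nrow(dx_codes)) {
    dx_codes$adg <- map_codes_to_adg(dx_codes$code, config)
    dx_flagged <- dx_codes |>
      dplyr::filter(.data$adg %in% config$major_chronic_adgs) |>
      dplyr::distinct(.data$person_id)
  } else {
    dx_flagged <- tibble::tibble(person_id = character())
  }

  kids |>
    dplyr::mutate(
      high_medication = .data$max_covered_days >= config$med_days_threshold,
      high_visits = .data$visit_count >= .data$cutoff,
      high_service_use = flag_high_service_use(.data$high_medication, .data$high_visits),
      has_major_chronic_dx = .data$person_id %in% dx_flagged$person_id,
      group = assign_group(.data$high_service_use, .data$has_major_chronic_dx)
    ) |>
    dplyr::select(child_id = "person_id", "age", "max_covered_days",
                  "high_medication", "visit_count",
                  visit_cutoff_for_age = "cutoff", "high_visits",
                  "high_service_use", "has_major_chronic_dx", "group")
}
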