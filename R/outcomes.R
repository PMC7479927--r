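strip_dots <- function(codes) gsub(".", "", as.character(codes), fixed = TRUE)

# vectorised "code starts with any of the prefixes"
match_any_prefix <- function(codes, prefixes) {
  codes <- strip_dots(codes)
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) hit <- hit | startsWith(codes, p)
  hit
}

claim_year <- function(d) as.integer(format(as.Date(d), "%Y"))

#' Count a person's claims of one service class in a year
#'
#' For maternal outcomes, claims flagged as pregnancy-related or carrying a
#' pregnancy/birth ICD-9 prefix are excluded.
#'
#' @param claims claims tibble (typically one person's)
#' @param service_class one of `"visit"`, `"lab"`, `"xray"`
#' @param year calendar year
#' @param exclude_pregnancy apply the maternal pregnancy/birth exclusion
#' @param pregnancy_codes ICD-9 exclusion prefixes
#' @return integer count
#' @export
count_visits <- function(claims, service_class = "visit", year = 2006,
                         exclude_pregnancy = FALSE,
                         pregnancy_codes = default_pregnancy_codes()) {
  if (!service_class %in% c("visit", "lab", "xray"))
    stop_validation(paste0("unknown service class: ", service_class))
  if (!nrow(claims)) return(0L)
  keep <- claims$service_class == service_class &
    claim_year(claims$service_date) == year
  if (exclude_pregnancy)
    keep <- keep & !(claims$pregnancy_related %||% FALSE) &
      !match_any_prefix(claims$icd9_code, pregnancy_codes)
  sum(keep)
}

#' Count distinct specialties among a person's qualifying visit claims
#'
#' @inheritParams count_visits
#' @return integer count of distinct `specialty_code` values
#' @export
count_distinct_specialists <- function(claims, year = 2006,
                                       exclude_pregnancy = FALSE,
                                       pregnancy_codes = default_pregnancy_codes()) {
  if (!nrow(claims)) return(0L)
  keep <- claims$service_class == "visit" &
    claim_year(claims$service_date) == year
  if (exclude_pregnancy)
    keep <- keep & !(claims$pregnancy_related %||% FALSE) &
      !match_any_prefix(claims$icd9_code, pregnancy_codes)
  length(unique(claims$specialty_code[keep]))
}

#' Prescription-medication summaries for one person-year
#'
#' Medication days reuse the interval-union engine of [covered_days()]
#' clipped to the year; the therapeutic-breadth count is the number of
#' distinct level-3 ATC classes (first four characters); pain and insomnia
#' flags are ATC-prefix matches.
#'
#' @param dispensings one person's dispensing tibble
#' @param year calendar year
#' @param exclude_birth_control drop fills flagged as birth control
#' @param pain_prefixes,insomnia_prefixes ATC prefix sets
#' @return list with `n_rx_days`, `n_prescriptions`, `n_distinct_atc3`,
#'   `received_pain_med`, `received_insomnia_med`
#' @export
rx_summaries <- function(dispensings, year = 2006, exclude_birth_control = TRUE,
                         pain_prefixes = default_pain_atc(),
                         insomnia_prefixes = default_insomnia_atc()) {
  d <- dispensings
  if (nrow(d) && any(nchar(d$atc_code) < 4 | is.na(d$atc_code)))
    stop_validation("malformed ATC codes (need at least the 4-character level-3 class)")
  if (exclude_birth_control && nrow(d))
    d <- d[!(d$is_birth_control %||% FALSE), , drop = FALSE]
  in_year <- if (nrow(d)) claim_year(d$fill_date) == year else logical(0)
  dy <- d[in_year, , drop = FALSE]
  ystart <- as.Date(sprintf("%d-01-01", year))
  yend <- as.Date(sprintf("%d-12-31", year))
  list(
    n_rx_days = covered_days(d$fill_date, d$days_supplied, ystart, yend),
    n_prescriptions = nrow(dy),
    n_distinct_atc3 = length(unique(substr(dy$atc_code, 1, 4))),
    received_pain_med = any(match_any_prefix(dy$atc_code, pain_prefixes)),
    received_insomnia_med = any(match_any_prefix(dy$atc_code, insomnia_prefixes))
  )
}

#' Hospitalization summary for one person-year
#'
#' Length of stay is counted as nights (discharge minus admit), attributed
#' to the year by clipping the night range to the year's boundaries.
#' Same-day stays contribute zero days but still set the hospitalization
#' flag. Birth-related stays can be excluded entirely.
#'
#' @param abstracts one person's hospital abstracts
#' @param year calendar year
#' @param exclude_birth drop stays flagged as birth-related
#' @return list with `any_hospitalization` and `days_hospitalized`
#' @export
hospitalization_summary <- function(abstracts, year = 2006, exclude_birth = TRUE) {
  if (!nrow(abstracts)) return(list(any_hospitalization = FALSE, days_hospitalized = 0L))
  a <- as.Date(abstracts$admit_date)
  d <- as.Date(abstracts$discharge_date)
  if (any(d < a)) stop_validation("discharge_date precedes admit_date")
  keep <- !(exclude_birth & (abstracts$birth_related %||% FALSE))
  ystart <- as.Date(sprintf("%d-01-01", year))
  yend <- as.Date(sprintf("%d-12-31", year))
  in_year <- keep & a <= yend & d >= ystart
  nights <- pmax(0L, as.integer(pmin(d - 1, yend) - pmax(a, ystart)) + 1L)
  list(any_hospitalization = any(in_year),
       days_hospitalized = as.integer(sum(nights[in_year])))
}

#' Chronic-condition flags from one person-year of diagnosis codes
#'
#' Each configured condition is TRUE when any code matches its ICD-9 prefix
#' list; `any_chronic` is the OR over all configured lists.
#'
#' @param codes character vector of ICD-9 codes observed in the year
#' @param codesets named list of ICD-9 prefix vectors
#' @return named logical list (one per condition, plus `any_chronic`)
#' @export
condition_flags <- function(codes, codesets = default_condition_codesets()) {
  if (!length(codesets) || any(!lengths(codesets)))
    stop_config("every condition code list must be non-empty")
  flags <- lapply(codesets, function(p) any(match_any_prefix(codes, p)))
  c(flags, list(any_chronic = any(unlist(flags))))
}

#' Compute all person-level outcomes for a set of people
#'
#' Batch engine over the event streams; equivalent to applying the
#' per-person operations ([count_visits()], [count_distinct_specialists()],
#' [rx_summaries()], [hospitalization_summary()], [condition_flags()]) to
#' each person, but vectorised. Persons without events get zero counts and
#' FALSE flags. For `role = "mother"` the pregnancy/birth visit exclusion
#' and the birth-control and birth-hospitalization exclusions apply.
#'
#' @param person_ids character vector of persons to report
#' @param claims,dispensings,hospital event stream tibbles
#' @param config an [outcome_config()]
#' @param role `"mother"` or `"child"`
#' @return tibble with one row per person: all outcome columns, plus one
#'   `cond_*` column per configured condition list
#' @export
compute_outcomes <- function(person_ids, claims, dispensings, hospital,
                             config = outcome_config(),
                             role = c("mother", "child")) {
  role <- match.arg(role)
  maternal <- role == "mother"
  year <- config$year
  out <- tibble::tibble(person_id = unique(as.character(person_ids)))

  cl <- dplyr::filter(claims, .data$person_id %in% out$person_id,
                      claim_year(.data$service_date) == year)
  excl <- if (maternal && nrow(cl)) {
    (cl$pregnancy_related %||% FALSE) |
      match_any_prefix(cl$icd9_code, config$pregnancy_exclusion_codes)
  } else rep(FALSE, nrow(cl))

  count_by <- function(tab, name) {
    x <- dplyr::count(tab, .data$person_id, name = name)
    out <<- dplyr::left_join(out, x, by = "person_id")
    out[[name]][is.na(out[[name]])] <<- 0L
    invisible(NULL)
  }
  count_by(cl[cl$service_class == "visit" & !excl, ], "n_physician_visits")
  count_by(cl[cl$service_class == "lab", ], "n_lab_visits")
  count_by(cl[cl$service_class == "xray", ], "n_xray_visits")
  spec <- cl[cl$service_class == "visit" & !excl, ] |>
    dplyr::distinct(.data$person_id, .data$specialty_code) |>
    dplyr::count(.data$person_id, name = "n_distinct_specialists")
  out <- dplyr::left_join(out, spec, by = "person_id")
  out$n_distinct_specialists[is.na(out$n_distinct_specialists)] <- 0L

  dd <- dplyr::filter(dispensings, .data$person_id %in% out$person_id)
  if (maternal && config$exclude_birth_control && nrow(dd))
    dd <- dd[!(dd$is_birth_control %||% FALSE), , drop = FALSE]
  if (nrow(dd) && any(nchar(dd$atc_code) < 4 | is.na(dd$atc_code)))
    stop_validation("malformed ATC codes in dispensings")
  ystart <- as.integer(as.Date(sprintf("%d-01-01", year)))
  yend <- as.integer(as.Date(sprintf("%d-12-31", year)))
  rxdays <- union_days_by_person(dd, ystart, yend)
  out <- dplyr::left_join(out, rxdays, by = "person_id")
  out$n_rx_days[is.na(out$n_rx_days)] <- 0L
  ddy <- dd[claim_year(dd$fill_date) == year, , drop = FALSE]
  count_by(ddy, "n_prescriptions")
  atc3 <- ddy |>
    dplyr::mutate(atc3 = substr(.data$atc_code, 1, 4)) |>
    dplyr::distinct(.data$person_id, .data$atc3) |>
    dplyr::count(.data$person_id, name = "n_distinct_atc3")
  out <- dplyr::left_join(out, atc3, by = "person_id")
  out$n_distinct_atc3[is.na(out$n_distinct_atc3)] <- 0L
  out$received_pain_med <- out$person_id %in%
    ddy$person_id[match_any_prefix(ddy$atc_code, config$pain_atc_prefixes)]
  out$received_insomnia_med <- out$person_id %in%
    ddy$person_id[match_any_prefix(ddy$atc_code, config$insomnia_atc_prefixes)]

  hh <- dplyr::filter(hospital, .data$person_id %in% out$person_id)
  if (nrow(hh)) {
    a <- as.Date(hh$admit_date); dis <- as.Date(hh$discharge_date)
    if (any(dis < a)) stop_validation("discharge_date precedes admit_date")
    if (maternal) hh <- hh[!(hh$birth_related %||% FALSE), , drop = FALSE]
    a <- as.Date(hh$admit_date); dis <- as.Date(hh$discharge_date)
    in_year <- as.integer(a) <= yend & as.integer(dis) >= ystart
    hh <- hh[in_year, , drop = FALSE]
    a <- a[in_year]; dis <- dis[in_year]
    nights <- pmax(0L, as.integer(pmin(as.integer(dis) - 1L, yend) -
                                    pmax(as.integer(a), ystart)) + 1L)
    hsum <- tibble::tibble(person_id = hh$person_id, nights = nights) |>
      dplyr::summarise(days_hospitalized = as.integer(sum(.data$nights)),
                       .by = "person_id")
    out <- dplyr::left_join(out, hsum, by = "person_id")
    out$any_hospitalization <- out$person_id %in% hh$person_id
  } else {
    out$days_hospitalized <- NA_integer_
    out$any_hospitalization <- FALSE
  }
  out$days_hospitalized[is.na(out$days_hospitalized)] <- 0L

  code_tab <- dplyr::bind_rows(
    dplyr::select(cl, "person_id", code = "icd9_code"),
    if (nrow(hh)) tibble::tibble(
      person_id = rep(hh$person_id, lengths(strsplit(hh$icd_codes, ";", fixed = TRUE))),
      code = unlist(strsplit(hh$icd_codes, ";", fixed = TRUE))
    )
  )
  for (nm in names(config$chronic_condition_codesets)) {
    hitters <- unique(code_tab$person_id[
      match_any_prefix(code_tab$code, config$chronic_condition_codesets[[nm]])])
    out[[paste0("cond_", nm)]] <- out$person_id %in% hitters
  }
  out$mood_anxiety <- out$cond_mood_anxiety
  cond_cols <- paste0("cond_", names(config$chronic_condition_codesets))
  out$any_chronic <- Reduce(`|`, lapply(cond_cols, function(cc) out[[cc]]))
  out
}

# per-person union-of-intervals day count clipped to [lo, hi] (integer days)
union_days_by_person <- function(dispensings, lo, hi) {
  if (!nrow(dispensings))
    return(tibble::tibble(person_id = character(), n_rx_days = integer()))
  tibble::tibble(
    person_id = dispensings$person_id,
    s = pmax(as.integer(as.Date(dispensings$fill_date)), lo),
    e = pmin(as.integer(as.Date(dispensings$fill_date)) +
               as.integer(dispensings$days_supplied) - 1L, hi)
  ) |>
    dplyr::filter(.data$s <= .data$e) |>
    dplyr::arrange(.data$person_id, .data$s, .data$e) |>
    dplyr::mutate(prev_max = dplyr::lag(cummax(.data$e)), .by = "person_id") |>
    dplyr::mutate(contrib = pmax(
      0L, .data$e - pmax(.data$s, dplyr::coalesce(.data$prev_max + 1L, .data$s)) + 1L)) |>
    dplyr::summarise(n_rx_days = as.integer(sum(.data$contrib)), .by = "person_id")
}
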