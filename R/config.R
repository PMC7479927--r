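#' Configuration for the synthetic linked-claims generator
#'
#' Defines the study conditions the generator emulates: a single study-year
#' cross-section of families registered with a provincial health plan, with
#' children aged 6-10 whose service use follows a latent four-class morbidity
#' structure calibrated so the downstream indicator prevalences match the
#' targets (defaults 18% High Service Use, 12% Diagnosis, 5% Both).
#'
#' @param n_families number of families to generate
#' @param study_year calendar year of the cross-section
#' @param obs_start,obs_end dates bounding the dispensing history used for the
#'   medication-days indicator
#' @param target_prev_hsu,target_prev_dx,target_prev_both target prevalences
#'   of the High Service Use indicator, the Diagnosis indicator and their
#'   conjunction among children
#' @param p_multi_mother_link proportion of children whose family contract
#'   carries more than one mother record (these links are excluded downstream)
#' @param p_multi_child_mother proportion of mothers with two or more
#'   children aged 6-10 in the study year
#' @param visit_dist_params per-latent-class negative-binomial parameters for
#'   study-year physician visit counts: a list with `ages` and, for each of
#'   `neither`, `dx_only`, `hsu_only`, `both`, a list `mu` (per-age means) and
#'   `size` (dispersion)
#' @param rx_duration_params lognormal days-supplied parameters for acute and
#'   chronic prescriptions plus the coverage range (days within one 365-day
#'   window) given to medication-route High Service Use children
#' @param maternal_effects per-group true maternal effects: additive mean
#'   shifts for the visit count (negative-binomial) and odds ratios for each
#'   binary outcome, with Neither as reference; base rates set the Neither
#'   level
#' @param p_male_morbid,p_male_healthy probability a child is male given
#'   latent morbidity status
#' @param p_latent_morbidity optional override for the total latent morbidity
#'   probability; `NULL` (default) lets the calibration derive it from the
#'   three prevalence targets
#' @param seed master integer seed; per-stream seeds are derived via
#'   [derive_seed()]
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_families = 2000,
                       study_year = 2006,
                       obs_start = "2005-01-01",
                       obs_end = "2007-12-31",
                       target_prev_hsu = 0.18,
                       target_prev_dx = 0.12,
                       target_prev_both = 0.05,
                       p_multi_mother_link = 0.12,
                       p_multi_child_mother = 0.23,
                       visit_dist_params = default_visit_dist_params(),
                       rx_duration_params = default_rx_duration_params(),
                       maternal_effects = default_maternal_effects(),
                       p_male_morbid = 0.556,
                       p_male_healthy = 0.503,
                       p_latent_morbidity = NULL,
                       seed = 1L) {
  cfg <- structure(
    list(
      n_families = as.integer(n_families),
      study_year = as.integer(study_year),
      obs_start = as_date_scalar(obs_start, "obs_start"),
      obs_end = as_date_scalar(obs_end, "obs_end"),
      target_prev_hsu = target_prev_hsu,
      target_prev_dx = target_prev_dx,
      target_prev_both = target_prev_both,
      p_multi_mother_link = p_multi_mother_link,
      p_multi_child_mother = p_multi_child_mother,
      visit_dist_params = visit_dist_params,
      rx_duration_params = rx_duration_params,
      maternal_effects = maternal_effects,
      p_male_morbid = p_male_morbid,
      p_male_healthy = p_male_healthy,
      p_latent_morbidity = p_latent_morbidity,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_families) || is.na(cfg$n_families) || cfg$n_families < 1)
    stop_config("`n_families` must be a positive integer")
  for (p in c("target_prev_hsu", "target_prev_dx", "target_prev_both",
              "p_multi_mother_link", "p_multi_child_mother",
              "p_male_morbid", "p_male_healthy"))
    check_prob(cfg[[p]], p)
  if (cfg$target_prev_both > min(cfg$target_prev_hsu, cfg$target_prev_dx))
    stop_config("`target_prev_both` must not exceed min(target_prev_hsu, target_prev_dx)")
  if (!(cfg$obs_start < cfg$obs_end))
    stop_config("`obs_start` must precede `obs_end`")
  yrs <- as.integer(format(c(cfg$obs_start, cfg$obs_end), "%Y"))
  if (cfg$study_year < yrs[1] || cfg$study_year > yrs[2])
    stop_config("`study_year` must lie within [year(obs_start), year(obs_end)]")
  if (!is.null(cfg$p_latent_morbidity)) check_prob(cfg$p_latent_morbidity, "p_latent_morbidity")
  shifts <- cfg$maternal_effects$visits$shift
  need <- c("DIAGNOSIS_ONLY", "HSU_ONLY", "BOTH")
  for (nm in c("visits", "chronic", "mood", "hospitalization")) {
    eff <- cfg$maternal_effects[[nm]]
    if (is.null(eff)) stop_config(paste0("maternal_effects$", nm, " is missing"))
    vec <- if (nm == "visits") eff$shift else eff$or
    if (!all(need %in% names(vec)))
      stop_config(paste0("maternal_effects$", nm, " must name effects for ",
                         paste(need, collapse = ", ")))
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  families:", x$n_families, " study year:", x$study_year, "\n")
  cat("  dispensing window:", format(x$obs_start), "..", format(x$obs_end), "\n")
  cat(sprintf("  target prevalences: HSU %.1f%%, Dx %.1f%%, Both %.1f%%\n",
              100 * x$target_prev_hsu, 100 * x$target_prev_dx, 100 * x$target_prev_both))
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' @rdname sim_config
#' @export
default_visit_dist_params <- function() {
  list(
    ages = 6:10,
    neither  = list(mu = c(2.9, 2.7, 2.5, 2.35, 2.2), size = 2.2),
    dx_only  = list(mu = rep(4.8, 5), size = 1.6),
    hsu_only = list(mu = c(8.6, 8.4, 8.2, 8.0, 7.8), size = 3.0),
    both     = list(mu = c(11.4, 11.2, 11.0, 10.8, 10.6), size = 3.0)
  )
}

#' @rdname sim_config
#' @export
default_rx_duration_params <- function() {
  list(
    acute_meanlog = log(9), acute_sdlog = 0.45,
    chronic_meanlog = log(45), chronic_sdlog = 0.35,
    coverage_min = 274, coverage_max = 340
  )
}

#' @rdname sim_config
#' @export
default_maternal_effects <- function() {
  g <- c("DIAGNOSIS_ONLY", "HSU_ONLY", "BOTH")
  list(
    visits = list(base_mean = 6.14, size = 0.65,
                  shift = setNames(c(1.33, 4.57, 4.87), g)),
    chronic = list(base_rate = 0.2742, or = setNames(c(1.30, 1.87, 1.90), g)),
    mood = list(base_rate = 0.1359, or = setNames(c(1.20, 1.69, 1.81), g)),
    hospitalization = list(base_rate = 0.0268, or = setNames(c(1.14, 1.33, 1.41), g))
  )
}

#' Null maternal effects (all shifts 0, all odds ratios 1)
#'
#' Convenience for calibration checks: under these effects every maternal
#' outcome has the same distribution in all four child groups.
#'
#' @return a maternal-effects list suitable for [sim_config()]
#' @export
null_maternal_effects <- function() {
  eff <- default_maternal_effects()
  eff$visits$shift[] <- 0
  for (nm in c("chronic", "mood", "hospitalization")) eff[[nm]]$or[] <- 1
  eff
}

#' Configuration for the child health indicators
#'
#' @param med_days_threshold minimum medication-covered days within one
#'   window to qualify as elevated medication use (default 274, i.e. nine
#'   months)
#' @param window_len sliding-window length in days (default 365)
#' @param med_obs_start,med_obs_end observation span scanned by the window
#' @param visit_percentile age-specific empirical percentile defining the
#'   elevated visit cut-off (default 0.95)
#' @param adg_map two-column data frame (`code`, `adg`) mapping ICD-9
#'   prefixes to ADG ids; see [default_adg_map()]
#' @param major_chronic_adgs ADG ids counted as major and/or chronic
#' @param unmapped_policy what to do with diagnosis codes absent from
#'   `adg_map`: warn and ignore (default), silently ignore, or error
#' @param include_hospital_dx whether hospital abstract diagnoses feed the
#'   Diagnosis indicator alongside physician claims
#' @return an object of class `indicator_config`
#' @export
indicator_config <- function(med_days_threshold = 274L,
                             window_len = 365L,
                             med_obs_start = "2005-01-01",
                             med_obs_end = "2007-12-31",
                             visit_percentile = 0.95,
                             adg_map = default_adg_map(),
                             major_chronic_adgs = default_major_chronic_adgs(),
                             unmapped_policy = c("warn", "ignore", "error"),
                             include_hospital_dx = TRUE) {
  cfg <- structure(
    list(
      med_days_threshold = as.integer(med_days_threshold),
      window_len = as.integer(window_len),
      med_obs_start = as_date_scalar(med_obs_start, "med_obs_start"),
      med_obs_end = as_date_scalar(med_obs_end, "med_obs_end"),
      visit_percentile = visit_percentile,
      adg_map = tibble::as_tibble(adg_map),
      major_chronic_adgs = as.integer(major_chronic_adgs),
      unmapped_policy = match.arg(unmapped_policy),
      include_hospital_dx = isTRUE(include_hospital_dx)
    ),
    class = "indicator_config"
  )
  if (cfg$med_days_threshold <= 0 || cfg$med_days_threshold > cfg$window_len)
    stop_config("`med_days_threshold` must satisfy 0 < threshold <= window_len")
  if (cfg$visit_percentile <= 0 || cfg$visit_percentile >= 1)
    stop_config("`visit_percentile` must lie strictly in (0, 1)")
  if (!all(c("code", "adg") %in% names(cfg$adg_map)))
    stop_config("`adg_map` needs columns `code` and `adg`")
  cfg
}

#' Configuration for outcome construction
#'
#' @param year calendar year outcomes are measured over
#' @param pregnancy_exclusion_codes ICD-9 prefixes whose claims are removed
#'   from maternal visit counts (in addition to the pregnancy flag)
#' @param chronic_condition_codesets named list of ICD-9 prefix vectors; must
#'   include `mood_anxiety`; the any-chronic flag is the OR over all lists
#' @param pain_atc_prefixes,insomnia_atc_prefixes ATC prefixes defining the
#'   medication-class outcome flags
#' @param exclude_birth_control whether birth-control dispensings are dropped
#'   from maternal prescription outcomes
#' @return an object of class `outcome_config`
#' @export
outcome_config <- function(year = 2006,
                           pregnancy_exclusion_codes = default_pregnancy_codes(),
                           chronic_condition_codesets = default_condition_codesets(),
                           pain_atc_prefixes = default_pain_atc(),
                           insomnia_atc_prefixes = default_insomnia_atc(),
                           exclude_birth_control = TRUE) {
  if (!length(chronic_condition_codesets) ||
      any(!lengths(chronic_condition_codesets)))
    stop_config("every named condition code list must be non-empty")
  if (!"mood_anxiety" %in% names(chronic_condition_codesets))
    stop_config("`chronic_condition_codesets` must include a `mood_anxiety` list")
  structure(
    list(
      year = as.integer(year),
      pregnancy_exclusion_codes = as.character(pregnancy_exclusion_codes),
      chronic_condition_codesets = chronic_condition_codesets,
      pain_atc_prefixes = as.character(pain_atc_prefixes),
      insomnia_atc_prefixes = as.character(insomnia_atc_prefixes),
      exclude_birth_control = isTRUE(exclude_birth_control)
    ),
    class = "outcome_config"
  )
}

#' Load pipeline configuration from a YAML file
#'
#' The file may contain top-level sections `sim`, `indicators` and
#' `outcomes`, each holding arguments for [sim_config()],
#' [indicator_config()] and [outcome_config()]; missing sections fall back
#' to defaults. Within `indicators`, `adg_map` may be a path to a
#' two-column CSV (`code`, `adg`).
#'
#' @param path YAML file path
#' @return list with elements `sim`, `indicators`, `outcomes`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_config(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  ind <- raw$indicators %||% list()
  if (!is.null(ind$adg_map) && is.character(ind$adg_map))
    ind$adg_map <- readr::read_csv(ind$adg_map, show_col_types = FALSE,
                                   col_types = readr::cols(code = "c", adg = "i"))
  list(
    sim = do.call(sim_config, raw$sim %||% list()),
    indicators = do.call(indicator_config, ind),
    outcomes = do.call(outcome_config, raw$outcomes %||% list())
  )
}
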