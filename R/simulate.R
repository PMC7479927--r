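LATENT_LEVELS <- c("NEITHER", "DIAGNOSIS_ONLY", "HSU_ONLY", "BOTH")

# synthetic ICD-9 pools (all child codes resolve in default_adg_map())
child_chronic_codes <- function() c("493", "250", "345", "343", "299", "714", "277")
child_benign_codes <- function() c("460", "465", "382", "079", "558", "919",
                                   "708", "692", "786", "780", "V20")
mother_benign_codes <- function() c("786", "780", "724", "460", "463", "919", "V70")
mother_mood_codes <- function() c("296", "300", "309", "311")
mother_physical_codes <- function() c("493", "250", "714", "401", "346", "244", "410", "428")

#' Calibrate latent class probabilities to the prevalence targets
#'
#' The generator assigns each child a latent class (Neither, Diagnosis only,
#' High Service Use only, Both). Children in the two HSU classes always
#' receive a medication spell meeting the coverage threshold (exact
#' medication route), while the visit route is *relative*: the age-specific
#' 95th-percentile cut-off also sweeps in some Neither and Diagnosis-only
#' children with high visit counts. This routine solves, by a fixed point on
#' negative-binomial tail probabilities, for latent probabilities such that
#' the expected recovered prevalences equal the targets after that
#' spillover.
#'
#' @param config a [sim_config()]
#' @param percentile visit percentile assumed downstream (default 0.95)
#' @return list with `pi` (named latent probabilities), per-age expected
#'   cut-offs, and the spillover rates for the Neither and Diagnosis-only
#'   classes
#' @export
calibrate_latent_probs <- function(config, percentile = 0.95) {
  vp <- config$visit_dist_params
  tH <- config$target_prev_hsu; tD <- config$target_prev_dx
  tB <- config$target_prev_both
  sD <- 0; sN <- 0
  piB <- piD <- piH <- piN <- NA_real_
  q <- rep(NA_real_, length(vp$ages))
  for (it in 1:12) {
    piB <- (tB - tD * sD) / (1 - sD)
    piD <- tD - piB
    piHB <- (tH - piD * sD - (1 - piD) * sN) / (1 - sN)
    piH <- piHB - piB
    piN <- 1 - piD - piHB
    if (min(piB, piD, piH, piN) < 0)
      stop_config("prevalence targets are not attainable with these visit distributions")
    for (a in seq_along(vp$ages)) {
      xs <- 0:200
      F <- piN * stats::pnbinom(xs, mu = vp$neither$mu[a], size = vp$neither$size) +
        piD * stats::pnbinom(xs, mu = vp$dx_only$mu[a], size = vp$dx_only$size) +
        piH * stats::pnbinom(xs, mu = vp$hsu_only$mu[a], size = vp$hsu_only$size) +
        piB * stats::pnbinom(xs, mu = vp$both$mu[a], size = vp$both$size)
      q[a] <- xs[which(F >= percentile)[1]]
    }
    sD <- mean(1 - stats::pnbinom(q - 1, mu = vp$dx_only$mu, size = vp$dx_only$size))
    sN <- mean(1 - stats::pnbinom(q - 1, mu = vp$neither$mu, size = vp$neither$size))
  }
  pi <- setNames(c(piN, piD, piH, piB), LATENT_LEVELS)
  if (!is.null(config$p_latent_morbidity)) {
    scale <- config$p_latent_morbidity / (1 - pi["NEITHER"])
    pi[-1] <- pi[-1] * scale
    pi[1] <- 1 - sum(pi[-1])
  }
  list(pi = pi, expected_cutoffs = tibble::tibble(age = vp$ages, cutoff = q),
       spill_neither = sN, spill_dx_only = sD)
}

draw_nb <- function(n, mu, size) rnbinom(n, mu = mu, size = size)

rand_dates <- function(n, lo, hi) {
  as.Date(as.integer(lo) + floor(runif(n) * (as.integer(hi) - as.integer(lo) + 1L)),
          origin = "1970-01-01")
}

#' Generate a linked synthetic administrative-data bundle
#'
#' Emits four schema-valid record streams (registry, physician claims, drug
#' dispensings, hospital abstracts) for `n_families` families, each with one
#' or two mother records and one to three children aged 6-10 in the study
#' year, plus a ground-truth table carrying each child's latent class and
#' realised indicator flags and each mother's true outcome-model parameters.
#' Maternal outcomes are drawn from the configured effect models applied to
#' the mother's *realised* analysis group (the most severe group among her
#' children), so downstream parameter recovery is exact in expectation.
#' Deterministic for a fixed seed; each stream uses its own derived seed.
#'
#' @param config a [sim_config()]
#' @return an `admin_bundle`: list with `registry`, `claims`, `dispensings`,
#'   `hospital`, `truth`, plus the config and calibration attached
#' @export
generate_population <- function(config = sim_config()) {
  config <- validate_sim_config(config)
  cal <- calibrate_latent_probs(config)
  n_fam <- config$n_families
  yr <- config$study_year
  ystart <- as.Date(sprintf("%d-01-01", yr)); yend <- as.Date(sprintf("%d-12-31", yr))

  ## -- families and registry ------------------------------------------------
  set.seed(derive_seed(config$seed, 1))
  fam_id <- sprintf("F%06d", seq_len(n_fam))
  pmc <- config$p_multi_child_mother
  n_children <- sample(1:3, n_fam, replace = TRUE,
                       prob = c(1 - pmc, pmc * 0.91, pmc * 0.09))
  two_mothers <- runif(n_fam) < config$p_multi_mother_link

  n_kids <- sum(n_children)
  kid_fam <- rep(seq_len(n_fam), n_children)
  kid_id <- sprintf("C%07d", seq_len(n_kids))
  kid_age <- sample(6:10, n_kids, replace = TRUE)
  latent <- sample(LATENT_LEVELS, n_kids, replace = TRUE, prob = cal$pi)
  morbid <- latent != "NEITHER"
  kid_sex <- ifelse(runif(n_kids) < ifelse(morbid, config$p_male_morbid,
                                           config$p_male_healthy), "M", "F")

  fam_morbid <- as.logical(tapply(morbid, kid_fam, any))
  income_q <- vapply(seq_len(n_fam), function(i) {
    p1 <- if (fam_morbid[i]) 0.207 else 0.194
    sample(1:5, 1, prob = c(p1, rep((1 - p1) / 4, 4)))
  }, integer(1))
  subsidy <- runif(n_fam) < ifelse(fam_morbid, 0.30, 0.235)

  n_moms <- n_fam + sum(two_mothers)
  mom_fam <- c(seq_len(n_fam), which(two_mothers))
  mom_id <- sprintf("M%07d", seq_len(n_moms))
  mom_age <- pmin(pmax(round(rnorm(n_moms, 38.06, 5.88)), 20), 60)

  registry <- dplyr::bind_rows(
    tibble::tibble(person_id = mom_id, family_contract_id = fam_id[mom_fam],
                   role = "mother", sex = "F", birth_year = yr - mom_age,
                   income_quintile = income_q[mom_fam],
                   premium_subsidy = subsidy[mom_fam], year = yr),
    tibble::tibble(person_id = kid_id, family_contract_id = fam_id[kid_fam],
                   role = "child", sex = kid_sex, birth_year = yr - kid_age,
                   income_quintile = income_q[kid_fam],
                   premium_subsidy = subsidy[kid_fam], year = yr)
  )

  ## -- child physician claims ----------------------------------------------
  set.seed(derive_seed(config$seed, 2))
  vp <- config$visit_dist_params
  aidx <- match(kid_age, vp$ages)
  class_key <- c(NEITHER = "neither", DIAGNOSIS_ONLY = "dx_only",
                 HSU_ONLY = "hsu_only", BOTH = "both")
  mu_lookup <- t(vapply(class_key, function(k) vp[[k]]$mu, numeric(length(vp$ages))))
  size_lookup <- vapply(class_key, function(k) vp[[k]]$size, numeric(1))
  cidx <- match(latent, LATENT_LEVELS)
  mu <- mu_lookup[cbind(cidx, aidx)]
  size <- size_lookup[cidx]
  kid_visits <- rnbinom(n_kids, mu = mu, size = size)
  has_dx <- latent %in% c("DIAGNOSIS_ONLY", "BOTH")
  kid_visits[has_dx & kid_visits == 0L] <- 1L

  kc_pid <- rep(kid_id, kid_visits)
  kc_seq <- sequence(kid_visits)
  kc_dx <- rep(has_dx, kid_visits) & kc_seq <= 2L
  kc_icd <- sample(child_benign_codes(), length(kc_pid), replace = TRUE)
  kc_icd[kc_dx] <- sample(child_chronic_codes(), sum(kc_dx), replace = TRUE)
  kid_claims <- tibble::tibble(
    person_id = kc_pid,
    service_date = rand_dates(length(kc_pid), ystart, yend),
    service_class = rep("visit", length(kc_pid)),
    specialty_code = sample(c("GP", "PEDS"), length(kc_pid), replace = TRUE,
                            prob = c(0.8, 0.2)),
    icd9_code = kc_icd,
    pregnancy_related = rep(FALSE, length(kc_pid))
  )
  lab_mu <- c(NEITHER = 0.20, DIAGNOSIS_ONLY = 0.9, HSU_ONLY = 1.2, BOTH = 2.3)[latent]
  xray_mu <- c(NEITHER = 0.07, DIAGNOSIS_ONLY = 0.30, HSU_ONLY = 0.45, BOTH = 0.65)[latent]
  kid_lab <- rnbinom(n_kids, mu = lab_mu, size = 0.3)
  kid_xray <- rnbinom(n_kids, mu = xray_mu, size = 0.3)
  kid_aux <- tibble::tibble(
    person_id = c(rep(kid_id, kid_lab), rep(kid_id, kid_xray)),
    service_date = rand_dates(sum(kid_lab) + sum(kid_xray), ystart, yend),
    service_class = rep(c("lab", "xray"), c(sum(kid_lab), sum(kid_xray))),
    specialty_code = rep(c("LAB", "XRAY"), c(sum(kid_lab), sum(kid_xray))),
    icd9_code = sample(child_benign_codes(), sum(kid_lab) + sum(kid_xray),
                       replace = TRUE),
    pregnancy_related = FALSE
  )

  ## -- child dispensings ----------------------------------------------------
  set.seed(derive_seed(config$seed, 3))
  rx <- config$rx_duration_params
  is_hsu <- latent %in% c("HSU_ONLY", "BOTH")
  idx_hsu <- which(is_hsu)
  wlen <- 365L
  win_start <- rand_dates(length(idx_hsu), config$obs_start,
                          config$obs_end - wlen + 1L)
  cov_days <- sample(rx$coverage_min:rx$coverage_max, length(idx_hsu), replace = TRUE)
  supply <- pmin(pmax(round(rlnorm(length(idx_hsu), rx$chronic_meanlog,
                                   rx$chronic_sdlog)), 14), 100)
  nfill <- ceiling(cov_days / supply)
  cd_pid <- rep(kid_id[idx_hsu], nfill)
  cd_seq <- sequence(nfill)
  cd_supply <- rep(supply, nfill)
  cd_start <- rep(as.integer(win_start), nfill) + (cd_seq - 1L) * cd_supply
  cd_last <- cd_seq == rep(nfill, nfill)
  cd_days <- cd_supply
  cd_days[cd_last] <- (rep(cov_days, nfill) - (cd_seq - 1L) * cd_supply)[cd_last]
  atc1 <- sample(c("R03AC02", "R03BA02", "N06BA04", "A10AB01", "N03AX09"),
                 length(idx_hsu), replace = TRUE)
  atc2 <- sample(c("R03AC02", "N02BE01", "D07AC01", "R06AX13"),
                 length(idx_hsu), replace = TRUE)
  cd_atc <- rep(atc2, nfill)
  cd_odd <- cd_seq %% 2L == 1L
  cd_atc[cd_odd] <- rep(atc1, nfill)[cd_odd]
  chronic_disp <- tibble::tibble(
    person_id = cd_pid,
    fill_date = as.Date(cd_start, origin = "1970-01-01"),
    days_supplied = as.integer(cd_days),
    atc_code = cd_atc, is_birth_control = FALSE
  )
  acute_lambda <- c(NEITHER = 0.6, DIAGNOSIS_ONLY = 1.6,
                    HSU_ONLY = 1.2, BOTH = 1.8)[latent]
  n_acute <- rpois(n_kids, acute_lambda)
  ac_pid <- rep(kid_id, n_acute)
  acute_disp <- tibble::tibble(
    person_id = ac_pid,
    fill_date = rand_dates(length(ac_pid), config$obs_start, config$obs_end),
    days_supplied = as.integer(pmin(pmax(round(rlnorm(length(ac_pid),
                                                      rx$acute_meanlog,
                                                      rx$acute_sdlog)), 3), 30)),
    atc_code = sample(c("J01CA04", "R06AX13", "D07AC01", "N02BE01"),
                      length(ac_pid), replace = TRUE),
    is_birth_control = FALSE
  )

  ## -- child hospital abstracts ---------------------------------------------
  set.seed(derive_seed(config$seed, 4))
  p_hosp_kid <- c(NEITHER = 0.005, DIAGNOSIS_ONLY = 0.030,
                  HSU_ONLY = 0.035, BOTH = 0.080)[latent]
  hosp_kid <- which(runif(n_kids) < p_hosp_kid)
  nk <- length(hosp_kid)
  kh_admit <- rand_dates(nk, ystart, yend)
  kh_los <- integer(nk)
  long <- runif(nk) >= 0.15
  kh_los[long] <- 1L + rpois(sum(long), 1.5)
  kh_icd <- sample(child_benign_codes(), nk, replace = TRUE)
  kh_icd[has_dx[hosp_kid]] <- sample(child_chronic_codes(),
                                     sum(has_dx[hosp_kid]), replace = TRUE)
  kid_hosp <- tibble::tibble(
    person_id = kid_id[hosp_kid],
    admit_date = kh_admit,
    discharge_date = kh_admit + kh_los,
    icd_codes = kh_icd,
    birth_related = rep(FALSE, nk)
  )

  ## -- classify children (realised groups) ----------------------------------
  kid_streams <- list(
    claims = dplyr::bind_rows(kid_claims, kid_aux),
    dispensings = dplyr::bind_rows(chronic_disp, acute_disp) |>
      dplyr::mutate(din = atc_formulary()$din[match(.data$atc_code,
                                                    atc_formulary()$atc)]) |>
      dplyr::relocate("din", .before = "atc_code"),
    hospital = kid_hosp
  )
  icfg <- indicator_config(
    med_obs_start = config$obs_start, med_obs_end = config$obs_end)
  groups <- classify_children(registry, kid_streams$claims,
                              kid_streams$dispensings, kid_streams$hospital,
                              icfg, yr)
  kid_group <- groups$group[match(kid_id, groups$child_id)]

  ## mother's analysis group: most severe among her family's children
  fam_rank <- tapply(severity_rank(kid_group), kid_fam, max)
  mom_group <- factor(group_levels()[fam_rank[mom_fam] + 1L],
                      levels = group_levels(), ordered = TRUE)

  ## -- maternal outcome draws ------------------------------------------------
  set.seed(derive_seed(config$seed, 5))
  eff <- config$maternal_effects
  shift_of <- function(vec, g) {
    s <- c(NEITHER = 0, vec)[as.character(g)]
    unname(s)
  }
  or_of <- function(vec, g) unname(c(NEITHER = 1, vec)[as.character(g)])
  lp_visits <- eff$visits$base_mean + shift_of(eff$visits$shift, mom_group)
  p_chronic <- stats::plogis(stats::qlogis(eff$chronic$base_rate) +
                               log(or_of(eff$chronic$or, mom_group)))
  p_mood <- stats::plogis(stats::qlogis(eff$mood$base_rate) +
                            log(or_of(eff$mood$or, mom_group)))
  p_hosp <- stats::plogis(stats::qlogis(eff$hospitalization$base_rate) +
                            log(or_of(eff$hospitalization$or, mom_group)))
  mom_visits <- rnbinom(n_moms, mu = lp_visits, size = eff$visits$size)
  mood <- runif(n_moms) < p_mood
  # couple the any-chronic draw to the mood draw so both marginals stay
  # logistic while any_chronic (the OR over all lists, mood included) holds
  p_extra <- pmax(0, (p_chronic - p_mood) / (1 - p_mood))
  chronic <- mood | (runif(n_moms) < p_extra)
  hosp <- runif(n_moms) < p_hosp

  ## -- maternal claims --------------------------------------------------------
  set.seed(derive_seed(config$seed, 6))
  n_cond <- as.integer(mood) + as.integer(chronic & !mood)
  n_emit <- pmax(mom_visits, n_cond)
  mc_pid <- rep(mom_id, n_emit)
  mc_seq <- sequence(n_emit)
  mc_mood <- rep(mood, n_emit) & mc_seq == 1L
  mc_phys <- rep(chronic & !mood, n_emit) & mc_seq == 1L
  mc_code <- sample(mother_benign_codes(), length(mc_pid), replace = TRUE)
  mc_code[mc_mood] <- sample(mother_mood_codes(), sum(mc_mood), replace = TRUE)
  mc_code[mc_phys] <- sample(mother_physical_codes(), sum(mc_phys), replace = TRUE)
  mom_claims <- tibble::tibble(
    person_id = mc_pid,
    service_date = rand_dates(length(mc_pid), ystart, yend),
    service_class = "visit",
    specialty_code = sample(c("GP", "OBGYN", "PSY", "INT", "DERM", "ORTH"),
                            length(mc_pid), replace = TRUE,
                            prob = c(0.55, 0.1, 0.1, 0.1, 0.08, 0.07)),
    icd9_code = mc_code,
    pregnancy_related = FALSE
  )
  preg <- which(runif(n_moms) < 0.07)
  n_preg <- 1L + rpois(length(preg), 0.8)
  preg_claims <- tibble::tibble(
    person_id = rep(mom_id[preg], n_preg),
    service_date = rand_dates(sum(n_preg), ystart, yend),
    service_class = "visit",
    specialty_code = "OBGYN",
    icd9_code = sample(c("650", "V22"), sum(n_preg), replace = TRUE),
    pregnancy_related = TRUE
  )
  lab_shift <- shift_of(setNames(c(0.35, 0.75, 0.78),
                                 c("DIAGNOSIS_ONLY", "HSU_ONLY", "BOTH")), mom_group)
  xr_shift <- shift_of(setNames(c(0.15, 0.32, 0.35),
                                c("DIAGNOSIS_ONLY", "HSU_ONLY", "BOTH")), mom_group)
  mom_lab <- rnbinom(n_moms, mu = 1.30 + lab_shift, size = 0.8)
  mom_xray <- rnbinom(n_moms, mu = 0.52 + xr_shift, size = 0.6)
  mom_aux <- tibble::tibble(
    person_id = c(rep(mom_id, mom_lab), rep(mom_id, mom_xray)),
    service_date = rand_dates(sum(mom_lab) + sum(mom_xray), ystart, yend),
    service_class = rep(c("lab", "xray"), c(sum(mom_lab), sum(mom_xray))),
    specialty_code = rep(c("LAB", "XRAY"), c(sum(mom_lab), sum(mom_xray))),
    icd9_code = sample(mother_benign_codes(), sum(mom_lab) + sum(mom_xray),
                       replace = TRUE),
    pregnancy_related = FALSE
  )

  ## -- maternal dispensings ----------------------------------------------------
  set.seed(derive_seed(config$seed, 7))
  fill_shift <- shift_of(setNames(c(1.5, 4.2, 4.0),
                                  c("DIAGNOSIS_ONLY", "HSU_ONLY", "BOTH")), mom_group)
  n_fills <- rnbinom(n_moms, mu = 5.6 + fill_shift, size = 0.5)
  md_pid_idx <- rep(seq_len(n_moms), n_fills)
  morbid_mom <- as.character(mom_group) != "NEITHER"
  form <- atc_formulary()
  pool <- setdiff(form$atc, "G03AA07")
  w_base <- rep(1, length(pool))
  w_morbid <- w_base + 2 * (substr(pool, 1, 3) %in% c("N02", "N05", "N06"))
  md_atc <- character(length(md_pid_idx))
  is_mm <- morbid_mom[md_pid_idx]
  md_atc[!is_mm] <- sample(pool, sum(!is_mm), replace = TRUE, prob = w_base)
  md_atc[is_mm] <- sample(pool, sum(is_mm), replace = TRUE, prob = w_morbid)
  mom_disp <- tibble::tibble(
    person_id = mom_id[md_pid_idx],
    fill_date = rand_dates(length(md_pid_idx), ystart, yend),
    days_supplied = as.integer(pmin(pmax(round(rlnorm(length(md_pid_idx),
                                                      log(18), 0.7)), 1), 100)),
    atc_code = md_atc, is_birth_control = FALSE
  )
  bc <- which(runif(n_moms) < 0.15)
  n_bc <- 1L + rpois(length(bc), 1.5)
  bc_disp <- tibble::tibble(
    person_id = rep(mom_id[bc], n_bc),
    fill_date = rand_dates(sum(n_bc), ystart, yend),
    days_supplied = as.integer(sample(c(28L, 56L, 84L), sum(n_bc), replace = TRUE)),
    atc_code = "G03AA07", is_birth_control = TRUE
  )

  ## -- maternal hospital -------------------------------------------------------
  set.seed(derive_seed(config$seed, 8))
  mh <- which(hosp)
  mh_admit <- rand_dates(length(mh), ystart, yend)
  mh_los <- integer(length(mh))
  mh_long <- runif(length(mh)) >= 0.12
  mh_los[mh_long] <- 1L + rpois(sum(mh_long), 2)
  mom_hosp <- tibble::tibble(
    person_id = mom_id[mh],
    admit_date = mh_admit,
    discharge_date = mh_admit + mh_los,
    icd_codes = sample(mother_benign_codes()[1:3], length(mh), replace = TRUE),
    birth_related = rep(FALSE, length(mh))
  )
  bh <- which(runif(n_moms) < 0.03)
  bh_admit <- rand_dates(length(bh), ystart, yend)
  birth_hosp <- tibble::tibble(
    person_id = mom_id[bh],
    admit_date = bh_admit,
    discharge_date = bh_admit + 1L + rpois(length(bh), 1),
    icd_codes = rep("V27", length(bh)), birth_related = rep(TRUE, length(bh))
  )

  ## -- assemble ----------------------------------------------------------------
  disp <- dplyr::bind_rows(kid_streams$dispensings,
                           dplyr::bind_rows(mom_disp, bc_disp) |>
                             dplyr::mutate(din = form$din[match(.data$atc_code, form$atc)]) |>
                             dplyr::relocate("din", .before = "atc_code"))
  truth <- dplyr::bind_rows(
    tibble::tibble(
      role = "child", person_id = kid_id, family_contract_id = fam_id[kid_fam],
      latent_class = latent, group = as.character(kid_group),
      high_medication = groups$high_medication[match(kid_id, groups$child_id)],
      high_visits = groups$high_visits[match(kid_id, groups$child_id)],
      diagnosis = groups$has_major_chronic_dx[match(kid_id, groups$child_id)],
      lp_visits = NA_real_, p_chronic = NA_real_, p_mood = NA_real_,
      p_hosp = NA_real_
    ),
    tibble::tibble(
      role = "mother", person_id = mom_id, family_contract_id = fam_id[mom_fam],
      latent_class = NA_character_, group = as.character(mom_group),
      high_medication = NA, high_visits = NA, diagnosis = NA,
      lp_visits = lp_visits, p_chronic = p_chronic, p_mood = p_mood,
      p_hosp = p_hosp
    )
  )
  new_admin_bundle(
    registry = registry,
    claims = dplyr::bind_rows(kid_streams$claims, mom_claims, preg_claims, mom_aux),
    dispensings = disp,
    hospital = dplyr::bind_rows(kid_hosp, mom_hosp, birth_hosp),
    truth = truth,
    config = config, calibration = cal
  )
}

new_admin_bundle <- function(registry, claims, dispensings, hospital, truth,
                             config = NULL, calibration = NULL) {
  b <- structure(list(registry = registry, claims = claims,
                      dispensings = dispensings, hospital = hospital,
                      truth = truth),
                 class = "admin_bundle")
  attr(b, "config") <- config
  attr(b, "calibration") <- calibration
  b
}

#' @export
print.admin_bundle <- function(x, ...) {
  cat("<admin_bundle>\n")
  for (nm in c("registry", "claims", "dispensings", "hospital", "truth"))
    cat(sprintf("  %-12s %8d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' Realised indicator prevalences of a generated bundle
#'
#' @param bundle an `admin_bundle`
#' @return tibble with the realised proportions of High Service Use,
#'   Diagnosis, Both and Neither among children
#' @export
realized_prevalences <- function(bundle) {
  g <- bundle$truth$group[bundle$truth$role == "child"]
  tibble::tibble(
    n_children = length(g),
    prev_hsu = mean(g %in% c("HSU_ONLY", "BOTH")),
    prev_dx = mean(g %in% c("DIAGNOSIS_ONLY", "BOTH")),
    prev_both = mean(g == "BOTH"),
    prev_neither = mean(g == "NEITHER")
  )
}
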