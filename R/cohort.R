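#' Link children to candidate mothers through the family contract id
#'
#' Every child aged 6-10 in the study year is paired with every registry
#' record of role `mother` sharing its family contract id. Children linked
#' to more than one mother are flagged (marital separation and family
#' dissolution can place a child on a contract with two mother records) and
#' are excluded downstream; children with no linked mother are dropped with
#' a message.
#'
#' @param registry registry tibble
#' @param study_year calendar year defining child ages
#' @return tibble of candidate links with child attributes, the linked
#'   mother's attributes, `n_mothers` and `multi_mother`
#' @export
link_children_to_mothers <- function(registry, study_year = 2006) {
  kids <- registry |>
    dplyr::filter(.data$role == "child",
                  study_year - .data$birth_year >= 6,
                  study_year - .data$birth_year <= 10) |>
    dplyr::transmute(child_id = .data$person_id,
                     family_contract_id = .data$family_contract_id,
                     child_age = study_year - .data$birth_year,
                     child_sex = .data$sex)
  mothers <- registry |>
    dplyr::filter(.data$role == "mother") |>
    dplyr::transmute(mother_id = .data$person_id,
                     family_contract_id = .data$family_contract_id,
                     mother_age = study_year - .data$birth_year,
                     income_quintile = .data$income_quintile,
                     premium_subsidy = .data$premium_subsidy)
  links <- dplyr::inner_join(kids, mothers, by = "family_contract_id",
                             relationship = "many-to-many")
  n_unlinked <- sum(!kids$child_id %in% links$child_id)
  if (n_unlinked > 0)
    message(n_unlinked, " children had no linked mother and were dropped")
  links |>
    dplyr::add_count(.data$child_id, name = "n_mothers") |>
    dplyr::mutate(multi_mother = .data$n_mothers > 1L)
}

#' Select one index child per mother by health-group severity
#'
#' Multi-mother children are removed first. When a mother is linked to two
#' or more remaining children, the child with the most severe health group
#' is retained (Both > High Service Use only > Diagnosis only > Neither);
#' equal-severity ties go to the eldest child, then the lexicographically
#' smallest child id, making the result independent of input row order.
#'
#' @param links candidate links from [link_children_to_mothers()]
#' @param groups_by_child tibble with `child_id` and `group` for every
#'   linked child
#' @return dyad tibble: one row per mother with her index child, the child's
#'   group, and family covariates
#' @export
select_index_child <- function(links, groups_by_child) {
  keep <- dplyr::filter(links, !.data$multi_mother)
  missing <- setdiff(keep$child_id, groups_by_child$child_id)
  if (length(missing))
    stop_validation(paste0("no group assignment for linked children: ",
                           paste(head(missing, 5), collapse = ", ")))
  lev <- group_levels()
  keep |>
    dplyr::left_join(dplyr::select(groups_by_child, "child_id", "group"),
                     by = "child_id") |>
    dplyr::mutate(group = factor(as.character(.data$group), levels = lev,
                                 ordered = TRUE)) |>
    dplyr::arrange(.data$mother_id, dplyr::desc(severity_rank(.data$group)),
                   dplyr::desc(.data$child_age), .data$child_id) |>
    dplyr::distinct(.data$mother_id, .keep_all = TRUE) |>
    dplyr::transmute(
      mother_id = .data$mother_id,
      child_id = .data$child_id,
      child_age = .data$child_age,
      child_sex = .data$child_sex,
      mother_age = .data$mother_age,
      income_quintile_lowest = .data$income_quintile == 1L,
      premium_subsidy = .data$premium_subsidy,
      child_group = .data$group
    ) |>
    dplyr::arrange(.data$mother_id)
}

#' Build the mother-child dyad cohort
#'
#' Convenience wrapper: [link_children_to_mothers()] then
#' [select_index_child()].
#'
#' @inheritParams link_children_to_mothers
#' @param groups_by_child classification table from [classify_children()]
#' @return dyad tibble (one row per mother)
#' @export
build_dyads <- function(registry, groups_by_child, study_year = 2006) {
  links <- link_children_to_mothers(registry, study_year)
  select_index_child(links, groups_by_child)
}

#' Cohort characteristics across the three child groupings
#'
#' Mirrors the structure of a family/maternal/child characteristics table:
#' for each grouping column (High Service Use yes/no, Diagnosis yes/no,
#' Both/Neither) it reports n, %, mean (sd) maternal age, % living in the
#' lowest income quintile, % receiving a premium subsidy, mean (sd) child
#' age and % male children.
#'
#' @param dyads dyad tibble from [build_dyads()]
#' @return tibble with one row per grouping column
#' @export
cohort_characteristics <- function(dyads) {
  if (!nrow(dyads)) stop_validation("`dyads` is empty")
  total <- nrow(dyads)
  cols <- grouping_columns(dyads)
  purrr::imap_dfr(cols, function(idx, label) {
    d <- dyads[idx, , drop = FALSE]
    n <- nrow(d)
    tibble::tibble(
      grouping = label,
      n = n,
      pct_of_cohort = 100 * n / total,
      mother_age_mean = if (n) mean(d$mother_age) else NA_real_,
      mother_age_sd = if (n > 1) stats::sd(d$mother_age) else NA_real_,
      pct_lowest_income = if (n) 100 * mean(d$income_quintile_lowest) else NA_real_,
      pct_premium_subsidy = if (n) 100 * mean(d$premium_subsidy) else NA_real_,
      child_age_mean = if (n) mean(d$child_age) else NA_real_,
      child_age_sd = if (n > 1) stats::sd(d$child_age) else NA_real_,
      pct_male = if (n) 100 * mean(d$child_sex == "M") else NA_real_
    )
  })
}

# the six analysis columns: each a logical index into the dyads
grouping_columns <- function(dyads) {
  g <- as.character(dyads$child_group)
  hsu <- g %in% c("HSU_ONLY", "BOTH")
  dx <- g %in% c("DIAGNOSIS_ONLY", "BOTH")
  list(
    hsu_yes = which(hsu), hsu_no = which(!hsu),
    dx_yes = which(dx), dx_no = which(!dx),
    both = which(g == "BOTH"), neither = which(g == "NEITHER")
  )
}
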