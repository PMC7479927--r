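test_that("children link to mothers through the family contract id", {
  reg <- toy_registry()
  links <- link_children_to_mothers(reg, 2006)
  # C1: one mother; C2/C3: one mother; C4 sits on a two-mother contract
  expect_identical(sort(unique(links$child_id)), c("C1", "C2", "C3", "C4"))
  expect_identical(links$n_mothers[links$child_id == "C4"], c(2L, 2L))
  expect_true(all(links$multi_mother[links$child_id == "C4"]))
  expect_false(any(links$multi_mother[links$child_id != "C4"]))
})

test_that("a childless registry yields an empty link set", {
  reg <- toy_registry()[toy_registry()$role == "mother", ]
  expect_identical(nrow(link_children_to_mothers(reg, 2006)), 0L)
})

test_that("motherless children are dropped with a message", {
  reg <- toy_registry()
  reg <- reg[!(reg$person_id %in% c("M2")), ]
  expect_message(link_children_to_mothers(reg, 2006), "no linked mother")
})

test_that("index child selection keeps the most severe child per mother", {
  reg <- toy_registry()
  links <- link_children_to_mothers(reg, 2006)
  groups <- tibble::tibble(
    child_id = c("C1", "C2", "C3", "C4"),
    group = c("NEITHER", "NEITHER", "HSU_ONLY", "BOTH"))
  dyads <- select_index_child(links, groups)
  # multi-mother child C4 excluded entirely; M3/M4 have no dyad
  expect_identical(sort(dyads$mother_id), c("M1", "M2"))
  # M2 keeps the HSU_ONLY child over the NEITHER sibling
  expect_identical(dyads$child_id[dyads$mother_id == "M2"], "C3")
  expect_identical(as.character(dyads$child_group[dyads$mother_id == "M2"]),
                   "HSU_ONLY")
})

test_that("equal-severity ties go to the eldest child, then the smallest id", {
  reg <- tibble::tibble(
    person_id = c("M1", "Cy", "Cx", "Cz"),
    family_contract_id = "F1",
    role = c("mother", "child", "child", "child"),
    sex = c("F", "M", "F", "M"),
    birth_year = c(1970, 1999, 1997, 1997),   # ages 7, 9, 9
    income_quintile = 3L, premium_subsidy = FALSE, year = 2006L)
  links <- link_children_to_mothers(reg, 2006)
  groups <- tibble::tibble(child_id = c("Cy", "Cx", "Cz"), group = "BOTH")
  dyads <- select_index_child(links, groups)
  expect_identical(nrow(dyads), 1L)
  # the two nine-year-olds beat the seven-year-old; Cx < Cz lexicographically
  expect_identical(dyads$child_id, "Cx")
  expect_identical(dyads$child_age, 9)
})

test_that("selection is invariant to input row order and idempotent", {
  b <- shared_bundle()
  groups <- classify_children(b$registry, b$claims, b$dispensings, b$hospital,
                              indicator_config(), 2006)
  links <- link_children_to_mothers(b$registry, 2006)
  d1 <- select_index_child(links, groups)
  set.seed(99)
  d2 <- select_index_child(links[sample(nrow(links)), ],
                           groups[sample(nrow(groups)), ])
  expect_identical(d1, d2)
  expect_identical(anyDuplicated(d1$mother_id), 0L)
  # re-selecting from the surviving links reproduces the same dyads
  surviving <- links[links$child_id %in% d1$child_id, ]
  expect_identical(select_index_child(surviving, groups), d1)
})

test_that("a linked child without a group assignment is a precondition error", {
  reg <- toy_registry()
  links <- link_children_to_mothers(reg, 2006)
  expect_error(select_index_child(links, tibble::tibble(child_id = "C1",
                                                        group = "NEITHER")),
               class = "dyadhealth_validation_error")
})

test_that("the dyad groups partition the cohort", {
  b <- shared_bundle()
  groups <- classify_children(b$registry, b$claims, b$dispensings, b$hospital,
                              indicator_config(), 2006)
  dyads <- build_dyads(b$registry, groups, 2006)
  ch <- cohort_characteristics(dyads)
  n <- function(g) ch$n[ch$grouping == g]
  counts <- table(factor(as.character(dyads$child_group), group_levels()))
  expect_identical(n("hsu_yes"), sum(counts[c("HSU_ONLY", "BOTH")]) |> as.integer())
  expect_identical(n("dx_yes"), sum(counts[c("DIAGNOSIS_ONLY", "BOTH")]) |> as.integer())
  expect_identical(n("both"), as.integer(counts[["BOTH"]]))
  expect_identical(n("neither"), as.integer(counts[["NEITHER"]]))
  expect_identical(n("hsu_yes") + n("hsu_no"), nrow(dyads))
})

test_that("cohort characteristics are exact on a hand-computable cohort", {
  dyads <- tibble::tibble(
    mother_id = c("M1", "M2"), child_id = c("C1", "C2"),
    child_age = c(6, 10), child_sex = c("M", "F"),
    mother_age = c(30, 40),
    income_quintile_lowest = c(TRUE, FALSE),
    premium_subsidy = c(TRUE, TRUE),
    child_group = factor(c("HSU_ONLY", "NEITHER"), group_levels(), ordered = TRUE))
  ch <- cohort_characteristics(dyads)
  hsu <- ch[ch$grouping == "hsu_yes", ]
  expect_identical(hsu$n, 1L)
  expect_equal(hsu$mother_age_mean, 30)
  expect_equal(hsu$pct_lowest_income, 100)
  expect_equal(hsu$pct_male, 100)
  expect_equal(ch$child_age_mean[ch$grouping == "hsu_no"], 10)
  expect_equal(ch$pct_of_cohort[ch$grouping == "neither"], 50)
})

test_that("an all-Neither cohort reports an empty HSU column", {
  dyads <- tibble::tibble(
    mother_id = c("M1", "M2"), child_id = c("C1", "C2"),
    child_age = c(7, 9), child_sex = c("M", "F"), mother_age = c(35, 37),
    income_quintile_lowest = FALSE, premium_subsidy = FALSE,
    child_group = factor("NEITHER", group_levels(), ordered = TRUE))
  ch <- cohort_characteristics(dyads)
  hsu <- ch[ch$grouping == "hsu_yes", ]
  expect_identical(hsu$n, 0L)
  expect_true(is.na(hsu$mother_age_mean))
  expect_error(cohort_characteristics(dyads[0, ]),
               class = "dyadhealth_validation_error")
})

test_that("morbid children are more often male in the generated cohort", {
  b <- shared_bundle()
  groups <- classify_children(b$registry, b$claims, b$dispensings, b$hospital,
                              indicator_config(), 2006)
  dyads <- build_dyads(b$registry, groups, 2006)
  ch <- cohort_characteristics(dyads)
  expect_gt(ch$pct_male[ch$grouping == "hsu_yes"],
            ch$pct_male[ch$grouping == "hsu_no"])
})
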