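bundle_schemas <- function() {
  list(
    registry = readr::cols(
      person_id = "c", family_contract_id = "c", role = "c", sex = "c",
      birth_year = "i", income_quintile = "i", premium_subsidy = "l", year = "i"),
    claims = readr::cols(
      person_id = "c", service_date = readr::col_date(), service_class = "c",
      specialty_code = "c", icd9_code = "c", pregnancy_related = "l"),
    dispensings = readr::cols(
      person_id = "c", fill_date = readr::col_date(), days_supplied = "i",
      din = "c", atc_code = "c", is_birth_control = "l"),
    hospital = readr::cols(
      person_id = "c", admit_date = readr::col_date(),
      discharge_date = readr::col_date(), icd_codes = "c", birth_related = "l"),
    truth = readr::cols(
      role = "c", person_id = "c", family_contract_id = "c",
      latent_class = "c", group = "c", high_medication = "l",
      high_visits = "l", diagnosis = "l", lp_visits = "d", p_chronic = "d",
      p_mood = "d", p_hosp = "d")
  )
}

#' Write an administrative bundle to a directory of CSV files
#'
#' Emits `registry.csv`, `claims.csv`, `dispensings.csv`, `hospital.csv` and
#' `truth.csv` (RFC 4180, ISO-8601 dates). The round trip through
#' [read_bundle()] reproduces all records exactly.
#'
#' @param bundle an `admin_bundle`
#' @param directory output directory (created if missing)
#' @return the file paths, invisibly
#' @export
write_bundle <- function(bundle, directory) {
  stopifnot(inherits(bundle, "admin_bundle"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(bundle_schemas()), function(nm) {
    p <- file.path(directory, paste0(nm, ".csv"))
    readr::write_csv(bundle[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Read an administrative bundle from a directory of CSV files
#'
#' Validates each stream against its schema: parse failures, negative
#' supplies, discharge-before-admit stays and event persons missing from the
#' registry raise a validation error listing the offending rows.
#'
#' @param directory directory written by [write_bundle()] (or hand-built
#'   files with the same names)
#' @return an `admin_bundle`
#' @export
read_bundle <- function(directory) {
  schemas <- bundle_schemas()
  tabs <- lapply(names(schemas), function(nm) {
    p <- file.path(directory, paste0(nm, ".csv"))
    if (!file.exists(p)) stop_validation(paste0("missing bundle file: ", p))
    x <- suppressWarnings(
      readr::read_csv(p, col_types = schemas[[nm]], progress = FALSE))
    probs <- readr::problems(x)
    if (nrow(probs))
      stop_validation(paste0(
        nm, ".csv failed schema validation at rows ",
        paste(head(unique(probs$row), 10), collapse = ", "),
        " (", head(probs$expected, 1)[[1]], " expected)"))
    x
  })
  names(tabs) <- names(schemas)
  b <- new_admin_bundle(tabs$registry, tabs$claims, tabs$dispensings,
                        tabs$hospital, tabs$truth)
  validate_bundle(b)
}

#' Validate an administrative bundle's cross-stream invariants
#'
#' @param bundle an `admin_bundle`
#' @return the bundle, invisibly, or a validation error
#' @export
validate_bundle <- function(bundle) {
  bad_rows <- function(cond) paste(head(which(cond), 10), collapse = ", ")
  d <- bundle$dispensings
  if (nrow(d) && any(d$days_supplied < 1, na.rm = TRUE))
    stop_validation(paste0("dispensings with days_supplied < 1 at rows ",
                           bad_rows(d$days_supplied < 1)))
  h <- bundle$hospital
  if (nrow(h) && any(h$discharge_date < h$admit_date, na.rm = TRUE))
    stop_validation(paste0("hospital stays with discharge before admit at rows ",
                           bad_rows(h$discharge_date < h$admit_date)))
  known <- bundle$registry$person_id
  for (nm in c("claims", "dispensings", "hospital")) {
    miss <- !bundle[[nm]]$person_id %in% known
    if (any(miss))
      stop_validation(paste0(nm, " reference persons absent from the registry at rows ",
                             bad_rows(miss)))
  }
  for (nm in names(bundle_schemas())) {
    if (anyNA(bundle[[nm]]$person_id))
      stop_validation(paste0(nm, " has missing person_id values"))
  }
  invisible(bundle)
}

#' An empty administrative bundle (header-only tables)
#'
#' @return an `admin_bundle` with zero-row, correctly-typed tables
#' @export
empty_bundle <- function() {
  new_admin_bundle(
    registry = tibble::tibble(person_id = character(), family_contract_id = character(),
                              role = character(), sex = character(),
                              birth_year = integer(), income_quintile = integer(),
                              premium_subsidy = logical(), year = integer()),
    claims = tibble::tibble(person_id = character(), service_date = as.Date(character()),
                            service_class = character(), specialty_code = character(),
                            icd9_code = character(), pregnancy_related = logical()),
    dispensings = tibble::tibble(person_id = character(), fill_date = as.Date(character()),
                                 days_supplied = integer(), din = character(),
                                 atc_code = character(), is_birth_control = logical()),
    hospital = tibble::tibble(person_id = character(), admit_date = as.Date(character()),
                              discharge_date = as.Date(character()),
                              icd_codes = character(), birth_related = logical()),
    truth = tibble::tibble(role = character(), person_id = character(),
                           family_contract_id = character(), latent_class = character(),
                           group = character(), high_medication = logical(),
                           high_visits = logical(), diagnosis = logical(),
                           lp_visits = double(), p_chronic = double(),
                           p_mood = double(), p_hosp = double())
  )
}
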