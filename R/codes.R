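#' Illustrative diagnosis-to-ADG mapping (synthetic)
#'
#' The Johns Hopkins ACG case-mix system assigns ICD diagnosis codes to 32
#' Aggregated Diagnosis Groups (ADGs) classified by persistence, stability and
#' severity; a subset of twelve is considered major and/or chronic for
#' children. The real grouper is proprietary, so this package ships a small
#' synthetic mapping adequate for the synthetic code universe, and accepts a
#' user-supplied two-column mapping (`code`, `adg`) for real data.
#'
#' Codes are matched by string prefix on dot-stripped ICD-9 codes: a claim
#' code matches a map entry when it starts with the entry's `code`.
#'
#' @return a tibble with columns `code` (ICD-9 prefix) and `adg` (integer id)
#' @seealso [default_major_chronic_adgs()]
#' @export
default_adg_map <- function() {
  tibble::tribble(
    ~code,  ~adg,
    # major and/or chronic conditions
    "493",  11L,  # asthma
    "250",  12L,  # diabetes mellitus
    "345",  13L,  # epilepsy
    "343",  14L,  # cerebral palsy
    "277",  15L,  # cystic fibrosis & metabolic
    "282",  16L,  # hereditary anemias
    "299",  17L,  # pervasive developmental disorders
    "714",  18L,  # inflammatory arthropathies
    "555",  19L,  # inflammatory bowel disease
    "204",  20L,  # leukemia
    "359",  21L,  # muscular dystrophies
    "758",  22L,  # chromosomal anomalies
    # time-limited / minor / likely-to-recur conditions
    "460",   1L,  # acute nasopharyngitis
    "465",   1L,  # acute URI
    "382",   2L,  # otitis media
    "079",   3L,  # viral infection
    "558",   4L,  # gastroenteritis
    "919",   5L,  # superficial injury
    "708",   6L,  # urticaria
    "692",   6L,  # contact dermatitis
    "786",   7L,  # respiratory symptoms
    "780",   7L,  # general symptoms
    "V20",   8L,  # well-child visit
    "E88",   9L   # accidental fall
  )
}

#' Default set of major and/or chronic ADG ids (synthetic)
#'
#' Twelve ids, mirroring the size of the major/chronic subset used for
#' children aged 0-17; the ids index the synthetic [default_adg_map()], not
#' the licensed grouper.
#'
#' @return integer vector of ADG ids
#' @export
default_major_chronic_adgs <- function() 11:22

#' Default maternal chronic-condition ICD-9 code lists
#'
#' Named lists of ICD-9 prefixes (dot-stripped, string-prefix semantics).
#' These are illustrative stand-ins for unpublished administrative
#' definitions and should be replaced for real analyses. The mood/anxiety
#' list covers depressive, anxiety and adjustment disorders.
#'
#' @return named list of character vectors of ICD-9 prefixes
#' @export
default_condition_codesets <- function() {
  list(
    mood_anxiety  = c("296", "300", "309", "311"),
    arthritis     = c("714", "715"),
    asthma        = c("493"),
    diabetes      = c("250"),
    heart_disease = c("410", "411", "412", "413", "414", "428"),
    hypertension  = c("401", "402"),
    migraine      = c("346"),
    thyroid       = c("244")
  )
}

#' Default pregnancy/birth-related ICD-9 exclusion prefixes
#'
#' Claims with these diagnosis prefixes (or a pregnancy flag) are removed
#' from maternal visit counts: supervision of pregnancy (V22), outcome of
#' delivery (V27) and the 630-679 complications-of-pregnancy block.
#'
#' @return character vector of ICD-9 prefixes
#' @export
default_pregnancy_codes <- function() c("V22", "V27", as.character(630:679))

# ATC prefix defaults for the medication-class outcome flags
default_pain_atc <- function() c("N02", "M01A")
default_insomnia_atc <- function() c("N05C")
default_birth_control_atc <- function() c("G03A")

# Synthetic drug formulary: 7-character ATC codes with a stable DIN each.
# Weights steer which classes each latent group tends to receive.
atc_formulary <- function() {
  tibble::tibble(
    atc = c("N02BE01", "N02BA01", "M01AE01", "N05CF01", "N05CD02", "N06AB04",
            "A10BA02", "C09AA05", "R03AC02", "R03BA02", "J01CA04", "A02BC01",
            "C10AA01", "H03AA01", "R06AX13", "D07AC01", "G03AA07", "N03AX09",
            "N06BA04", "A10AB01"),
    din = sprintf("%08d", 10000019 + 13 * seq_len(20))
  )
}
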