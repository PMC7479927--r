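#' The four-level non-categorical child health grouping
#'
#' Children are classified by two indicators — High Service Use (elevated
#' medication-days coverage or elevated physician visits) and Diagnosis of a
#' major and/or chronic condition — into four groups ordered by severity:
#' Neither < Diagnosis only < High Service Use only < Both.
#'
#' @return character vector of group levels in increasing severity order
#' @export
group_levels <- function() c("NEITHER", "DIAGNOSIS_ONLY", "HSU_ONLY", "BOTH")

#' @rdname group_levels
#' @param group a vector of group labels or a `child_group` factor
#' @return integer severity rank, 0 (Neither) .. 3 (Both)
#' @export
severity_rank <- function(group) {
  m <- match(as.character(group), group_levels())
  if (anyNA(m)) stop_validation("unknown child health group label")
  m - 1L
}

#' Combine the two indicator flags into the four-level group
#'
#' @param high_service_use,has_major_chronic_dx logical vectors (recycled)
#' @return an ordered factor over [group_levels()]
#' @export
assign_group <- function(high_service_use, has_major_chronic_dx) {
  if (!is.logical(high_service_use) || !is.logical(has_major_chronic_dx))
    stop_validation("indicator flags must be logical")
  n <- max(length(high_service_use), length(has_major_chronic_dx))
  hsu <- rep_len(high_service_use, n)
  dx <- rep_len(has_major_chronic_dx, n)
  lev <- group_levels()
  out <- ifelse(hsu & dx, lev[4], ifelse(hsu, lev[3], ifelse(dx, lev[2], lev[1])))
  out[is.na(hsu) | is.na(dx)] <- NA
  factor(out, levels = lev, ordered = TRUE)
}
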