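#' Condition-string rules for head and neck cancer
#'
#' A condition name counts as a neoplasm if its lower-cased text contains at
#' least one of the six stems "neopl", "cancer", "malignan", "tumor",
#' "carcino", "onco". It counts as an HNC condition if it is a neoplasm AND
#' contains one of the head-neck region strings ("head", "neck", "mouth",
#' "oral cavity", "pharynx", "larynx", "nose", "paranasal", "salivary",
#' "uadt", "upper aerodigestive tract", "gingiva", "otorinolar", "tongue",
#' "tonsil"). Matching is case-insensitive plain substring — the lists are
#' deliberate stems, so no word boundaries are applied.
#'
#' @param condition_name Character vector of condition names.
#' @return A logical vector.
#' @export
#' @examples
#' is_neoplasm_condition("Head and Neck Neoplasms")   # TRUE
#' is_hnc_condition("cancer of the larynx")           # TRUE
#' is_hnc_condition("laryngeal cancer")               # FALSE: no "larynx"
is_neoplasm_condition <- function(condition_name) {
  contains_any(condition_name, neoplasm_strings())
}

#' @rdname is_neoplasm_condition
#' @export
is_hnc_condition <- function(condition_name) {
  is_neoplasm_condition(condition_name) &
    contains_any(condition_name, hnc_region_strings())
}

contains_any <- function(x, strings) {
  x <- tolower(chr0(x))
  out <- rep(FALSE, length(x))
  for (s in strings) {
    out <- out | stringr::str_detect(x, stringr::fixed(s))
  }
  out
}

#' HNC-condition index of a study
#'
#' The fraction of a study's listed conditions that qualify as HNC
#' conditions; only studies whose every condition is HNC (index 1) enter the
#' cohort. An empty condition list leaves the index undefined (`NA`) and the
#' study is treated as non-HNC.
#'
#' @param conditions A character vector of condition names for one study.
#' @return A fraction in \[0, 1\], or `NA_real_` for an empty list.
#' @export
#' @examples
#' hnc_condition_index(c("cancer of the larynx", "breast cancer"))  # 0.5
hnc_condition_index <- function(conditions) {
  conditions <- conditions[!is.na(conditions) & conditions != ""]
  if (length(conditions) == 0) {
    warn("Empty condition list: HNC index undefined; study treated as non-HNC.")
    return(NA_real_)
  }
  mean(is_hnc_condition(conditions))
}

#' Select the analysis cohort
#'
#' Applies the three inclusion gates in order:
#' 1. HNC uniqueness — every listed condition (free-text conditions and MeSH
#'    browse conditions pooled) is an HNC condition (index = 1);
#' 2. status — `overall_status` is not Withdrawn or Terminated;
#' 3. eligible sex — the study is open to all sexes (single-sex studies are
#'    removed).
#'
#' Exclusions are counted hierarchically in that order, so the gate counts
#' plus the included count add up to the number of HNC studies.
#'
#' @param registry An `hnc_registry` from [load_registry()] or
#'   [generate_registry()].
#' @return An `hnc_cohort`: a tibble with one row per screened study and
#'   columns `nct_id`, `hnc_index`, `gate_hnc`, `gate_status`, `gate_sex`
#'   (logicals), `gate` (first failed gate or `"included"`) and `included`.
#'   The [cohort_report()] summary is attached as attribute `"report"` and
#'   available via [glance()].
#' @export
select_cohort <- function(registry) {
  pooled <- purrr::map2(registry$conditions, registry$browse_conditions, c)
  idx <- vapply(pooled, function(cc) {
    cc <- cc[!is.na(cc) & cc != ""]
    if (length(cc) == 0) NA_real_ else mean(is_hnc_condition(cc))
  }, 0)
  n_empty <- sum(is.na(idx))
  if (n_empty > 0) {
    warn(paste0(n_empty, " studies have no listed conditions; treated as non-HNC."))
  }
  gate_hnc <- !is.na(idx) & idx == 1
  gate_status <- !tolower(registry$overall_status) %in% c("withdrawn", "terminated")
  gate_sex <- registry$eligibility_sex == "ALL"

  gate <- dplyr::case_when(
    !gate_hnc ~ "not_hnc_unique",
    !gate_status ~ "withdrawn_terminated",
    !gate_sex ~ "single_sex",
    TRUE ~ "included"
  )
  out <- tibble::tibble(
    nct_id = registry$nct_id,
    hnc_index = idx,
    gate_hnc = gate_hnc,
    gate_status = gate_status,
    gate_sex = gate_sex,
    gate = gate,
    included = gate == "included"
  )
  report <- tibble::tibble(
    n_screened = nrow(out),
    n_hnc_unique = sum(gate_hnc),
    n_excluded_status = sum(gate == "withdrawn_terminated"),
    n_excluded_single_sex = sum(gate == "single_sex"),
    n_included = sum(out$included)
  )
  structure(out, class = c("hnc_cohort", class(out)), report = report)
}

#' Cohort selection summary
#'
#' One-row accounting of the screening flow: studies screened, HNC-unique
#' studies, exclusions per gate, and the included count. The identity
#' `n_hnc_unique = n_excluded_status + n_excluded_single_sex + n_included`
#' holds by construction of the hierarchical gates.
#'
#' @param cohort An `hnc_cohort` from [select_cohort()].
#' @return A one-row tibble.
#' @export
cohort_report <- function(cohort) {
  attr(cohort, "report")
}

#' @export
glance.hnc_cohort <- function(x, ...) cohort_report(x)

#' @export
print.hnc_cohort <- function(x, ...) {
  r <- cohort_report(x)
  cat("<HNC cohort selection: ", r$n_screened, " screened, ",
      r$n_hnc_unique, " HNC-unique, -", r$n_excluded_status,
      " withdrawn/terminated, -", r$n_excluded_single_sex,
      " single-sex, ", r$n_included, " included>\n", sep = "")
  NextMethod()
}
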