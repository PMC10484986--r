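#' Controlled vs uncontrolled classification
#'
#' A study is controlled if at least one arm (design group) is typed
#' "Experimental", "Active Comparator", "Placebo Comparator" or
#' "Sham Comparator" (case-insensitive exact label match); otherwise —
#' arms typed "No Intervention"/"Other", or no arms at all — it is
#' uncontrolled. Unknown arm-type labels do not qualify and are warned
#' about.
#'
#' @param arms A tibble with column `arm_type` (one study), or a list of
#'   such tibbles.
#' @return `"controlled"` or `"uncontrolled"` (vectorised over a list).
#' @export
#' @examples
#' classify_control(tibble::tibble(title = "A", arm_type = "Experimental"))
classify_control <- function(arms) {
  if (is.data.frame(arms)) arms <- list(arms)
  qualifying <- c("experimental", "active comparator", "placebo comparator",
                  "sham comparator")
  known <- c(qualifying, "no intervention", "other", "")
  types <- lapply(arms, function(a) tolower(trimws(chr0(a$arm_type))))
  unknown <- setdiff(unique(unlist(types)), known)
  if (length(unknown) > 0) {
    warn(paste0("Unknown arm type(s) treated as non-qualifying: ",
                paste(unknown, collapse = ", ")))
  }
  out <- vapply(types, function(tt) any(tt %in% qualifying), TRUE)
  ifelse(out, "controlled", "uncontrolled")
}

#' Randomized vs non-randomized classification
#'
#' Based on the design allocation field: exactly "Randomized"
#' (case-insensitive) is randomized; anything else, including an absent
#' allocation (observational studies), is non-randomized.
#'
#' @param allocation Character vector of allocation labels (`NA` allowed).
#' @return Character vector with levels `randomized`, `non_randomized`.
#' @export
classify_randomization <- function(allocation) {
  ifelse(!is.na(allocation) & tolower(trimws(allocation)) == "randomized",
         "randomized", "non_randomized")
}

#' Phase grouping
#'
#' Collapses the registry phase vocabulary into the five reporting groups:
#' Early Phase 1 and Phase 1 -> `early_phase1_phase1`; Phase 1/Phase 2 ->
#' `phase1_phase2`; Phase 2, Phase 2/Phase 3 and Phase 3 -> `phase2_phase3`;
#' Phase 4 -> `phase4`; N/A or missing -> `not_applicable`. Observational
#' studies are always `not_applicable`, and unknown phase labels fall there
#' with a warning.
#'
#' @param phase_raw Character vector of registry phase labels.
#' @param study_type Character vector of study types (parallel).
#' @return Character vector of phase groups.
#' @export
phase_group <- function(phase_raw, study_type = "Interventional") {
  key <- tolower(trimws(chr0(phase_raw)))
  map <- c("early phase 1" = "early_phase1_phase1",
           "phase 1" = "early_phase1_phase1",
           "phase 1/phase 2" = "phase1_phase2",
           "phase 2" = "phase2_phase3",
           "phase 2/phase 3" = "phase2_phase3",
           "phase 3" = "phase2_phase3",
           "phase 4" = "phase4",
           "n/a" = "not_applicable",
           "na" = "not_applicable")
  out <- unname(map[key])
  out[key == ""] <- "not_applicable"
  if (anyNA(out)) {
    warn(paste0("Unknown phase label(s) mapped to not_applicable: ",
                paste(unique(phase_raw[is.na(out)]), collapse = ", ")))
    out[is.na(out)] <- "not_applicable"
  }
  obs <- classify_study_type(study_type) == "observational"
  out[obs] <- "not_applicable"
  out
}

#' Enrolment grouping
#'
#' Dichotomises the planned/actual sample size at 100 subjects; missing
#' values are pooled with the small group.
#'
#' @param enrollment Integer vector of subject counts (`NA` allowed).
#' @return Character vector with levels `le_100`, `gt_100`.
#' @export
enrolment_group <- function(enrollment) {
  ifelse(!is.na(enrollment) & enrollment > 100, "gt_100", "le_100")
}

#' Recruitment-status grouping
#'
#' Collapses the retained overall-status vocabulary (Withdrawn/Terminated
#' studies are excluded upstream) into five groups: Active-not-recruiting,
#' Completed, Not-yet-recruiting, Recruiting merged with Enrolling by
#' invitation, and Unknown status merged with Suspended. Unrecognised
#' labels fall into the last group with a warning.
#'
#' @param overall_status Character vector of status labels.
#' @return Character vector of status groups.
#' @export
status_group <- function(overall_status) {
  key <- tolower(trimws(chr0(overall_status)))
  map <- c("active, not recruiting" = "active_not_recruiting",
           "completed" = "completed",
           "not yet recruiting" = "not_yet_recruiting",
           "recruiting" = "recruiting_or_invitation",
           "enrolling by invitation" = "recruiting_or_invitation",
           "unknown status" = "unknown_or_suspended",
           "suspended" = "unknown_or_suspended")
  out <- unname(map[key])
  if (anyNA(out)) {
    warn(paste0("Unrecognised status label(s) grouped as unknown_or_suspended: ",
                paste(unique(overall_status[is.na(out)]), collapse = ", ")))
    out[is.na(out)] <- "unknown_or_suspended"
  }
  out
}

classify_study_type <- function(study_type) {
  key <- tolower(trimws(chr0(study_type)))
  ifelse(grepl("^observational", key), "observational", "interventional")
}

#' Derive all stratification labels for the cohort
#'
#' Joins the mention tags with the design-derived labels: study type
#' (patient registries merge into observational), controlled/uncontrolled,
#' randomization, phase group, enrolment group, status group and submission
#' year.
#'
#' @param registry An `hnc_registry`.
#' @param tags A tibble from [tag_mentions()]; its `nct_id` set defines the
#'   studies labelled.
#' @return A tibble with one row per study and one column per label:
#'   `nct_id`, `sg_category`, `hpv_mention`, `subsite_group`, `study_type`,
#'   `control_class`, `randomization`, `phase_group`, `enrolment_group`,
#'   `status_group`, `submission_year`.
#' @export
derive_labels <- function(registry, tags) {
  registry <- registry[match(tags$nct_id, registry$nct_id), ]
  if (anyNA(registry$nct_id)) {
    abort("Some tagged studies are missing from the registry.")
  }
  st <- classify_study_type(registry$study_type)
  tibble::tibble(
    nct_id = tags$nct_id,
    sg_category = tags$sg_category,
    hpv_mention = tags$hpv_mention,
    subsite_group = tags$subsite_group,
    study_type = st,
    control_class = classify_control(registry$arms),
    randomization = classify_randomization(registry$allocation),
    phase_group = phase_group(registry$phase_raw, registry$study_type),
    enrolment_group = enrolment_group(registry$enrollment),
    status_group = status_group(registry$overall_status),
    submission_year = as.integer(format(registry$first_submitted, "%Y"))
  )
}
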