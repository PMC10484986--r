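#' Parameters for the synthetic registry generator
#'
#' Defaults emulate the composition of the real HNC cohort: 1952 screened
#' studies of which ~14% withdrawn/terminated and ~0.4% single-sex; 84%
#' interventional, of which ~86% controlled and ~38% randomized; section
#' injection rates tuned so that ~5% of studies carry an S/G term in an
#' analysis section and ~59% in eligibility text (giving the ~5/56/38
#' analytical / recruitment-only / no-mention split); 17% HPV mention; 34%
#' HPV-relevant subsites; lognormal enrolment with ~70% at 100 subjects or
#' fewer (2% missing); phase and status mixes matching the reported
#' marginal frequencies; submissions over 1999-2022 with increasing yearly
#' weight.
#'
#' @param n_studies Number of studies to generate.
#' @param p_non_hnc Probability a study fails the HNC-uniqueness gate
#'   (either purely non-HNC conditions or a mixed condition list).
#' @param p_interventional Probability of an interventional study.
#' @param p_controlled_given_interventional,p_randomized_given_interventional
#'   Design probabilities for interventional studies.
#' @param sg_section_probs Named per-section probabilities of injecting an
#'   S/G term (names from [analysis_sections()] / [eligibility_sections()]).
#' @param p_hpv Probability of planting an HPV phrase.
#' @param p_subsite_A Probability an HNC study's conditions name an
#'   HPV-relevant subsite.
#' @param enrolment_meanlog,enrolment_sdlog,p_enrolment_missing Lognormal
#'   enrolment law (rounded to integer, minimum 1) and missingness rate.
#' @param phase_weights Named multinomial over the registry phase
#'   vocabulary (interventional studies).
#' @param status_weights Named multinomial over the registry status
#'   vocabulary, including Withdrawn/Terminated.
#' @param sex_weights Named multinomial over `c("All", "Male", "Female")`.
#' @param year_range First and last submission year.
#' @param year_weights Per-year weights; default increases as (index)^1.5.
#' @param decoy_rate Probability of inserting a boundary-trap decoy word
#'   ("human", "treatment", "management", ...) into each free-text section.
#' @param seed Integer seed driving every draw.
#' @return A `synth_params` list, validated.
#' @export
synth_params <- function(
    n_studies = 1952,
    p_non_hnc = 0.05,
    p_interventional = 0.84,
    p_controlled_given_interventional = 0.86,
    p_randomized_given_interventional = 0.38,
    sg_section_probs = c(
      brief_title = 0.004, official_title = 0.008, brief_summary = 0.012,
      detailed_description = 0.015, outcomes = 0.012, design_groups = 0.004,
      interventions = 0.004,
      eligibility_population = 0.15, eligibility_criteria = 0.52),
    p_hpv = 0.17,
    p_subsite_A = 0.34,
    enrolment_meanlog = log(50), enrolment_sdlog = 1.4,
    p_enrolment_missing = 0.021,
    phase_weights = c(
      "Early Phase 1" = 0.04, "Phase 1" = 0.09, "Phase 1/Phase 2" = 0.07,
      "Phase 2" = 0.35, "Phase 2/Phase 3" = 0.05, "Phase 3" = 0.18,
      "Phase 4" = 0.01, "N/A" = 0.21),
    status_weights = c(
      "Active, not recruiting" = 0.090, "Completed" = 0.370,
      "Not yet recruiting" = 0.056, "Recruiting" = 0.190,
      "Enrolling by invitation" = 0.017, "Unknown status" = 0.120,
      "Suspended" = 0.018, "Withdrawn" = 0.099, "Terminated" = 0.040),
    sex_weights = c(All = 0.996, Male = 0.0035, Female = 0.0005),
    year_range = c(1999, 2022),
    year_weights = NULL,
    decoy_rate = 0.3,
    seed = 1L) {
  p <- as.list(environment())
  probs <- c(p$p_non_hnc, p$p_interventional,
             p$p_controlled_given_interventional,
             p$p_randomized_given_interventional, p$sg_section_probs,
             p$p_hpv, p$p_subsite_A, p$p_enrolment_missing, p$decoy_rate)
  if (any(probs < 0 | probs > 1)) abort("All probabilities must lie in [0, 1].")
  for (w in c("phase_weights", "status_weights", "sex_weights")) {
    if (any(p[[w]] < 0)) abort(paste0(w, " must be nonnegative."))
    p[[w]] <- p[[w]] / sum(p[[w]])
  }
  secs <- c(analysis_sections(), eligibility_sections())
  missing_secs <- setdiff(secs, names(p$sg_section_probs))
  if (length(missing_secs) > 0) {
    p$sg_section_probs[missing_secs] <- 0
  }
  if (is.null(p$year_weights)) {
    n_yr <- diff(p$year_range) + 1
    p$year_weights <- (seq_len(n_yr))^1.5
  }
  p$year_weights <- p$year_weights / sum(p$year_weights)
  p$seed <- as.integer(seed)
  structure(p, class = "synth_params")
}

# vocabulary for condition construction; A-pool names contain an
# HPV-relevant subsite substring, B-pool names do not (but all match the
# HNC region list), non-HNC names match neither rule set
synth_vocab <- function() {
  list(
    region_a = c("larynx", "oropharynx", "tonsil", "oral cavity",
                 "base of tongue", "hypopharynx"),
    region_b = c("head and neck", "paranasal sinus", "salivary gland",
                 "tongue", "mouth", "gingiva"),
    neoplasm = c("cancer", "carcinoma", "neoplasm", "tumor",
                 "malignant neoplasm"),
    non_hnc = c("breast cancer", "hypertension", "diabetes mellitus",
                "lung cancer", "chronic kidney disease"),
    decoys = c("human", "treatment", "management", "amendment", "germane",
               "acumen"),
    sg_surface = c(sex = "sex", gender = "gender", woman = "woman",
                   women = "women", man = "man", men = "men",
                   female = "female", females = "females", male = "male",
                   males = "males", girl = "girl", girls = "girls",
                   boy = "boy", boys = "boys", pregnan = "pregnancy",
                   transg = "transgender"),
    hpv_phrases = c("HPV", "human papillomavirus", "HPV16",
                    "papillomavirus, human")
  )
}

sample_w <- function(x, weights = NULL, n = 1) {
  x[sample.int(length(x), n, replace = TRUE, prob = weights)]
}

#' Generate a seeded synthetic registry with planted truth
#'
#' Builds an AACT-shaped registry whose free-text sections are template
#' sentences with controlled insertion slots: S/G terms are injected into
#' chosen sections, HPV phrases planted at a configurable rate, condition
#' names assembled from region + neoplasm templates so the HNC-condition
#' index is controllable, and a configurable fraction of non-HNC,
#' withdrawn/terminated and single-sex studies exercises every exclusion
#' gate. Decoy words carrying embedded-but-not-whole-word lexicon
#' substrings ("human", "treatment") probe the word-boundary rule.
#'
#' Deterministic given the seed: each study draws from a substream derived
#' from (seed, study index), so insertion order never changes draws.
#'
#' @param params A [synth_params()].
#' @return A list with `registry` (an `hnc_registry`) and `truth` (a tibble
#'   of planted gate outcomes and labels per study).
#' @export
generate_registry <- function(params = synth_params()) {
  if (!inherits(params, "synth_params")) abort("`params` must come from synth_params().")
  v <- synth_vocab()
  n <- params$n_studies
  ids <- sprintf("NCT%08d", seq_len(n))
  years <- seq(params$year_range[1], params$year_range[2])

  one_study <- function(i) {
    study_seed <- (params$seed * 7919L + i * 104729L) %% 2147483647L
    withr::with_seed(study_seed, {
      interventional <- stats::runif(1) < params$p_interventional
      study_type <- if (interventional) "Interventional" else {
        sample_w(c("Observational", "Observational [Patient Registry]"))
      }
      non_hnc <- stats::runif(1) < params$p_non_hnc
      subsite_a <- stats::runif(1) < params$p_subsite_A
      region_pool <- if (subsite_a) v$region_a else v$region_b
      n_cond <- sample.int(3, 1)
      hnc_conds <- paste(sample_w(region_pool, n = n_cond, weights = NULL),
                         sample_w(v$neoplasm, n = n_cond))
      mixed <- FALSE
      if (non_hnc) {
        if (stats::runif(1) < 0.5) {
          conds <- sample_w(v$non_hnc, n = n_cond)         # purely non-HNC
        } else {
          conds <- c(hnc_conds[1], sample_w(v$non_hnc, n = 1))  # index < 1
          mixed <- TRUE
        }
      } else {
        conds <- hnc_conds
      }
      truth_subsite <- if ((!non_hnc || mixed) && subsite_a)
        "A_hpv_relevant" else "B_other"
      browse <- if (stats::runif(1) < 0.5) conds else character(0)

      status <- sample_w(names(params$status_weights), params$status_weights)
      sex <- sample_w(names(params$sex_weights), params$sex_weights)
      enrollment <- if (stats::runif(1) < params$p_enrolment_missing) {
        NA_integer_
      } else {
        max(1L, as.integer(round(stats::rlnorm(1, params$enrolment_meanlog,
                                               params$enrolment_sdlog))))
      }
      phase <- if (interventional) {
        sample_w(names(params$phase_weights), params$phase_weights)
      } else NA_character_
      controlled <- interventional &&
        stats::runif(1) < params$p_controlled_given_interventional
      randomized <- interventional &&
        stats::runif(1) < params$p_randomized_given_interventional
      allocation <- if (!interventional) NA_character_
                    else if (randomized) "Randomized" else "Non-Randomized"
      year <- sample_w(years, params$year_weights)
      first_sub <- as.Date(sprintf("%d-%02d-%02d", year,
                                   sample.int(12, 1), sample.int(28, 1)))

      if (interventional) {
        n_arms <- 1 + stats::rbinom(1, 2, 0.5)
        types <- sample_w(c("No Intervention", "Other"), n = n_arms)
        if (controlled) {
          types[1] <- sample_w(c("Experimental", "Active Comparator",
                                 "Placebo Comparator", "Sham Comparator"))
        }
        arms <- tibble::tibble(title = paste("Cohort", seq_len(n_arms)),
                               arm_type = types)
      } else {
        arms <- tibble::tibble(title = character(0), arm_type = character(0))
      }

      # free-text sections from neutral templates
      maybe_decoy <- function() {
        if (stats::runif(1) < params$decoy_rate) {
          paste0(" The ", sample_w(v$decoys),
                 " protocol follows standard clinical practice.")
        } else ""
      }
      sg_inject <- function(section) {
        stats::runif(1) < params$sg_section_probs[[section]]
      }
      sg_sentence <- function() {
        term <- sample_w(names(v$sg_surface))
        paste0(" Subgroup results will be reported by ",
               unname(v$sg_surface[term]), " of the participants.")
      }
      base <- list(
        brief_title = paste("A clinical evaluation of therapy for",
                            conds[1]),
        official_title = paste("A prospective evaluation of supportive",
                               "therapy in participants with", conds[1]),
        brief_summary = paste("This protocol evaluates supportive care",
                              "in participants with", conds[1],
                              "across multiple centers."),
        detailed_description = paste("Participants receive standard",
                                     "supportive care with scheduled",
                                     "follow-up visits over two years."),
        outcomes = "Objective response rate\nDuration of clinical benefit",
        design_groups = paste(arms$title, collapse = "\n"),
        interventions = "Supportive care delivered per local standards.",
        eligibility_population = "Adults attending the participating centers.",
        eligibility_criteria = paste("Inclusion: age 18 or older; confirmed",
                                     "diagnosis. Exclusion: prior enrolment",
                                     "in a conflicting protocol.")
      )
      sg_where <- character(0)
      for (s in names(base)) {
        if (s %in% c("outcomes", "design_groups")) next  # list-built below
        base[[s]] <- paste0(base[[s]], maybe_decoy())
        if (sg_inject(s)) {
          base[[s]] <- paste0(base[[s]], sg_sentence())
          sg_where <- c(sg_where, s)
        }
      }
      outcome_tbl <- tibble::tibble(
        measure = c("Objective response rate", "Duration of clinical benefit"),
        description = c(paste0("Proportion of participants with a confirmed",
                               " response.", maybe_decoy()),
                        "Time from response to progression.")
      )
      if (sg_inject("outcomes")) {
        outcome_tbl$description[1] <- paste0(outcome_tbl$description[1],
                                             sg_sentence())
        sg_where <- c(sg_where, "outcomes")
      }
      if (nrow(arms) > 0 && sg_inject("design_groups")) {
        term <- sample_w(names(v$sg_surface))
        arms$title[1] <- paste(arms$title[1], "-",
                               unname(v$sg_surface[term]), "stratum")
        sg_where <- c(sg_where, "design_groups")
      }
      intervention_tbl <- tibble::tibble(
        name = "Supportive care",
        description = base$interventions
      )

      hpv <- stats::runif(1) < params$p_hpv
      if (hpv) {
        phrase <- sample_w(v$hpv_phrases)
        base$brief_summary <- paste0(base$brief_summary, " Baseline ",
                                     phrase, " status will be recorded.")
      }

      truth_sg <- if (any(sg_where %in% analysis_sections())) "analytical"
                  else if (any(sg_where %in% eligibility_sections())) "recruitment_only"
                  else "no_mention"
      truth_gate <- if (non_hnc) "not_hnc_unique"
                    else if (status %in% c("Withdrawn", "Terminated")) "withdrawn_terminated"
                    else if (sex != "All") "single_sex"
                    else "included"
      phase_truth_map <- c("Early Phase 1" = "early_phase1_phase1",
                          "Phase 1" = "early_phase1_phase1",
                          "Phase 1/Phase 2" = "phase1_phase2",
                          "Phase 2" = "phase2_phase3",
                          "Phase 2/Phase 3" = "phase2_phase3",
                          "Phase 3" = "phase2_phase3",
                          "Phase 4" = "phase4",
                          "N/A" = "not_applicable")
      status_truth_map <- c("Active, not recruiting" = "active_not_recruiting",
                            "Completed" = "completed",
                            "Not yet recruiting" = "not_yet_recruiting",
                            "Recruiting" = "recruiting_or_invitation",
                            "Enrolling by invitation" = "recruiting_or_invitation",
                            "Unknown status" = "unknown_or_suspended",
                            "Suspended" = "unknown_or_suspended")

      list(
        record = tibble::tibble(
          nct_id = ids[i],
          brief_title = base$brief_title,
          official_title = base$official_title,
          brief_summary = base$brief_summary,
          detailed_description = base$detailed_description,
          eligibility_sex = toupper(sex),
          eligibility_population = base$eligibility_population,
          eligibility_criteria = base$eligibility_criteria,
          enrollment = enrollment,
          phase_raw = phase,
          overall_status = status,
          allocation = allocation,
          study_type = study_type,
          first_submitted = first_sub,
          conditions = list(conds),
          browse_conditions = list(browse),
          arms = list(arms),
          outcomes = list(outcome_tbl),
          interventions = list(intervention_tbl)
        ),
        truth = tibble::tibble(
          nct_id = ids[i],
          gate = truth_gate,
          included = truth_gate == "included",
          sg_category = truth_sg,
          hpv_mention = hpv,
          subsite_group = truth_subsite,
          study_type = if (interventional) "interventional" else "observational",
          control_class = if (controlled) "controlled" else "uncontrolled",
          randomization = if (randomized) "randomized" else "non_randomized",
          phase_group = if (!interventional) "not_applicable"
                        else unname(phase_truth_map[phase]),
          enrolment_group = if (!is.na(enrollment) && enrollment > 100)
                              "gt_100" else "le_100",
          status_group = unname(status_truth_map[status]) %||% NA_character_,
          submission_year = as.integer(year)
        )
      )
    })
  }

  parts <- lapply(seq_len(n), one_study)
  registry <- dplyr::bind_rows(lapply(parts, `[[`, "record"))
  registry <- structure(registry, class = c("hnc_registry", class(registry)),
                        snapshot_date = as.Date(sprintf(
                          "%d-12-31", params$year_range[2])))
  truth <- dplyr::bind_rows(lapply(parts, `[[`, "truth"))
  list(registry = registry, truth = truth)
}

#' Compare recovered labels with planted truth
#'
#' Per shared label, a square confusion matrix (truth x predicted) and the
#' exact agreement fraction.
#'
#' @param truth The `truth` tibble from [generate_registry()].
#' @param predicted A labels tibble (e.g. from [derive_labels()]) keyed by
#'   the same `nct_id` set.
#' @return A tibble with columns `label`, `n`, `agreement` and a
#'   list-column `confusion`.
#' @export
recovery_report <- function(truth, predicted) {
  extra_t <- setdiff(truth$nct_id, predicted$nct_id)
  extra_p <- setdiff(predicted$nct_id, truth$nct_id)
  if (length(extra_t) > 0 || length(extra_p) > 0) {
    abort(paste0(
      "nct_id sets differ. Only in truth: ",
      paste(head(extra_t, 5), collapse = ", "),
      if (length(extra_t) > 5) " ..." else "",
      "; only in predicted: ",
      paste(head(extra_p, 5), collapse = ", "),
      if (length(extra_p) > 5) " ..." else ""))
  }
  truth <- truth[match(predicted$nct_id, truth$nct_id), ]
  labels <- setdiff(intersect(names(truth), names(predicted)), "nct_id")
  rows <- lapply(labels, function(lb) {
    t_ <- as.character(truth[[lb]])
    p_ <- as.character(predicted[[lb]])
    lev <- sort(unique(c(t_, p_)))
    cm <- table(truth = factor(t_, lev), predicted = factor(p_, lev))
    tibble::tibble(label = lb, n = length(t_),
                   agreement = mean(t_ == p_), confusion = list(cm))
  })
  dplyr::bind_rows(rows)
}
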