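test_that("condition-string rules agree with a brute-force substring oracle", {
  cases <- c("Head and Neck Neoplasms", "Squamous Cell Carcinoma of the Larynx",
             "cancer of the larynx", "laryngeal cancer", "breast cancer",
             "hypertension", "", "Oropharyngeal Carcinoma", "HEAD tumor",
             "oncology follow-up of the tongue")
  neo <- c("neopl", "cancer", "malignan", "tumor", "carcino", "onco")
  reg <- c("head", "neck", "mouth", "oral cavity", "pharynx", "larynx",
           "nose", "paranasal", "salivary", "uadt",
           "upper aerodigestive tract", "gingiva", "otorinolar", "tongue",
           "tonsil")
  oracle_neo <- vapply(cases, function(x)
    any(vapply(neo, match_oracle, TRUE, text = x, mode = "substring")), TRUE)
  oracle_hnc <- oracle_neo & vapply(cases, function(x)
    any(vapply(reg, match_oracle, TRUE, text = x, mode = "substring")), TRUE)
  expect_equal(unname(is_neoplasm_condition(cases)), unname(oracle_neo))
  expect_equal(unname(is_hnc_condition(cases)), unname(oracle_hnc))
  # pinned outcomes: the region list holds "larynx", not the stem "laryn"
  expect_true(is_hnc_condition("cancer of the larynx"))
  expect_false(is_hnc_condition("laryngeal cancer"))
  expect_false(is_neoplasm_condition(""))
})

test_that("the HNC-condition index is the qualifying fraction", {
  expect_equal(hnc_condition_index("cancer of the larynx"), 1.0)
  expect_equal(hnc_condition_index(c("cancer of the larynx", "breast cancer")),
               0.5)
  expect_equal(hnc_condition_index("hypertension"), 0.0)
  expect_warning(idx <- hnc_condition_index(character(0)), "undefined")
  expect_true(is.na(idx))
})

test_that("cohort gates apply hierarchically and the accounting identity holds", {
  gen <- generate_registry(synth_params(n_studies = 500, seed = 21,
                                        p_non_hnc = 0.2))
  cohort <- suppressWarnings(select_cohort(gen$registry))
  rep_ <- cohort_report(cohort)
  expect_equal(rep_$n_hnc_unique,
               rep_$n_excluded_status + rep_$n_excluded_single_sex +
                 rep_$n_included)
  expect_equal(rep_$n_screened, 500)
  # planted gate outcomes recovered exactly
  expect_equal(cohort$gate, gen$truth$gate)
  expect_true(all(cohort$gate_hnc[cohort$included] &
                    cohort$gate_status[cohort$included] &
                    cohort$gate_sex[cohort$included]))
})

test_that("single gates exclude as specified", {
  dir <- make_registry_dir(
    studies_row(c("NCT1", "NCT2", "NCT3"),
                status = c("Withdrawn", "Completed", "Completed")),
    conditions = data.frame(nct_id = c("NCT1", "NCT2", "NCT3"),
                            name = "cancer of the larynx"),
    eligibilities = data.frame(nct_id = c("NCT1", "NCT2", "NCT3"),
                               gender = c("All", "Male", "All"),
                               population = "", criteria = ""))
  cohort <- select_cohort(quiet_load(dir))
  expect_equal(cohort$gate,
               c("withdrawn_terminated", "single_sex", "included"))
})

test_that("adding a non-HNC condition removes a study from the cohort", {
  gen <- generate_registry(synth_params(n_studies = 120, seed = 9))
  reg <- gen$registry
  cohort <- suppressWarnings(select_cohort(reg))
  idx <- which(cohort$included)[1]
  reg$conditions[[idx]] <- c(reg$conditions[[idx]], "hypertension")
  cohort2 <- suppressWarnings(select_cohort(reg))
  expect_false(cohort2$included[idx])
  expect_lt(cohort2$hnc_index[idx], 1)
})

test_that("MeSH browse conditions participate in HNC matching", {
  dir <- make_registry_dir(
    studies_row("NCT1"),
    browse_conditions = data.frame(nct_id = "NCT1",
                                   mesh_term = "Head and Neck Neoplasms"),
    eligibilities = data.frame(nct_id = "NCT1", gender = "All",
                               population = "", criteria = ""))
  cohort <- select_cohort(quiet_load(dir))
  expect_true(cohort$included)
})
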