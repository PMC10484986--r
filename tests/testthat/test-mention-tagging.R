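test_that("whole-word matching respects boundaries and stems match prefixes", {
  expect_setequal(match_terms("women and men were enrolled", sg_lexicon()),
                  c("women", "men"))
  expect_length(match_terms("human papillomavirus treatment", sg_lexicon()), 0)
  expect_equal(match_terms("pregnant or breastfeeding subjects are excluded",
                           sg_lexicon()), "pregnan")
  expect_setequal(match_terms("Male-to-female differences in management",
                              sg_lexicon()), c("male", "female"))
  expect_length(match_terms("semen analysis for the acumen cohort",
                            sg_lexicon()), 0)
})

test_that("match_terms agrees with the character-scanning oracle on trap sentences", {
  vocab <- c("women", "men", "man", "management", "semen", "human",
             "treatment", "female", "females", "transgender", "pregnant",
             "sex", "sextant", "boy", "boys", "amendment", "girl",
             "acumen", "hpv", "hpv16")
  lex <- sg_lexicon()
  withr::with_seed(42, {
    for (i in 1:150) {
      sentence <- paste(sample(vocab, sample(3:8, 1), replace = TRUE),
                        collapse = sample(c(" ", "-", ", ", "\n"), 1))
      got <- match_terms(sentence, lex)
      want <- unique(lex$term[vapply(seq_len(nrow(lex)), function(j) {
        match_oracle(sentence, lex$term[j], lex$mode[j])
      }, TRUE)])
      expect_setequal(got, want)
    }
  })
})

make_sections <- function(...) {
  vals <- list(...)
  out <- tibble::as_tibble(
    setNames(as.list(rep("", 10)),
             c("nct_id", analysis_sections(), eligibility_sections())))
  for (nm in names(vals)) out[[nm]] <- vals[[nm]]
  out
}

test_that("S/G classification is hierarchical: analytical dominates recruitment", {
  expect_equal(classify_sg(make_sections(outcomes = "stratified by sex")),
               "analytical")
  expect_equal(classify_sg(make_sections(
    eligibility_criteria = "pregnant subjects excluded")), "recruitment_only")
  expect_equal(classify_sg(make_sections()), "no_mention")
  # adding an analysis-section hit flips a recruitment-only study
  both <- make_sections(eligibility_criteria = "pregnant subjects excluded",
                        brief_title = "Outcomes by gender")
  expect_equal(classify_sg(both), "analytical")
  # removing eligibility text never demotes an analytical label
  only_analysis <- make_sections(brief_title = "Outcomes by gender")
  expect_equal(classify_sg(only_analysis), "analytical")
})

test_that("HPV detection covers phrases, bare HPV, and embedded variants", {
  secs <- make_sections()
  expect_true(detect_hpv(secs,
    list("HPV-Positive Oropharyngeal Squamous Cell Carcinoma")))
  expect_true(detect_hpv(make_sections(
    brief_summary = "papillomavirus, human vaccination history"), list(character(0))))
  expect_true(detect_hpv(make_sections(brief_summary = "HPV16 positive"),
                         list(character(0))))
  expect_false(detect_hpv(secs, list("cancer of the larynx")))
})

test_that("subsite grouping keys on the five HPV-relevant substrings", {
  expect_equal(assign_subsite_group("oropharyngeal carcinoma"), "A_hpv_relevant")
  expect_equal(assign_subsite_group("carcinoma of the base of tongue"),
               "A_hpv_relevant")
  expect_equal(assign_subsite_group("paranasal sinus cancer"), "B_other")
  expect_equal(assign_subsite_group(list(c("head and neck cancer",
                                           "tonsil cancer"))), "A_hpv_relevant")
})

test_that("the three categories partition the cohort", {
  gen <- generate_registry(synth_params(n_studies = 300, seed = 4))
  cohort <- suppressWarnings(select_cohort(gen$registry))
  tags <- tag_mentions(gen$registry, cohort)
  expect_equal(nrow(tags), sum(cohort$included))
  expect_setequal(unique(tags$sg_category),
                  intersect(c("analytical", "recruitment_only", "no_mention"),
                            tags$sg_category))
  expect_equal(sum(table(tags$sg_category)), nrow(tags))
  # hits recorded iff category is not no_mention
  has_hits <- vapply(tags$sg_hits, nrow, 0L) > 0
  expect_equal(tags$sg_category == "no_mention", !has_hits)
})
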