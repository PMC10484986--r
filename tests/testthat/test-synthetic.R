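test_that("generation is deterministic given the seed, regardless of call order", {
  p <- synth_params(n_studies = 80, seed = 99)
  g1 <- generate_registry(p)
  g2 <- generate_registry(p)
  expect_identical(g1$truth, g2$truth)
  expect_equal(as.data.frame(g1$registry), as.data.frame(g2$registry))
  d1 <- tempfile(); d2 <- tempfile()
  write_registry(g1$registry, d1); write_registry(g2$registry, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  g3 <- generate_registry(synth_params(n_studies = 80, seed = 100))
  expect_false(identical(as.data.frame(g1$registry), as.data.frame(g3$registry)))
})

test_that("planted extremes propagate: no injections, all-HPV", {
  secs <- c(analysis_sections(), eligibility_sections())
  p0 <- synth_params(n_studies = 60, seed = 2, decoy_rate = 0,
                     sg_section_probs = setNames(rep(0, length(secs)), secs))
  g0 <- generate_registry(p0)
  cohort <- suppressWarnings(select_cohort(g0$registry))
  tags <- tag_mentions(g0$registry, cohort)
  expect_true(all(tags$sg_category == "no_mention"))
  g1 <- generate_registry(synth_params(n_studies = 60, seed = 2, p_hpv = 1))
  cohort1 <- suppressWarnings(select_cohort(g1$registry))
  tags1 <- tag_mentions(g1$registry, cohort1)
  expect_true(all(tags1$hpv_mention))
})

test_that("whole-word matching survives decoys; a substring matcher does not", {
  p <- synth_params(n_studies = 600, seed = 12, decoy_rate = 1)
  gen <- generate_registry(p)
  cohort <- suppressWarnings(select_cohort(gen$registry))
  tags <- tag_mentions(gen$registry, cohort)
  labels <- derive_labels(gen$registry, tags)
  inc <- gen$truth[gen$truth$included, ]
  rr <- recovery_report(inc[c("nct_id", "sg_category")],
                        labels[c("nct_id", "sg_category")])
  expect_equal(rr$agreement, 1)
  # deliberately mis-configured lexicon: every term a plain substring
  bad_lex <- lexicon(tibble::tibble(term = sg_lexicon()$term,
                                    mode = "substring"), name = "bad")
  bad_tags <- tag_mentions(gen$registry, cohort,
                           lexicons = list(sg = bad_lex, hpv = hpv_lexicon()))
  rr_bad <- recovery_report(inc[c("nct_id", "sg_category")],
                            bad_tags[c("nct_id", "sg_category")])
  expect_lt(rr_bad$agreement, 1)
})

test_that("recovery_report computes confusions, rates, and id mismatches", {
  truth <- tibble::tibble(nct_id = sprintf("N%02d", 1:10),
                          lab = rep(c("a", "b"), 5))
  pred <- truth
  expect_equal(recovery_report(truth, pred)$agreement, 1)
  pred2 <- pred; pred2$lab[1] <- "b"
  rr <- recovery_report(truth, pred2)
  expect_equal(rr$agreement, 9 / 10)
  expect_equal(sum(rr$confusion[[1]]), 10)
  pred3 <- pred; pred3$nct_id <- sprintf("M%02d", 1:10)
  expect_error(recovery_report(truth, pred3), "nct_id sets differ")
})

test_that("invalid generator probabilities are rejected", {
  expect_error(synth_params(p_hpv = 1.5), "probabilities")
  expect_error(synth_params(status_weights = c(Completed = -1, Other = 2)),
               "nonnegative")
})
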