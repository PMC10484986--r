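test_that("crosstab conserves counts and recovers planted cells", {
  df <- tibble::tibble(a = rep(c("x", "y"), each = 4),
                       b = rep(c("u", "v"), 4))
  xt <- crosstab(df, "a", "b")
  expect_equal(sum(xt), 8)
  expect_equal(unname(unclass(xt)[, ]), matrix(2L, 2, 2), ignore_attr = TRUE)
  # planted counts
  df2 <- tibble::tibble(
    g = c(rep("i", 5), rep("o", 3)),
    m = c(rep("yes", 4), "no", rep("no", 3)))
  xt2 <- crosstab(df2, "g", "m")
  expect_equal(unclass(xt2)["i", "yes"], 4L, ignore_attr = TRUE)
  expect_equal(unclass(xt2)["o", "no"], 3L, ignore_attr = TRUE)
  # filter restricts the population
  xt3 <- crosstab(df2, "g", "m", filter = df2$g == "i")
  expect_equal(sum(xt3), 5)
  expect_error(crosstab(df2, "nope", "m"), "Unknown variable")
})

test_that("tidy row percentages sum to 100 per row", {
  xt <- as_xtab(matrix(c(7, 3, 2, 8, 1, 4), nrow = 2), "r", "c")
  td <- tidy(xt)
  sums <- tapply(td$row_pct, td$r, sum)
  expect_equal(as.numeric(sums), c(100, 100))
})

test_that("Pearson chi-square matches hand-computed examples", {
  t0 <- chi_square_test(as_xtab(matrix(c(10, 10, 10, 10), 2)))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  t1 <- chi_square_test(as_xtab(matrix(c(20, 10, 10, 20), 2)))
  expect_equal(t1$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(t1$df, 1)
  expect_equal(t1$p_value, 0.009823, tolerance = 1e-4)
  # planted independence via outer product -> statistic 0
  m <- outer(c(2, 3), c(4, 5, 6))
  expect_equal(chi_square_test(as_xtab(m))$statistic, 0, tolerance = 1e-12)
  expect_error(chi_square_test(as_xtab(matrix(c(0, 0, 3, 4), 2,
                                              byrow = TRUE))),
               "empty margin")
})

test_that("Pearson 2x2 equals the classical closed form", {
  withr::with_seed(7, {
    for (i in 1:50) {
      m <- matrix(rpois(4, 20) + 1, 2)
      expect_equal(chi_square_test(as_xtab(m))$statistic,
                   pearson_closed_form(m), tolerance = 1e-10)
    }
  })
})

test_that("Fisher exact equals the enumeration oracle", {
  expect_equal(fisher_exact(as_xtab(matrix(c(5, 5, 5, 5), 2)))$p_value, 1)
  expect_equal(fisher_exact(as_xtab(matrix(c(0, 5, 5, 0), 2)))$p_value,
               2 / choose(10, 5), tolerance = 1e-12)
  withr::with_seed(11, {
    for (i in 1:40) {
      m <- matrix(rpois(4, 4) + 1, 2)
      expect_equal(fisher_exact(as_xtab(m))$p_value, fisher_oracle(m),
                   tolerance = 1e-9)
    }
  })
  expect_warning(res <- fisher_exact(as_xtab(matrix(1:6, 2))),
                 "restricted to 2x2")
  expect_equal(res$method, "pearson_chi2")
})

test_that("the test-selection rule keys on expected counts and table shape", {
  expect_equal(choose_test(as_xtab(matrix(c(2, 3, 3, 2), 2))), "fisher_exact")
  expect_equal(choose_test(as_xtab(matrix(100, 2, 2))), "pearson_chi2")
  expect_warning(ct <- choose_test(as_xtab(matrix(c(1, 9, 1, 9, 20, 20), 2))),
                 "Pearson")
  expect_equal(ct, "pearson_chi2")
})

test_that("mention collapsing pools analytical with recruitment-only", {
  expect_equal(collapse_mention(c("analytical", "recruitment_only",
                                  "no_mention")),
               c("mention", "mention", "no_mention"))
  expect_error(collapse_mention("other"), "Unknown S/G category")
})

test_that("odds ratio: cross-product, Wald CI, Haldane correction", {
  o <- odds_ratio(as_xtab(matrix(c(960, 72, 447, 193), 2)))
  expect_equal(round(o$estimate, 2), 5.76)
  expect_equal(round(o$ci_low, 2), 4.29)
  expect_equal(round(o$ci_high, 2), 7.72)
  expect_false(o$haldane)
  expect_equal(o$log_se, sqrt(1/960 + 1/447 + 1/72 + 1/193))
  # symmetric table
  expect_equal(odds_ratio(as_xtab(matrix(3, 2, 2)))$estimate, 1)
  # single zero cell: add 0.5 everywhere and flag
  oh <- odds_ratio(as_xtab(matrix(c(0, 5, 5, 5), 2, byrow = TRUE)))
  expect_true(oh$haldane)
  expect_equal(oh$estimate, (0.5 * 5.5) / (5.5 * 5.5), tolerance = 1e-12)
  # a zero line is undefined
  expect_error(odds_ratio(as_xtab(matrix(c(0, 0, 5, 5), 2, byrow = TRUE))),
               "undefined")
})

test_that("odds-ratio symmetry and inversion identities hold", {
  withr::with_seed(3, {
    for (i in 1:25) {
      m <- matrix(rpois(4, 15) + 1, 2)
      o <- odds_ratio(as_xtab(m))$estimate
      # swapping both rows and both columns leaves the estimate unchanged
      expect_equal(odds_ratio(as_xtab(m[2:1, 2:1]))$estimate, o,
                   tolerance = 1e-12)
      # swapping rows alone inverts it exactly
      expect_equal(odds_ratio(as_xtab(m[2:1, ]))$estimate, 1 / o,
                   tolerance = 1e-12)
    }
  })
})

test_that("characteristics tables count every study once per block", {
  gen <- generate_registry(synth_params(n_studies = 350, seed = 17))
  cohort <- suppressWarnings(select_cohort(gen$registry))
  labels <- derive_labels(gen$registry, tag_mentions(gen$registry, cohort))
  t1 <- suppressWarnings(build_table1(labels))
  by_var <- tapply(t1$n, t1$variable, sum)
  n_int <- sum(labels$study_type == "interventional")
  expect_true(all(by_var[setdiff(names(by_var), "phase_group")] ==
                    nrow(labels)))
  expect_equal(as.numeric(by_var["phase_group"]), n_int)
  # category columns add back to the level count
  expect_equal(t1$analytical_n + t1$recruitment_only_n + t1$no_mention_n,
               t1$n)
  t2 <- suppressWarnings(build_table2(labels))
  expect_setequal(unique(t2$control_class), c("controlled", "uncontrolled"))
  st <- t2[t2$variable == "study_type", ]
  expect_equal(sum(st$n), nrow(labels))
})

test_that("the collapsed-mention odds ratio helper orients rows as asked", {
  gen <- generate_registry(synth_params(n_studies = 400, seed = 23))
  cohort <- suppressWarnings(select_cohort(gen$registry))
  labels <- derive_labels(gen$registry, tag_mentions(gen$registry, cohort))
  o1 <- mention_odds_ratio(labels, "enrolment_group", "le_100", "gt_100")
  o2 <- mention_odds_ratio(labels, "enrolment_group", "gt_100", "le_100")
  expect_equal(o1$estimate, 1 / o2$estimate, tolerance = 1e-12)
  expect_equal(o1$reference_row, "le_100")
})
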