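test_that("a studies table alone yields records with empty sections and lists", {
  dir <- make_registry_dir(studies_row(c("NCT1", "NCT2", "NCT3")))
  reg <- quiet_load(dir)
  expect_equal(nrow(reg), 3)
  expect_equal(reg$brief_summary, rep("", 3))
  expect_equal(lengths(reg$conditions), rep(0L, 3))
  expect_equal(vapply(reg$arms, nrow, 0L), rep(0L, 3))
})

test_that("the eligible-sex field maps to the enum; absences default to ALL with a warning", {
  dir <- make_registry_dir(
    studies_row(c("NCT1", "NCT2", "NCT3")),
    eligibilities = data.frame(nct_id = c("NCT1", "NCT2"),
                               gender = c("All", "male"),
                               population = c("Adults", "Adults"),
                               criteria = c("", "")))
  expect_warning(reg <- load_registry(dir), "treated as ALL")
  expect_equal(reg$eligibility_sex, c("ALL", "MALE", "ALL"))
})

test_that("duplicate or missing study identifiers are fatal", {
  dir <- make_registry_dir(studies_row(c("NCT00000001", "NCT00000001")))
  expect_error(load_registry(dir), "Duplicate nct_id")
  dir2 <- tempfile(); dir.create(dir2)
  readr::write_csv(data.frame(nct_id = "NCT1", name = "x"),
                   file.path(dir2, "conditions.csv"))
  expect_error(load_registry(dir2), "studies")
})

test_that("section_map is total, has a fixed key set, and joins list sections safely", {
  dir <- make_registry_dir(
    studies_row(c("NCT1", "NCT2"), official_title = c("Only title", "")),
    design_outcomes = data.frame(
      nct_id = c("NCT1", "NCT1"),
      measure = c("Response rate", "Survival"),
      description = c("First outcome", "Second outcome")))
  reg <- quiet_load(dir)
  sm <- section_map(reg)
  expect_setequal(setdiff(names(sm), "nct_id"),
                  c(analysis_sections(), eligibility_sections()))
  # both measures and both descriptions present, newline-separated
  expect_match(sm$outcomes[1], "Response rate")
  expect_match(sm$outcomes[1], "Second outcome")
  expect_false(grepl("rateSurvival", gsub("\n", "", sm$outcomes[1])) &&
                 !grepl("\n", sm$outcomes[1]))
  # the empty record is fully present, all sections empty
  empty_secs <- unlist(sm[2, setdiff(names(sm), "nct_id")])
  expect_true(all(empty_secs == ""))
  # exactly one non-empty section for the title-only record
  row1 <- unlist(sm[1, setdiff(names(sm), c("nct_id", "outcomes"))])
  expect_equal(sum(row1 != ""), 1)
})

test_that("writing and re-loading a registry is field-identical", {
  gen <- generate_registry(synth_params(n_studies = 40, seed = 5))
  dir <- tempfile()
  write_registry(gen$registry, dir)
  reg2 <- quiet_load(dir, snapshot_date = attr(gen$registry, "snapshot_date"))
  for (nm in names(gen$registry)) {
    expect_equal(as.data.frame(gen$registry[nm]), as.data.frame(reg2[nm]),
                 ignore_attr = TRUE, label = nm)
  }
})
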