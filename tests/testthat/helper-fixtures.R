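# Build a minimal AACT-style table directory on disk.
make_registry_dir <- function(studies, ..., dir = tempfile("reg")) {
  dir.create(dir)
  tabs <- list(...)
  readr::write_csv(studies, file.path(dir, "studies.csv"), na = "")
  for (nm in names(tabs)) {
    readr::write_csv(tabs[[nm]], file.path(dir, paste0(nm, ".csv")), na = "")
  }
  dir
}

studies_row <- function(nct_id, status = "Completed", type = "Interventional",
                        phase = NA, enrollment = NA,
                        brief_title = "", official_title = "",
                        date = "2015-06-01") {
  data.frame(nct_id = nct_id, brief_title = brief_title,
             official_title = official_title, study_type = type,
             overall_status = status, enrollment = enrollment,
             phase = phase, study_first_submitted_date = date)
}

# One in-memory record via the synthetic machinery is overkill for unit
# tests; this builds an empty-sections registry straight from a studies df.
quiet_load <- function(dir, ...) suppressWarnings(load_registry(dir, ...))
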