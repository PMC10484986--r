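#' Pipeline run configuration
#'
#' @param registry_dir Directory of AACT-style tables (see
#'   [registry-format]).
#' @param output_dir Directory for stage outputs (created if needed).
#' @param lexicon_dir Directory with `sg_terms.txt` / `hpv_terms.txt`;
#'   `NULL` uses the shipped lexicons.
#' @param snapshot_date Registry snapshot date.
#' @param delim Table delimiter.
#' @param trend_compare Optional `c(year1, year2)` for the two-year
#'   analytical-share comparison; `NULL` skips it.
#' @return A `run_config` list.
#' @export
run_config <- function(registry_dir, output_dir, lexicon_dir = NULL,
                       snapshot_date = Sys.Date(), delim = ",",
                       trend_compare = NULL) {
  structure(list(registry_dir = registry_dir, output_dir = output_dir,
                 lexicon_dir = lexicon_dir,
                 snapshot_date = as.Date(snapshot_date), delim = delim,
                 trend_compare = trend_compare),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Every field of [run_config()] has a YAML twin with the same name.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(
    registry_dir = y$registry_dir, output_dir = y$output_dir,
    lexicon_dir = y$lexicon_dir,
    snapshot_date = y$snapshot_date %||% Sys.Date(),
    delim = y$delim %||% ",",
    trend_compare = y$trend_compare
  )
}

#' Run the full analysis pipeline
#'
#' Executes, in order: registry load, cohort selection, mention tagging,
#' label derivation, the three characteristics tables, and the yearly
#' trends; writes each stage's output as delimited text plus a JSON
#' manifest with input checksums and row counts. Any stage error aborts
#' with the stage name, and partial outputs are removed.
#'
#' @param config A `run_config` (or path to a YAML config).
#' @return The manifest, invisibly, as a list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, nm) {
    path <- file.path(out_dir, nm)
    readr::write_csv(df, path)
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      abort(paste0("Pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  manifest <- list(stages = character(0))

  registry <- stage("registry_io", {
    reg <- load_registry(config$registry_dir, delim = config$delim,
                         snapshot_date = config$snapshot_date)
    files <- list.files(config$registry_dir, pattern = "\\.csv$",
                        full.names = TRUE)
    manifest$inputs <- lapply(setNames(files, basename(files)),
                              function(f) unname(tools::md5sum(f)))
    manifest$stages <- c(manifest$stages, "registry_io")
    manifest$n_studies_loaded <- nrow(reg)
    reg
  })

  cohort <- stage("cohort_selection", {
    ch <- select_cohort(registry)
    emit(ch[setdiff(names(ch), character(0))], "cohort.csv")
    manifest$cohort_report <- as.list(cohort_report(ch))
    manifest$stages <- c(manifest$stages, "cohort_selection")
    ch
  })

  lexicons <- stage("mention_tagging", {
    lx <- load_lexicons(config$lexicon_dir)
    manifest$lexicons <- list(
      sg = nrow(lx$sg), hpv = nrow(lx$hpv),
      dir = config$lexicon_dir %||% "builtin")
    lx
  })
  tags <- stage("mention_tagging", {
    tg <- tag_mentions(registry, cohort, lexicons)
    manifest$stages <- c(manifest$stages, "mention_tagging")
    tg
  })

  labels <- stage("design_classification", {
    lb <- derive_labels(registry, tags)
    emit(lb, "study_labels.csv")
    manifest$stages <- c(manifest$stages, "design_classification")
    manifest$n_labelled <- nrow(lb)
    lb
  })

  stage("association_stats", {
    t1 <- build_table1(labels)
    t2 <- build_table2(labels)
    t3 <- build_table3(labels)
    emit(t1, "table1.csv"); emit(t2, "table2.csv"); emit(t3, "table3.csv")
    or_main <- tryCatch(
      mention_odds_ratio(labels, "study_type", "interventional",
                         "observational"),
      error = function(e) NULL)
    manifest$or_interventional_vs_observational <- if (is.null(or_main)) {
      NA
    } else tidy(or_main)[c("estimate", "ci_low", "ci_high")]
    manifest$stages <- c(manifest$stages, "association_stats")
  })

  stage("trend_analysis", {
    tr_sg <- yearly_series(labels, "sg_category")
    tr_hpv <- yearly_series(labels, "hpv_mention")
    emit(tibble::as_tibble(tr_sg), "trends_sg.csv")
    emit(tibble::as_tibble(tr_hpv), "trends_hpv.csv")
    if (!is.null(config$trend_compare)) {
      cmp <- compare_year_proportions(tr_sg, "analytical",
                                      config$trend_compare[1],
                                      config$trend_compare[2])
      manifest$trend_comparison <- list(
        years = config$trend_compare, stratum = "analytical",
        p_value = cmp$p_value)
    }
    manifest$stages <- c(manifest$stages, "trend_analysis")
  })

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
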