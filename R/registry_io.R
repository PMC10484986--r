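#' AACT-style registry tables
#'
#' The pipeline reads the relational export format of ClinicalTrials.gov
#' (AACT): one delimited text file per table, keyed by `nct_id`, with the
#' public data-dictionary column names. The `studies` table is mandatory;
#' every other table is optional and an absent join simply yields empty text
#' or an empty list for that study.
#'
#' @name registry-format
#' @keywords internal
NULL

aact_tables <- function() {
  c("studies", "conditions", "browse_conditions", "eligibilities", "designs",
    "design_groups", "design_outcomes", "interventions", "brief_summaries",
    "detailed_descriptions")
}

chr0 <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}

# Collect per-study rows of an auxiliary table into a named list of tibbles.
nest_by_id <- function(df, ids) {
  if (is.null(df) || nrow(df) == 0) {
    return(setNames(rep(list(df), length(ids)), ids))
  }
  split(df[setdiff(names(df), "nct_id")], factor(df$nct_id, levels = ids))
}

#' Load an AACT-style registry
#'
#' Reads the per-table delimited files and assembles one record per study:
#' structured fields from `studies`, `eligibilities` and `designs`, the two
#' free-text description tables, and list-columns for conditions, MeSH
#' browse conditions, arms (design groups), outcomes and interventions.
#'
#' @param path Either a directory containing `<table>.csv` files, or a named
#'   list/vector of file paths keyed by table name (see [registry-format]).
#' @param delim Field delimiter (default `","`).
#' @param snapshot_date Date of the registry snapshot; defaults to today.
#' @return An `hnc_registry`: a tibble with one row per study and columns
#'   `nct_id`, `brief_title`, `official_title`, `brief_summary`,
#'   `detailed_description`, `eligibility_sex` (`"ALL"|"MALE"|"FEMALE"`),
#'   `eligibility_population`, `eligibility_criteria`, `enrollment`,
#'   `phase_raw`, `overall_status`, `allocation`, `study_type`,
#'   `first_submitted` (Date), and list-columns `conditions`,
#'   `browse_conditions` (character vectors), `arms`, `outcomes`,
#'   `interventions` (tibbles).
#' @export
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' readr::write_csv(
#'   data.frame(nct_id = "NCT1", brief_title = "A study",
#'              overall_status = "Completed"),
#'   file.path(dir, "studies.csv"))
#' load_registry(dir)
load_registry <- function(path, delim = ",", snapshot_date = Sys.Date()) {
  if (length(path) == 1 && is.character(path) && is.null(names(path))) {
    files <- file.path(path, paste0(aact_tables(), ".csv"))
    names(files) <- aact_tables()
    files <- files[file.exists(files)]
  } else {
    files <- unlist(path)
  }
  if (!"studies" %in% names(files)) {
    abort("The `studies` table is required but was not found.")
  }
  read_tbl <- function(nm) {
    if (!nm %in% names(files)) return(NULL)
    readr::read_delim(files[[nm]], delim = delim, col_types = readr::cols(
      .default = readr::col_character()
    ), progress = FALSE, locale = readr::locale(encoding = "UTF-8"))
  }
  tabs <- lapply(setNames(aact_tables(), aact_tables()), read_tbl)
  assemble_registry(tabs, snapshot_date = snapshot_date)
}

assemble_registry <- function(tabs, snapshot_date = Sys.Date()) {
  studies <- tabs$studies
  if (is.null(studies) || nrow(studies) == 0) {
    abort("The `studies` table is empty or missing.")
  }
  if (!"nct_id" %in% names(studies)) abort("`studies` lacks an nct_id column.")
  dup <- studies$nct_id[duplicated(studies$nct_id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate nct_id in studies table: ",
                 paste(unique(dup), collapse = ", ")))
  }
  if (any(is.na(studies$nct_id) | studies$nct_id == "")) {
    abort("Empty nct_id in studies table.")
  }
  ids <- studies$nct_id
  col <- function(df, nm) if (!is.null(df) && nm %in% names(df)) df[[nm]] else rep(NA_character_, nrow(df %||% studies))

  one_text <- function(tab, field) {
    # single-row-per-study text tables (brief_summaries, detailed_descriptions)
    out <- setNames(rep("", length(ids)), ids)
    df <- tabs[[tab]]
    if (!is.null(df) && nrow(df) > 0) {
      txt <- vapply(split(chr0(col(df, field)), factor(df$nct_id, levels = ids)),
                    paste, "", collapse = "\n")
      out[names(txt)] <- txt
    }
    unname(out[ids])
  }
  list_text <- function(tab, field) {
    out <- setNames(rep(list(character(0)), length(ids)), ids)
    df <- tabs[[tab]]
    if (!is.null(df) && nrow(df) > 0 && field %in% names(df)) {
      sp <- split(chr0(df[[field]]), factor(df$nct_id, levels = ids))
      out[names(sp)] <- sp
    }
    unname(out[ids])
  }
  pair_tbl <- function(tab, f1, f2, n1, n2) {
    out <- setNames(rep(list(tibble::tibble(!!n1 := character(0),
                                            !!n2 := character(0))), length(ids)), ids)
    df <- tabs[[tab]]
    if (!is.null(df) && nrow(df) > 0) {
      df2 <- tibble::tibble(nct_id = df$nct_id,
                            !!n1 := chr0(col(df, f1)),
                            !!n2 := chr0(col(df, f2)))
      sp <- split(df2[-1], factor(df2$nct_id, levels = ids))
      out[names(sp)] <- lapply(sp, tibble::as_tibble)
    }
    unname(out[ids])
  }

  elig <- tabs$eligibilities
  elig_row <- function(field) {
    out <- setNames(rep(NA_character_, length(ids)), ids)
    if (!is.null(elig) && nrow(elig) > 0 && field %in% names(elig)) {
      keep <- !duplicated(elig$nct_id) & elig$nct_id %in% ids
      out[elig$nct_id[keep]] <- elig[[field]][keep]
    }
    unname(out[ids])
  }
  sex_raw <- elig_row("gender")
  sex <- toupper(trimws(chr0(sex_raw)))
  sex[sex == ""] <- NA_character_
  unknown_sex <- !is.na(sex) & !sex %in% c("ALL", "MALE", "FEMALE")
  if (any(unknown_sex)) {
    warn(paste0("Unrecognised eligible-sex value(s) treated as ALL: ",
                paste(unique(sex[unknown_sex]), collapse = ", ")))
    sex[unknown_sex] <- "ALL"
  }
  if (anyNA(sex)) {
    warn(paste0(sum(is.na(sex)), " studies lack an eligible-sex value; treated as ALL."))
    sex[is.na(sex)] <- "ALL"
  }

  designs <- tabs$designs
  alloc <- setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(designs) && nrow(designs) > 0 && "allocation" %in% names(designs)) {
    keep <- !duplicated(designs$nct_id) & designs$nct_id %in% ids
    alloc[designs$nct_id[keep]] <- designs$allocation[keep]
  }

  enr <- suppressWarnings(as.numeric(col(studies, "enrollment")))
  if (any(!is.na(enr) & enr < 0)) abort("Negative enrollment value in studies table.")
  first_sub <- as.Date(col(studies, "study_first_submitted_date"))

  reg <- tibble::tibble(
    nct_id = ids,
    brief_title = chr0(col(studies, "brief_title")),
    official_title = chr0(col(studies, "official_title")),
    brief_summary = one_text("brief_summaries", "description"),
    detailed_description = one_text("detailed_descriptions", "description"),
    eligibility_sex = sex,
    eligibility_population = chr0(elig_row("population")),
    eligibility_criteria = chr0(elig_row("criteria")),
    enrollment = as.integer(round(enr)),
    phase_raw = as.character(col(studies, "phase")),
    overall_status = chr0(col(studies, "overall_status")),
    allocation = unname(alloc[ids]),
    study_type = chr0(col(studies, "study_type")),
    first_submitted = first_sub,
    conditions = list_text("conditions", "name"),
    browse_conditions = list_text("browse_conditions", "mesh_term"),
    arms = pair_tbl("design_groups", "title", "group_type", "title", "arm_type"),
    outcomes = pair_tbl("design_outcomes", "measure", "description",
                        "measure", "description"),
    interventions = pair_tbl("interventions", "name", "description",
                             "name", "description")
  )
  structure(reg, class = c("hnc_registry", class(reg)),
            snapshot_date = as.Date(snapshot_date))
}

#' Write a registry back to AACT-style tables
#'
#' Inverse of [load_registry()]: emits the per-table delimited files so that
#' re-loading yields field-identical records. Used by the synthetic
#' generator and for round-trip validation.
#'
#' @param registry An `hnc_registry`.
#' @param dir Output directory (created if needed).
#' @param delim Field delimiter.
#' @return `dir`, invisibly.
#' @export
write_registry <- function(registry, dir, delim = ",") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, nm) {
    readr::write_delim(df, file.path(dir, paste0(nm, ".csv")), delim = delim,
                       na = "")
  }
  wr(tibble::tibble(
    nct_id = registry$nct_id,
    brief_title = registry$brief_title,
    official_title = registry$official_title,
    study_type = registry$study_type,
    overall_status = registry$overall_status,
    enrollment = registry$enrollment,
    phase = registry$phase_raw,
    study_first_submitted_date = format(registry$first_submitted, "%Y-%m-%d")
  ), "studies")
  unnest_chr <- function(col_, value_nm) {
    n <- lengths(registry[[col_]])
    tibble::tibble(nct_id = rep(registry$nct_id, n),
                   !!value_nm := unlist(registry[[col_]], use.names = FALSE) %||% character(0))
  }
  wr(unnest_chr("conditions", "name"), "conditions")
  wr(unnest_chr("browse_conditions", "mesh_term"), "browse_conditions")
  wr(tibble::tibble(nct_id = registry$nct_id,
                    gender = c(ALL = "All", MALE = "Male",
                               FEMALE = "Female")[registry$eligibility_sex],
                    population = registry$eligibility_population,
                    criteria = registry$eligibility_criteria), "eligibilities")
  wr(tibble::tibble(nct_id = registry$nct_id,
                    allocation = registry$allocation), "designs")
  unnest_pairs <- function(col_, from, to) {
    n <- vapply(registry[[col_]], nrow, 0L)
    flat <- dplyr::bind_rows(registry[[col_]])
    out <- tibble::tibble(nct_id = rep(registry$nct_id, n))
    for (i in seq_along(from)) out[[to[i]]] <- flat[[from[i]]]
    out
  }
  wr(unnest_pairs("arms", c("title", "arm_type"), c("title", "group_type")),
     "design_groups")
  wr(unnest_pairs("outcomes", c("measure", "description"),
                  c("measure", "description")), "design_outcomes")
  wr(unnest_pairs("interventions", c("name", "description"),
                  c("name", "description")), "interventions")
  nonempty <- function(col_) registry[[col_]] != ""
  wr(tibble::tibble(nct_id = registry$nct_id,
                    description = registry$brief_summary)[nonempty("brief_summary"), ],
     "brief_summaries")
  wr(tibble::tibble(nct_id = registry$nct_id,
                    description = registry$detailed_description)[
       nonempty("detailed_description"), ], "detailed_descriptions")
  invisible(dir)
}

#' Section identifiers targeted by the term search
#'
#' Analysis sections are the free-text fields where an S/G term counts as an
#' analytical mention: titles, summaries, outcome measures and descriptions,
#' design-group titles and intervention descriptions. Eligibility sections
#' (population and criteria) count only as recruitment mentions.
#'
#' @return A character vector of section ids.
#' @export
analysis_sections <- function() {
  c("brief_title", "official_title", "brief_summary", "detailed_description",
    "outcomes", "design_groups", "interventions")
}

#' @rdname analysis_sections
#' @export
eligibility_sections <- function() {
  c("eligibility_population", "eligibility_criteria")
}

#' Extract the targeted text sections of each study
#'
#' Produces one column of concatenated text per targeted section. The key
#' set is identical for every study; list-valued sections (outcome measures
#' and descriptions, design-group titles, intervention descriptions) are
#' joined with newlines so that no spurious word adjacency is created.
#'
#' @param registry An `hnc_registry` (or any subset of its rows).
#' @return A tibble with `nct_id` and one character column per section id
#'   from [analysis_sections()] and [eligibility_sections()].
#' @export
section_map <- function(registry) {
  join_pairs <- function(tbls) {
    vapply(tbls, function(t) {
      txt <- unlist(t, use.names = FALSE)
      paste(txt[txt != ""], collapse = "\n")
    }, "")
  }
  tibble::tibble(
    nct_id = registry$nct_id,
    brief_title = registry$brief_title,
    official_title = registry$official_title,
    brief_summary = registry$brief_summary,
    detailed_description = registry$detailed_description,
    outcomes = join_pairs(registry$outcomes),
    design_groups = vapply(registry$arms, function(a) {
      paste(a$title[a$title != ""], collapse = "\n")
    }, ""),
    interventions = vapply(registry$interventions, function(i) {
      paste(i$description[i$description != ""], collapse = "\n")
    }, ""),
    eligibility_population = registry$eligibility_population,
    eligibility_criteria = registry$eligibility_criteria
  )
}

#' Flatten a registry to one row per study
#'
#' The normalised study-level table written for downstream stages: all
#' structured fields plus one column per targeted section and the
#' newline-joined condition lists.
#'
#' @param registry An `hnc_registry`.
#' @return A tibble with plain (non-list) columns only.
#' @export
study_table <- function(registry) {
  dplyr::bind_cols(
    section_map(registry),
    tibble::tibble(
      conditions = vapply(registry$conditions, paste, "", collapse = "\n"),
      browse_conditions = vapply(registry$browse_conditions, paste, "",
                                 collapse = "\n"),
      eligibility_sex = registry$eligibility_sex,
      enrollment = registry$enrollment,
      phase_raw = registry$phase_raw,
      overall_status = registry$overall_status,
      allocation = registry$allocation,
      study_type = registry$study_type,
      first_submitted = registry$first_submitted
    )
  )
}
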