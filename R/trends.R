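#' Yearly submission counts by stratum
#'
#' Counts every study once in its first-submission year, stratified by a
#' label (S/G category for the mention trend, HPV mention for the HPV
#' trend). Years between the first and last observed are filled with zero
#' counts so the series is contiguous.
#'
#' @param labels A labels tibble from [derive_labels()] with
#'   `submission_year`.
#' @param stratum_var Label column to stratify by.
#' @param year_range Optional `c(first, last)` to clip/extend the series;
#'   default the observed range. Studies outside the range are an error.
#' @return An `hnc_trend`: a tibble with `year`, `stratum`, `n`, in long
#'   form, complete over years x strata.
#' @export
yearly_series <- function(labels, stratum_var, year_range = NULL) {
  if (!stratum_var %in% names(labels)) {
    abort(paste0("Unknown variable name: ", stratum_var))
  }
  if (nrow(labels) == 0) {
    return(structure(tibble::tibble(year = integer(0), stratum = character(0),
                                    n = integer(0)),
                     class = c("hnc_trend", class(tibble::tibble())),
                     stratum_var = stratum_var))
  }
  if (anyNA(labels$submission_year)) {
    abort("submission_year must be present for every study.")
  }
  yr <- as.integer(labels$submission_year)
  if (is.null(year_range)) year_range <- range(yr)
  if (any(yr < year_range[1] | yr > year_range[2])) {
    abort(paste0("Studies dated outside [", year_range[1], ", ",
                 year_range[2], "]."))
  }
  strata <- unique(as.character(labels[[stratum_var]]))
  out <- tibble::tibble(year = yr,
                        stratum = as.character(labels[[stratum_var]])) |>
    dplyr::count(.data$year, .data$stratum) |>
    tidyr::complete(year = seq(year_range[1], year_range[2]),
                    stratum = strata, fill = list(n = 0L)) |>
    dplyr::arrange(.data$year, .data$stratum)
  structure(out, class = c("hnc_trend", class(out)), stratum_var = stratum_var)
}

#' Compare a stratum's share between two years
#'
#' Fisher's exact test on the 2x2 table (stratum vs all other strata) x
#' (year1 vs year2), e.g. the share of analytical S/G mentions in 2010
#' versus 2020.
#'
#' @param series An `hnc_trend` from [yearly_series()].
#' @param stratum The stratum label of interest.
#' @param year1,year2 The two years to compare.
#' @return An `hnc_test` from [fisher_exact()].
#' @export
compare_year_proportions <- function(series, stratum, year1, year2) {
  for (y in c(year1, year2)) {
    tot <- sum(series$n[series$year == y])
    if (length(tot) == 0 || tot == 0) {
      abort(paste0("Year ", y, " has no studies in the series."))
    }
  }
  cell <- function(y, in_stratum) {
    rows <- series$year == y &
      (if (in_stratum) series$stratum == stratum else series$stratum != stratum)
    sum(series$n[rows])
  }
  m <- matrix(c(cell(year1, TRUE), cell(year1, FALSE),
                cell(year2, TRUE), cell(year2, FALSE)),
              nrow = 2, byrow = TRUE,
              dimnames = list(year = c(year1, year2),
                              stratum = c(stratum, paste0("not_", stratum))))
  fisher_exact(as_xtab(m, row_var = "year", col_var = stratum))
}

#' @export
autoplot.hnc_trend <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$year, y = .data$n,
                                       fill = .data$stratum)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Submission year", y = "Studies submitted",
                  fill = attr(object, "stratum_var")) +
    ggplot2::theme_minimal()
}

#' Stacked yearly-trend plot
#'
#' @param labels A labels tibble from [derive_labels()].
#' @param stratum_var Label column to stratify by (default S/G category).
#' @param ... Passed to [yearly_series()].
#' @return A ggplot object.
#' @export
plot_trend <- function(labels, stratum_var = "sg_category", ...) {
  autoplot(yearly_series(labels, stratum_var, ...))
}
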