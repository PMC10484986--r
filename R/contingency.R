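#' Cross-tabulate two study labels
#'
#' Counts every study exactly once into an r x c contingency table; an
#' optional filter restricts the population first (e.g. controlled studies
#' only). Row and column orders follow the order of first appearance unless
#' the label columns are factors.
#'
#' @param labels A labels tibble from [derive_labels()] (or any data frame).
#' @param row_var,col_var Column names to tabulate.
#' @param filter Optional logical vector or one-argument predicate applied
#'   to `labels` rows.
#' @param row_levels,col_levels Optional explicit level orders.
#' @return An `hnc_xtab`: an integer matrix with dimnames, carrying the
#'   variable names as attributes. Margins via [margins()].
#' @export
crosstab <- function(labels, row_var, col_var, filter = NULL,
                     row_levels = NULL, col_levels = NULL) {
  if (!row_var %in% names(labels) || !col_var %in% names(labels)) {
    abort(paste0("Unknown variable name(s): ",
                 paste(setdiff(c(row_var, col_var), names(labels)),
                       collapse = ", ")))
  }
  if (!is.null(filter)) {
    keep <- if (is.function(filter)) filter(labels) else filter
    labels <- labels[keep, ]
  }
  lev <- function(x, forced) {
    if (!is.null(forced)) forced
    else if (is.factor(x)) levels(x)
    else unique(as.character(x))
  }
  r <- as.character(labels[[row_var]])
  c_ <- as.character(labels[[col_var]])
  m <- table(factor(r, levels = lev(labels[[row_var]], row_levels)),
             factor(c_, levels = lev(labels[[col_var]], col_levels)))
  m <- matrix(as.integer(m), nrow = nrow(m), dimnames = dimnames(m))
  as_xtab(m, row_var = row_var, col_var = col_var)
}

#' Build a contingency table from a count matrix
#'
#' @param counts A nonnegative integer matrix (dimnames optional).
#' @param row_var,col_var Variable names recorded on the table.
#' @return An `hnc_xtab`.
#' @export
as_xtab <- function(counts, row_var = "row", col_var = "col") {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Contingency counts must be nonnegative integers.")
  }
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts))) rownames(counts) <- paste0("r", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("c", seq_len(ncol(counts)))
  structure(counts, class = c("hnc_xtab", "matrix", "array"),
            row_var = row_var, col_var = col_var)
}

#' @export
print.hnc_xtab <- function(x, ...) {
  cat("<contingency table: ", attr(x, "row_var"), " x ", attr(x, "col_var"),
      ", n = ", sum(x), ">\n", sep = "")
  print(unclass_xtab(x))
  invisible(x)
}

unclass_xtab <- function(x) {
  attr(x, "row_var") <- NULL
  attr(x, "col_var") <- NULL
  unclass(x)
}

#' Margins of a contingency table
#'
#' @param x An `hnc_xtab`.
#' @return A list with `row`, `col` and `total`.
#' @export
margins <- function(x) {
  list(row = rowSums(x), col = colSums(x), total = sum(x))
}

#' @export
tidy.hnc_xtab <- function(x, ...) {
  df <- as.data.frame.table(unclass_xtab(x), responseName = "n",
                            stringsAsFactors = FALSE)
  names(df) <- c(attr(x, "row_var"), attr(x, "col_var"), "n")
  out <- tibble::as_tibble(df)
  out |>
    dplyr::group_by(.data[[attr(x, "row_var")]]) |>
    dplyr::mutate(row_pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

check_degenerate <- function(x) {
  m <- margins(x)
  if (any(m$row == 0) || any(m$col == 0)) {
    empty <- c(names(m$row)[m$row == 0], names(m$col)[m$col == 0])
    abort(paste0("Degenerate table: empty margin(s) ",
                 paste(empty, collapse = ", ")))
  }
  if (m$total == 0) abort("Degenerate table: grand total is zero.")
}

new_test_result <- function(method, statistic, df, p_value, table) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, table = table),
            class = "hnc_test")
}

#' @export
print.hnc_test <- function(x, ...) {
  cat("<", x$method,
      if (!is.na(x$statistic)) paste0(": X2 = ", signif(x$statistic, 4),
                                      ", df = ", x$df) else "",
      ", p = ", signif(x$p_value, 3), ">\n", sep = "")
  invisible(x)
}

#' @export
tidy.hnc_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic, df = x$df,
                 p_value = x$p_value)
}

#' @export
glance.hnc_test <- function(x, ...) tidy(x)

#' Pearson chi-square test of independence
#'
#' The classical Pearson statistic sum((O - E)^2 / E) without continuity
#' correction, with (r-1)(c-1) degrees of freedom. Empty row or column
#' margins are an error (the stratum should be dropped upstream).
#'
#' @param x An `hnc_xtab` (r, c >= 2).
#' @return An `hnc_test` with `method`, `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(x) {
  if (nrow(x) < 2 || ncol(x) < 2) abort("Need at least a 2x2 table.")
  check_degenerate(x)
  ct <- suppressWarnings(stats::chisq.test(unclass_xtab(x), correct = FALSE))
  new_test_result("pearson_chi2", unname(ct$statistic), unname(ct$parameter),
                  ct$p.value, x)
}

#' Fisher exact test (2x2)
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities, over
#' all tables with the observed margins, of tables no more probable than
#' the observed one. Non-2x2 input falls back to Pearson with a warning.
#'
#' @param x An `hnc_xtab`.
#' @return An `hnc_test` (statistic and df are `NA` for the exact test).
#' @export
fisher_exact <- function(x) {
  if (nrow(x) != 2 || ncol(x) != 2) {
    warn("Fisher exact test is restricted to 2x2 tables; using Pearson chi-square.")
    return(chi_square_test(x))
  }
  check_degenerate(x)
  ft <- stats::fisher.test(unclass_xtab(x))
  new_test_result("fisher_exact", NA_real_, NA_integer_, ft$p.value, x)
}

#' Test-selection rule
#'
#' Fisher's exact test is used iff the table is 2x2 and any expected cell
#' count is below 5; otherwise Pearson's chi-square. An r x c table with a
#' small expected cell still gets Pearson, with a warning.
#'
#' @param x An `hnc_xtab`.
#' @return `"fisher_exact"` or `"pearson_chi2"`.
#' @export
choose_test <- function(x) {
  check_degenerate(x)
  m <- margins(x)
  expected <- outer(m$row, m$col) / m$total
  small <- any(expected < 5)
  if (small && nrow(x) == 2 && ncol(x) == 2) return("fisher_exact")
  if (small) {
    warn("Expected cell count < 5 in an r x c table; Pearson chi-square used anyway.")
  }
  "pearson_chi2"
}

#' Run the selected association test
#'
#' Applies [choose_test()] and runs the chosen test.
#'
#' @param x An `hnc_xtab`.
#' @return An `hnc_test`.
#' @export
association_test <- function(x) {
  if (choose_test(x) == "fisher_exact") fisher_exact(x) else chi_square_test(x)
}

#' Collapse the three-way S/G category to mention vs no mention
#'
#' Analytical and recruitment-only both count as "mention"; the 2x2
#' odds-ratio analyses compare this collapsed indicator.
#'
#' @param sg_category Character vector of categories.
#' @return Character vector with levels `mention`, `no_mention`.
#' @export
collapse_mention <- function(sg_category) {
  bad <- setdiff(unique(sg_category),
                 c("analytical", "recruitment_only", "no_mention"))
  if (length(bad) > 0) {
    abort(paste0("Unknown S/G category: ", paste(bad, collapse = ", ")))
  }
  ifelse(sg_category == "no_mention", "no_mention", "mention")
}

#' Odds ratio with Wald confidence interval
#'
#' The plain cross-product estimate (a*d)/(b*c) of a 2x2 table
#' \[\[a, b\], \[c, d\]\], with the log-scale standard error
#' sqrt(1/a + 1/b + 1/c + 1/d) and the 95% Wald interval
#' exp(log OR +/- 1.96 * SE). If any single cell is zero the
#' Haldane-Anscombe correction (add 0.5 to every cell) is applied and the
#' result flagged; a fully zero row or column is an error. The first row
#' and first column are the declared reference levels.
#'
#' @param x A 2x2 `hnc_xtab` (or plain 2x2 matrix).
#' @param conf_z Normal quantile for the interval (default 1.96).
#' @return An `hnc_or` with `estimate`, `log_se`, `ci_low`, `ci_high`,
#'   `reference_row`, `reference_col`, `haldane`.
#' @export
#' @examples
#' odds_ratio(as_xtab(matrix(c(960, 72, 447, 193), 2)))  # OR 5.76 [4.29, 7.72]
odds_ratio <- function(x, conf_z = 1.96) {
  if (!inherits(x, "hnc_xtab")) x <- as_xtab(x)
  if (nrow(x) != 2 || ncol(x) != 2) abort("Odds ratios need a 2x2 table.")
  cells <- unclass_xtab(x)
  zero_line <- any(rowSums(cells == 0) == 2) || any(colSums(cells == 0) == 2)
  if (zero_line) {
    abort("Odds ratio undefined: a full row or column of zeros.")
  }
  haldane <- any(cells == 0)
  work <- if (haldane) cells + 0.5 else cells
  a <- work[1, 1]; b <- work[1, 2]; c_ <- work[2, 1]; d <- work[2, 2]
  est <- (a * d) / (b * c_)
  log_se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  structure(list(
    estimate = est, log_se = log_se,
    ci_low = exp(log(est) - conf_z * log_se),
    ci_high = exp(log(est) + conf_z * log_se),
    reference_row = rownames(cells)[1], reference_col = colnames(cells)[1],
    haldane = haldane, table = x
  ), class = "hnc_or")
}

#' @export
print.hnc_or <- function(x, ...) {
  cat("<OR = ", round(x$estimate, 2), ", 95% CI [", round(x$ci_low, 2), ", ",
      round(x$ci_high, 2), "]", if (x$haldane) ", Haldane-corrected" else "",
      " (ref: ", x$reference_row, " / ", x$reference_col, ")>\n", sep = "")
  invisible(x)
}

#' @export
tidy.hnc_or <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, log_se = x$log_se,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 reference_row = x$reference_row,
                 reference_col = x$reference_col, haldane = x$haldane)
}

#' @export
glance.hnc_or <- function(x, ...) tidy(x)
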