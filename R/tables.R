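#' Breakdown of a stratifier by S/G mention category
#'
#' One block of the characteristics tables: for each level of `var`, the
#' overall count (and column %), the count and row % in each S/G category,
#' plus the association test for the var x category table.
#'
#' @param labels A labels tibble from [derive_labels()].
#' @param var A label column name to stratify by.
#' @param filter Optional logical vector or predicate restricting the rows.
#' @return A tibble, one row per level of `var`, with attribute `"test"`
#'   (the `hnc_test`) and columns `variable`, `level`, `n`, `pct`,
#'   `<category>_n`, `<category>_pct` and `p_value`, `method`.
#' @export
mention_breakdown <- function(labels, var, filter = NULL) {
  if (!is.null(filter)) {
    keep <- if (is.function(filter)) filter(labels) else filter
    labels <- labels[keep, ]
  }
  cats <- c("analytical", "recruitment_only", "no_mention")
  xt <- crosstab(labels, var, "sg_category", col_levels = cats)
  test <- safe_association_test(xt)
  m <- margins(xt)
  out <- tibble::tibble(
    variable = var,
    level = rownames(xt),
    n = unname(m$row),
    pct = 100 * unname(m$row) / m$total
  )
  for (ct in cats) {
    out[[paste0(ct, "_n")]] <- unname(unclass_xtab(xt)[, ct])
    out[[paste0(ct, "_pct")]] <- unname(100 * unclass_xtab(xt)[, ct] /
                                          pmax(m$row, 1))
  }
  out$p_value <- if (is.null(test)) NA_real_ else test$p_value
  out$method <- if (is.null(test)) NA_character_ else test$method
  attr(out, "test") <- test
  out
}

# association_test on the informative sub-table: empty rows/columns are
# dropped first (a category absent from a stratum carries no information);
# a stratum degenerate beyond 2x2 yields NULL rather than an error.
safe_association_test <- function(xt) {
  m <- unclass_xtab(xt)
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) return(NULL)
  association_test(as_xtab(m, row_var = attr(xt, "row_var"),
                           col_var = attr(xt, "col_var")))
}

#' Study characteristics by S/G mention (Table 1 layout)
#'
#' Stacks [mention_breakdown()] blocks for study type, overall status,
#' enrolment group, HPV mention, HPV-relevant subsite group, and — for
#' interventional studies only — phase group.
#'
#' @param labels A labels tibble from [derive_labels()].
#' @return A tibble of stacked breakdown blocks.
#' @export
build_table1 <- function(labels) {
  blocks <- list(
    mention_breakdown(labels, "study_type"),
    mention_breakdown(labels, "status_group"),
    mention_breakdown(labels, "enrolment_group"),
    mention_breakdown(labels, "hpv_mention"),
    mention_breakdown(labels, "subsite_group"),
    mention_breakdown(labels, "phase_group",
                      filter = function(d) d$study_type == "interventional")
  )
  dplyr::bind_rows(blocks)
}

#' Characteristics of controlled vs uncontrolled studies (Table 2 layout)
#'
#' The Table-1 breakdowns computed separately within controlled and
#' uncontrolled studies, plus, per variable, the p-value comparing the
#' variable's distribution between the two control classes.
#'
#' @param labels A labels tibble from [derive_labels()].
#' @return A tibble with an extra `control_class` column and a
#'   `p_vs_other_class` column (per-variable controlled-vs-uncontrolled
#'   test).
#' @export
build_table2 <- function(labels) {
  vars <- c("study_type", "status_group", "enrolment_group", "hpv_mention",
            "phase_group")
  per_class <- function(cls) {
    keep <- labels$control_class == cls
    dplyr::bind_rows(lapply(vars, function(v) {
      filt <- if (v == "phase_group") {
        keep & labels$study_type == "interventional"
      } else keep
      if (sum(filt) == 0) return(NULL)
      mention_breakdown(labels, v, filter = filt)
    })) |>
      dplyr::mutate(control_class = cls, .before = 1)
  }
  out <- dplyr::bind_rows(per_class("controlled"), per_class("uncontrolled"))
  compare_p <- vapply(vars, function(v) {
    tst <- safe_association_test(crosstab(labels, v, "control_class"))
    if (is.null(tst)) NA_real_ else tst$p_value
  }, 0)
  out$p_vs_other_class <- unname(compare_p[out$variable])
  out
}

#' HPV mention by study characteristics within subsite groups (Table 3 layout)
#'
#' Within each subsite group (A: HPV-relevant sites; B: other), tabulates
#' HPV mention against each stratifier, with the per-variable association
#' test and, per level, the odds ratio of HPV mention versus the variable's
#' reference (first) level. The `a_vs_b` rows report, per level, the odds
#' ratio of HPV mention in group A versus group B among studies at that
#' level.
#'
#' @param labels A labels tibble from [derive_labels()].
#' @return A tibble with columns `subsite_group`, `variable`, `level`,
#'   `n`, `no_mention_n`, `mention_n`, `or`, `or_ci_low`, `or_ci_high`,
#'   `p_value`, and A-vs-B columns `a_vs_b_or`, `a_vs_b_ci_low`,
#'   `a_vs_b_ci_high`.
#' @export
build_table3 <- function(labels) {
  vars <- c("status_group", "study_type", "enrolment_group", "sg_category",
            "phase_group")
  hpv_col <- function(d) ifelse(d$hpv_mention, "mention", "no_mention")
  one_group <- function(grp) {
    keep <- labels$subsite_group == grp
    dplyr::bind_rows(lapply(vars, function(v) {
      filt <- if (v == "phase_group") {
        keep & labels$study_type == "interventional"
      } else keep
      d <- labels[filt, ]
      if (nrow(d) == 0) return(NULL)
      d$hpv <- hpv_col(d)
      xt <- crosstab(d, v, "hpv", col_levels = c("no_mention", "mention"))
      tst <- safe_association_test(xt)
      p <- if (is.null(tst)) NA_real_ else tst$p_value
      lvls <- rownames(xt)
      ors <- lapply(seq_along(lvls), function(i) {
        if (i == 1) return(list(NA_real_, NA_real_, NA_real_))
        cells <- unclass_xtab(xt)[c(i, 1), c("mention", "no_mention")]
        if (any(rowSums(cells) == 0) || any(colSums(cells) == 0)) {
          return(list(NA_real_, NA_real_, NA_real_))
        }
        o <- odds_ratio(as_xtab(cells, row_var = v, col_var = "hpv"))
        list(o$estimate, o$ci_low, o$ci_high)
      })
      tibble::tibble(
        subsite_group = grp, variable = v, level = lvls,
        n = unname(rowSums(xt)),
        no_mention_n = unname(unclass_xtab(xt)[, "no_mention"]),
        mention_n = unname(unclass_xtab(xt)[, "mention"]),
        or = vapply(ors, `[[`, 0, 1),
        or_ci_low = vapply(ors, `[[`, 0, 2),
        or_ci_high = vapply(ors, `[[`, 0, 3),
        p_value = p
      )
    }))
  }
  out <- dplyr::bind_rows(one_group("A_hpv_relevant"), one_group("B_other"))
  ab <- function(variable, level) {
    d <- labels[as.character(labels[[variable]]) == level, ]
    if (variable == "phase_group") d <- d[d$study_type == "interventional", ]
    d$hpv <- hpv_col(d)
    cells <- table(factor(d$subsite_group, c("A_hpv_relevant", "B_other")),
                   factor(d$hpv, c("mention", "no_mention")))
    if (any(rowSums(cells) == 0) || any(colSums(cells) == 0)) {
      return(c(NA_real_, NA_real_, NA_real_))
    }
    o <- odds_ratio(as_xtab(matrix(as.integer(cells), 2,
                                   dimnames = dimnames(cells)),
                            row_var = "subsite_group", col_var = "hpv"))
    c(o$estimate, o$ci_low, o$ci_high)
  }
  abm <- t(mapply(ab, out$variable, out$level))
  out$a_vs_b_or <- abm[, 1]
  out$a_vs_b_ci_low <- abm[, 2]
  out$a_vs_b_ci_high <- abm[, 3]
  out
}

#' Collapsed-mention odds ratio between two levels of a stratifier
#'
#' Builds the 2x2 of (level_hi vs level_lo) against (S/G mention vs no
#' mention) — mention pooling the analytical and recruitment-only
#' categories — and returns its [odds_ratio()]. This is the form behind
#' the headline comparisons, e.g. interventional vs observational.
#'
#' @param labels A labels tibble from [derive_labels()].
#' @param var Label column to compare on.
#' @param level_hi Level placed on the first row (numerator odds).
#' @param level_lo Reference level (second row).
#' @param filter Optional restriction (logical vector or predicate).
#' @return An `hnc_or`.
#' @export
#' @examples
#' \dontrun{
#' mention_odds_ratio(labels, "study_type", "interventional", "observational")
#' }
mention_odds_ratio <- function(labels, var, level_hi, level_lo, filter = NULL) {
  if (!is.null(filter)) {
    keep <- if (is.function(filter)) filter(labels) else filter
    labels <- labels[keep, ]
  }
  labels$mention <- collapse_mention(labels$sg_category)
  xt <- crosstab(labels, var, "mention",
                 row_levels = c(level_hi, level_lo),
                 col_levels = c("mention", "no_mention"))
  odds_ratio(xt)
}
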