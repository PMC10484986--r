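#' Match lexicon terms in free text
#'
#' Case-insensitive matching with per-term modes (see [lexicon()]). Word
#' characters are letters and digits; anything else — spaces, hyphens,
#' punctuation, the text edge — is a word boundary. Whitespace runs are
#' collapsed to single spaces before substring matching so multi-word
#' phrases match across line wraps. Each lexicon entry is reported at most
#' once per text.
#'
#' @param text Character vector of texts to scan.
#' @param lex A [lexicon()].
#' @return For a single text, a character vector of matched terms; for a
#'   vector of texts, a list of such vectors.
#' @export
#' @examples
#' match_terms("women and men were enrolled", sg_lexicon())
#' match_terms("human papillomavirus treatment", sg_lexicon())  # no hits
match_terms <- function(text, lex) {
  hits <- term_hit_matrix(text, lex)
  keys <- unique(lex$term)
  out <- lapply(seq_along(text), function(i) keys[hits[i, , drop = TRUE]])
  if (length(text) == 1) out[[1]] else out
}

# logical matrix: texts x unique terms (a term matching under any of its
# modes counts once)
term_hit_matrix <- function(text, lex) {
  text <- tolower(chr0(text))
  text <- stringr::str_replace_all(text, "\\s+", " ")
  keys <- unique(lex$term)
  m <- matrix(FALSE, nrow = length(text), ncol = length(keys),
              dimnames = list(NULL, keys))
  for (j in seq_len(nrow(lex))) {
    term <- lex$term[j]
    pat <- switch(lex$mode[j],
      whole_word  = paste0("(?<![a-z0-9])", escape_regex(term), "(?![a-z0-9])"),
      prefix_stem = paste0("(?<![a-z0-9])", escape_regex(term)),
      substring   = NULL
    )
    hit <- if (is.null(pat)) {
      stringr::str_detect(text, stringr::fixed(term))
    } else {
      stringr::str_detect(text, stringr::regex(pat))
    }
    m[, term] <- m[, term] | hit
  }
  m
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Classify a study's sex/gender mention
#'
#' The hierarchical three-way category:
#' * `analytical` — an S/G term occurs in at least one analysis section
#'   (titles, summaries, outcomes, design-group titles, intervention
#'   descriptions); dominates everything else;
#' * `recruitment_only` — S/G terms occur only in the eligibility sections
#'   (population, criteria);
#' * `no_mention` — no S/G term anywhere.
#'
#' The structured eligible-sex field ("All") is not itself a mention; only
#' free-text term hits count.
#'
#' @param sections A tibble from [section_map()] (any number of rows).
#' @param sg_lex The S/G [lexicon()]; default [sg_lexicon()].
#' @return A character vector (one value per row) with levels
#'   `analytical`, `recruitment_only`, `no_mention`.
#' @export
classify_sg <- function(sections, sg_lex = sg_lexicon()) {
  any_hit <- function(ids) {
    hit <- rep(FALSE, nrow(sections))
    for (s in ids) hit <- hit | rowSums(term_hit_matrix(sections[[s]], sg_lex)) > 0
    hit
  }
  in_analysis <- any_hit(analysis_sections())
  in_elig <- any_hit(eligibility_sections())
  dplyr::case_when(in_analysis ~ "analytical",
                   in_elig ~ "recruitment_only",
                   TRUE ~ "no_mention")
}

#' Detect HPV mention
#'
#' Scans all targeted sections plus the condition names (free-text and MeSH)
#' for any HPV lexicon entry.
#'
#' @param sections A tibble from [section_map()].
#' @param conditions List of character vectors of condition names, parallel
#'   to the rows of `sections` (free-text and browse conditions pooled).
#' @param hpv_lex The HPV [lexicon()]; default [hpv_lexicon()].
#' @return A logical vector, one value per study.
#' @export
detect_hpv <- function(sections, conditions = NULL, hpv_lex = hpv_lexicon()) {
  hit <- rep(FALSE, nrow(sections))
  for (s in setdiff(names(sections), "nct_id")) {
    hit <- hit | rowSums(term_hit_matrix(sections[[s]], hpv_lex)) > 0
  }
  if (!is.null(conditions)) {
    cond_txt <- vapply(conditions, paste, "", collapse = "\n")
    hit <- hit | rowSums(term_hit_matrix(cond_txt, hpv_lex)) > 0
  }
  hit
}

#' Assign the HPV-relevant subsite group
#'
#' Group A collects studies naming an oral cavity, oropharyngeal or
#' laryngeal cancer among their conditions — the subsites with an
#' established HPV aetiology — via the substrings in
#' [hpv_subsite_strings()]; everything else is group B.
#'
#' @param conditions List of character vectors of condition names (one
#'   element per study), or a single character vector for one study.
#' @return Character vector with levels `A_hpv_relevant`, `B_other`.
#' @export
#' @examples
#' assign_subsite_group(list(c("oropharyngeal carcinoma")))
assign_subsite_group <- function(conditions) {
  if (is.character(conditions)) conditions <- list(conditions)
  txt <- vapply(conditions, paste, "", collapse = "\n")
  ifelse(contains_any(txt, hpv_subsite_strings()), "A_hpv_relevant", "B_other")
}

#' Tag S/G, HPV and subsite for every study in a cohort
#'
#' Runs [classify_sg()], [detect_hpv()] and [assign_subsite_group()] over
#' the included studies and records which (section, term) pairs fired.
#'
#' @param registry An `hnc_registry`.
#' @param cohort Optional `hnc_cohort` from [select_cohort()]; when given,
#'   only included studies are tagged.
#' @param lexicons A list with elements `sg` and `hpv` (default the shipped
#'   lexicons).
#' @return A tibble with columns `nct_id`, `sg_category`, `hpv_mention`,
#'   `subsite_group`, and list-columns `sg_hits`, `hpv_hits` of
#'   (section, term) tibbles.
#' @export
tag_mentions <- function(registry, cohort = NULL,
                         lexicons = list(sg = sg_lexicon(), hpv = hpv_lexicon())) {
  if (!is.null(cohort)) {
    registry <- registry[registry$nct_id %in% cohort$nct_id[cohort$included], ]
  }
  sections <- section_map(registry)
  pooled <- purrr::map2(registry$conditions, registry$browse_conditions, c)

  hit_pairs <- function(lex, section_ids, extra_cond = FALSE) {
    per_section <- lapply(section_ids, function(s) {
      m <- term_hit_matrix(sections[[s]], lex)
      lapply(seq_len(nrow(m)), function(i) {
        terms <- colnames(m)[m[i, ]]
        if (length(terms) == 0) return(NULL)
        tibble::tibble(section = s, term = terms)
      })
    })
    if (extra_cond) {
      cond_txt <- vapply(pooled, paste, "", collapse = "\n")
      m <- term_hit_matrix(cond_txt, lex)
      per_section <- c(per_section, list(lapply(seq_len(nrow(m)), function(i) {
        terms <- colnames(m)[m[i, ]]
        if (length(terms) == 0) return(NULL)
        tibble::tibble(section = "conditions", term = terms)
      })))
    }
    lapply(seq_len(nrow(sections)), function(i) {
      parts <- purrr::compact(lapply(per_section, `[[`, i))
      if (length(parts) == 0) {
        tibble::tibble(section = character(0), term = character(0))
      } else {
        dplyr::bind_rows(parts)
      }
    })
  }

  all_sections <- c(analysis_sections(), eligibility_sections())
  tibble::tibble(
    nct_id = registry$nct_id,
    sg_category = classify_sg(sections, lexicons$sg),
    hpv_mention = detect_hpv(sections, pooled, lexicons$hpv),
    subsite_group = assign_subsite_group(pooled),
    sg_hits = hit_pairs(lexicons$sg, all_sections),
    hpv_hits = hit_pairs(lexicons$hpv, all_sections, extra_cond = TRUE)
  )
}
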