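#' Term lexicons
#'
#' A lexicon is a tibble with columns `term` (lower-case) and `mode`, one of
#' `"whole_word"`, `"prefix_stem"`, `"substring"`. Matching semantics:
#'
#' * `whole_word` — the term must be delimited by non-alphanumeric characters
#'   (or the text edge) on both sides; hyphens count as boundaries.
#' * `prefix_stem` — any word *beginning* with the stem matches ("pregnan"
#'   matches "pregnant", "pregnancy").
#' * `substring` — plain substring match anywhere, after whitespace
#'   normalisation (so multi-word phrases match across line wraps).
#'
#' All matching is case-insensitive.
#'
#' @param entries A data frame with columns `term` and `mode`.
#' @param name Lexicon name (used in messages and reports).
#' @return A `hnc_lexicon`: a tibble with columns `term`, `mode` and a
#'   `lexicon_name` attribute.
#' @export
#' @examples
#' lexicon(data.frame(term = c("sex", "pregnan"),
#'                    mode = c("whole_word", "prefix_stem")), name = "demo")
lexicon <- function(entries, name = "lexicon") {
  entries <- tibble::as_tibble(entries)
  if (!all(c("term", "mode") %in% names(entries)) || nrow(entries) == 0) {
    abort("A lexicon needs a non-empty data frame with columns `term` and `mode`.")
  }
  entries$term <- tolower(trimws(entries$term))
  entries$mode <- tolower(entries$mode)
  bad <- setdiff(unique(entries$mode), c("whole_word", "prefix_stem", "substring"))
  if (length(bad) > 0) {
    abort(paste0("Unknown lexicon mode(s): ", paste(bad, collapse = ", ")))
  }
  if (any(entries$term == "")) abort("Lexicon terms must be non-empty.")
  entries <- dplyr::distinct(entries, .data$term, .data$mode)
  structure(entries, class = c("hnc_lexicon", class(entries)),
            lexicon_name = name)
}

#' @export
print.hnc_lexicon <- function(x, ...) {
  cat("<lexicon '", attr(x, "lexicon_name"), "': ", nrow(x), " entries>\n", sep = "")
  NextMethod()
}

#' Default sex/gender term lexicon
#'
#' The S/G search terms: "sex", "gender", "woman", "women", "man", "men",
#' "female", "females", "male", "males", "girl", "girls", "boy", "boys",
#' plus the deliberately truncated stems "pregnan" and "transg". Full terms
#' are whole-word (substring matching of "man"/"men"/"male" would fire on
#' "human", "treatment", "females"); the two stems are prefix-stems.
#'
#' @return A [lexicon()].
#' @export
sg_lexicon <- function() {
  words <- c("sex", "gender", "woman", "women", "man", "men", "female",
             "females", "male", "males", "girl", "girls", "boy", "boys")
  lexicon(tibble::tibble(
    term = c(words, "pregnan", "transg"),
    mode = c(rep("whole_word", length(words)), "prefix_stem", "prefix_stem")
  ), name = "sg")
}

#' Default HPV term lexicon
#'
#' MeSH-derived HPV strings. Multi-word phrases are substrings (after
#' whitespace normalisation); bare "hpv" is carried both as a whole word and
#' as a substring so that "HPV16" and "HPV-positive" match. Duplicated
#' entries in the source string list are collapsed.
#'
#' @return A [lexicon()].
#' @export
hpv_lexicon <- function() {
  phrases <- c("human papillomavirus", "hpv human papillomavirus",
               "alphapapillomaviruses", "hpv human papillomaviruses",
               "papillomavirus, human", "human papillomaviruses, hpv",
               "papillomaviruses, human", "human papillomaviruses")
  lexicon(tibble::tibble(
    term = c(phrases, "hpv", "hpv"),
    mode = c(rep("substring", length(phrases)), "whole_word", "substring")
  ), name = "hpv")
}

# Condition-string rule sets (plain case-insensitive substrings).
neoplasm_strings <- function() {
  c("neopl", "cancer", "malignan", "tumor", "carcino", "onco")
}

hnc_region_strings <- function() {
  c("head", "neck", "mouth", "oral cavity", "pharynx", "larynx", "nose",
    "paranasal", "salivary", "uadt", "upper aerodigestive tract", "gingiva",
    "otorinolar", "tongue", "tonsil")
}

#' HPV-relevant subsite strings
#'
#' Condition substrings marking oral cavity, oropharyngeal and laryngeal
#' cancers, the subsites where HPV is an established risk factor:
#' "oral cavity", "pharyn", "laryn", "tonsil", "base of tongue".
#'
#' @return A character vector of lower-case substrings.
#' @export
hpv_subsite_strings <- function() {
  c("oral cavity", "pharyn", "laryn", "tonsil", "base of tongue")
}

#' Read / write a lexicon file
#'
#' Lexicon files are editable plain text: one entry per line,
#' `term<TAB>mode`. Lines starting with `#` and blank lines are ignored.
#'
#' @param path File path.
#' @param name Lexicon name; defaults to the file stem.
#' @return `read_lexicon()` returns a [lexicon()]; `write_lexicon()` returns
#'   `path` invisibly.
#' @export
read_lexicon <- function(path, name = NULL) {
  if (!file.exists(path)) abort(paste0("Lexicon file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- stringr::str_split_fixed(lines, "\t", 2)
  if (any(parts[, 2] == "")) {
    abort(paste0("Malformed lexicon line(s) in ", path, " (need term<TAB>mode)."))
  }
  lexicon(tibble::tibble(term = parts[, 1], mode = parts[, 2]),
          name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_lexicon
#' @param lex A [lexicon()].
#' @export
write_lexicon <- function(lex, path) {
  writeLines(paste(lex$term, lex$mode, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' Load the lexicon set used by the tagging stage
#'
#' @param dir Directory containing `sg_terms.txt` and `hpv_terms.txt`;
#'   `NULL` (default) uses the lexicons shipped with the package.
#' @return A named list with elements `sg` and `hpv`.
#' @export
load_lexicons <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- system.file("extdata", "lexicons", package = "hncmeta")
  }
  if (!dir.exists(dir)) abort(paste0("Lexicon directory not found: ", dir))
  list(sg  = read_lexicon(file.path(dir, "sg_terms.txt"), name = "sg"),
       hpv = read_lexicon(file.path(dir, "hpv_terms.txt"), name = "hpv"))
}
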