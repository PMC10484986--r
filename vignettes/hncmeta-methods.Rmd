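---
title: "Methods: quantifying sex/gender and HPV consideration in HNC trial registrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying sex/gender and HPV consideration in HNC trial registrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Registered clinical studies describe themselves in two very different
voices: structured fields (status, phase, allocation, eligible sex,
enrolment) and free text (titles, summaries, outcome measures, eligibility
criteria). Whether a study *plans to analyse* sex and/or gender (S/G) is
visible only in the free text — and where in the record a term appears
matters more than whether it appears. "Female" inside an outcome measure
signals an analytical intent; "females who are pregnant are excluded"
inside the eligibility criteria signals only a recruitment rule.

`hncmeta` operationalises this as a hierarchical, rule-based classifier
over an AACT-style relational export of ClinicalTrials.gov, followed by
standard contingency-table inference. The package deliberately contains no
NLP: no negation handling, no disambiguation of sex vs gender (the two are
treated as one undifferentiated term set), no stemming beyond two
deliberately truncated prefixes. The assumptions are therefore explicit
and auditable: a mention is a lexicon term occurring in a targeted
section, nothing more.

## Cohort selection

A condition name is a *neoplasm* if it contains one of six case-insensitive
substrings (`neopl`, `cancer`, `malignan`, `tumor`, `carcino`, `onco`) and
an *HNC condition* if it additionally contains one of fifteen head-neck
region strings. Both lists are applied as plain substrings because they are
stems by construction; no word-boundary guard is added (a string like
"head" could in principle over-match, but the neoplasm conjunction screens
out almost all such cases, and we add no guard the rule set does not
define). Note one sharp edge of the verbatim region list: it contains
`larynx`/`pharynx`, not the stems `laryn`/`pharyn`, so "laryngeal cancer"
does **not** qualify while "cancer of the larynx" does. The subsite lexicon
(below) uses the stems, so the two rule sets intentionally differ.

Free-text conditions and MeSH browse conditions are pooled, and the
HNC-condition index of a study is the fraction of its pooled condition
names that qualify. Inclusion requires index = 1 (HNC as the unique
investigated condition). Exclusions are then hierarchical: withdrawn or
terminated status first, single-sex eligibility last, so the gate counts
add exactly to the HNC-unique count. Studies with an empty condition list
have an undefined index and are treated as non-HNC with a warning.

## Mention tagging

Matching semantics are the core numerical choice of the package. Word
characters are letters and digits; any other character (hyphen included)
or the text edge is a boundary. The 14 full S/G terms match whole words
only — substring matching would fire on "hu**man**", "treat**men**t",
"fe**males**" and make category counts meaningless — while `pregnan` and
`transg` are prefix stems. HPV phrases are whitespace-normalised
substrings; bare `hpv` is carried both as a whole word and as a substring
so that "HPV16" and "HPV-positive" match. Each lexicon entry is counted at
most once per text. Lexicons ship as editable two-column text files.

The category hierarchy is strict: any S/G hit in an analysis section
(brief/official title, brief summary, detailed description, outcome
measures and descriptions, design-group titles, intervention descriptions)
makes the study *analytical*, regardless of eligibility hits; otherwise any
hit in the eligibility population/criteria makes it *recruitment-only*;
otherwise *no mention*. Two reading decisions were open and are resolved
as follows: design-group **titles** only are searched (descriptions are not
part of the targeted field list), and the HPV search runs over the targeted
sections plus condition names (not registry keyword tables). The
structured eligible-sex value "All" is not itself a mention — otherwise the
no-mention category would be empty by construction.

List-valued sections are concatenated with newlines before matching, so no
spurious word adjacency can arise at element joins.

## Design labels

Controlled means at least one arm typed Experimental / Active Comparator /
Placebo Comparator / Sham Comparator (case-insensitive exact label);
randomized means allocation exactly "Randomized"; enrolment dichotomises at
100 subjects with missing values pooled into the small group; phase
vocabulary collapses to five groups (with Phase 2 and Phase 3 joining
Phase 2/Phase 3 so the groups exhaust the registry vocabulary), and
observational studies are always phase not-applicable. Enrolment reads the
export's single enrolment column, which carries whichever of the
actual/anticipated counts the registry recorded. Submission year comes
from the first-submitted date.

## Inference

Tables are plain cross-tabulations; every study counts exactly once per
table. The test is Pearson's chi-square without continuity correction,
except on 2×2 tables with any expected cell below 5, where Fisher's exact
two-sided test (sum of hypergeometric probabilities no larger than the
observed table's) is used; an r×c table with a small expected cell still
gets Pearson, with a warning, since the exact r×c test is out of scope. The
selection rule is a convention of this package (the convention the field
defaults to), and reports always record which test ran. Degenerate strata
are handled by dropping empty rows/columns before testing; if fewer than
two informative levels remain the p-value is reported as `NA` rather than
an error (this happens by construction, e.g. controlled studies are all
interventional).

Odds ratios are the plain cross-product `ad/bc` with the Wald 95% interval
on the log scale (z = 1.96). This reproduces, to two decimals, every CI
pair derivable from the published cell counts ([4.29–7.72], [1.04–1.60],
[0.42–0.94]). When a single cell is zero the Haldane–Anscombe +0.5
correction is applied and flagged; a fully zero row or column is an error.
A small number of published ORs do not equal the cross-product of their
printed cells at two decimals; the cross-product is what this package
computes, and no attempt is made to reverse-engineer a different estimator.
The two-year trend comparison uses Fisher's exact test on the 2×2 of
stratum membership by year, chosen because per-year analytical counts are
small.

## The synthetic registry

The generator exists so that every stage has a planted ground truth. Its
defaults are fixed to the composition of the real cohort: 1952 screened
studies; ~14% withdrawn/terminated and ~0.4% single-sex; 84%
interventional, ~86% of those controlled and ~38% randomized; per-section
S/G injection rates tuned to yield roughly the 5% / 56% / 38% analytical /
recruitment-only / no-mention split; 17% HPV mention; 34% HPV-relevant
subsites; lognormal enrolment (meanlog log 50, sdlog 1.4; ~70% at ≤100
including 2% missing); status and phase multinomials matching the reported
marginals; submissions over 1999–2022 with increasing yearly weight
(index^1.5). The non-HNC fraction (5%) has no real-world analogue — the
real query had already screened for HNC — and exists purely to exercise
the first gate.

Sections are template sentences with insertion slots. Templates avoid
lexicon vocabulary except for controlled decoys ("human", "treatment",
"management", …) that embed S/G substrings without word boundaries; with
decoys at rate 1, whole-word matching still recovers planted labels
exactly, while a deliberately substring-configured matcher does not — that
asymmetry is itself a regression test of the boundary rule. One integer
seed drives everything; each study draws from a substream derived from
(seed, index), so generation is byte-identical across runs and independent
of evaluation order.

What passing these tests shows: the rules are implemented exactly, the
statistics agree with independent oracles (closed forms, exhaustive
enumeration), and the pipeline is deterministic. What it does not show:
that the lexicons capture how real protocols phrase sex and gender, or
that real AACT text is as clean as the templates — real registries contain
typos, multilingual fragments and idiosyncratic section usage that
rule-based matching will read literally. The published headline cohort
(1952 screened / 1672 included) depends on a specific 2022 registry
snapshot and is not reproducible from code alone; this package reproduces
the *method* and the statistics derivable from the published tables.

## Problem sizes

The validation suite uses synthetic registries of 40–600 studies for unit
properties and a single 5000-study registry for end-to-end recovery and
marginal-convergence checks (binomial tolerance, four standard errors);
the Fisher-vs-enumeration sweep covers all 5238 non-degenerate 2×2 tables
with every margin ≤ 12, and the Pearson closed-form check is exhaustive
over 2×2 tables with cells ≤ 5. These sizes make the whole suite run in
roughly two minutes on one CPU while keeping every check exact rather than
sampled where exhaustiveness is feasible.

## Known limitations

- Whole-word matching cannot see mentions split by line-wrap hyphenation,
  and prefix stems are only as good as their two chosen truncations.
- The subsite stems (`pharyn`, `laryn`) intentionally capture
  nasopharynx/hypopharynx; the narrower oropharynx-only reading would
  need a different lexicon, which users can supply as a file.
- Percentages and ORs are reported unadjusted; there is no multivariable
  modelling and no multiplicity correction, matching the univariable
  design of the analysis the package implements.
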