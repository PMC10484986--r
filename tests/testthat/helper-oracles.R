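# Independent oracles used to cross-check the implementation. These are
# deliberately written as naive scans/enumerations, sharing no code with
# the package internals.

# character-scanning term matcher
match_oracle <- function(text, term, mode) {
  text <- tolower(text)
  text <- gsub("[[:space:]]+", " ", text)
  term <- tolower(term)
  n <- nchar(text); k <- nchar(term)
  if (k == 0 || n < k) return(FALSE)
  is_word_char <- function(ch) grepl("[a-z0-9]", ch)
  for (i in seq_len(n - k + 1)) {
    if (substr(text, i, i + k - 1) != term) next
    if (mode == "substring") return(TRUE)
    left_ok <- i == 1 || !is_word_char(substr(text, i - 1, i - 1))
    right_ok <- (i + k) > n || !is_word_char(substr(text, i + k, i + k))
    if (mode == "prefix_stem" && left_ok) return(TRUE)
    if (mode == "whole_word" && left_ok && right_ok) return(TRUE)
  }
  FALSE
}

# two-sided Fisher p by full enumeration over margin-compatible tables
fisher_oracle <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  a_vals <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(a_vals, r1, r2, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# classical closed form for the Pearson statistic of a 2x2 table
pearson_closed_form <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}
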