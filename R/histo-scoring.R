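#' NAFLD activity score (NAS)
#'
#' Four ordinal features are graded 0-3 on H&E sections: macrovesicular
#' steatosis, microvesicular steatosis, hepatocellular hypertrophy and
#' inflammation. NAS is the unweighted sum of steatosis, hypertrophy and
#' inflammation, ranging 0-9. Because two steatosis subscores feed a single
#' steatosis term, they must be combined: the default takes
#' `max(macro, micro)` (preserves the 0-9 range and grades mixed-pattern
#' steatosis by its dominant component); `combine = "sum_capped"` instead
#' sums the two and caps at 3.
#'
#' @param macro,micro,hypertrophy,inflammation integer grades 0-3
#'   (vectorized).
#' @param combine `"max"` (default) or `"sum_capped"` rule for the steatosis
#'   term.
#' @return integer NAS in 0-9.
#' @export
nas <- function(macro, micro, hypertrophy, inflammation,
                combine = c("max", "sum_capped")) {
  combine <- match.arg(combine)
  for (nm in c("macro", "micro", "hypertrophy", "inflammation")) {
    v <- get(nm)
    if (!all(v %in% 0:3))
      stop_husphen("validation_error", "'%s' must be an integer grade in 0..3", nm)
  }
  steatosis <- switch(combine,
    max = pmax(macro, micro),
    sum_capped = pmin(macro + micro, 3L)
  )
  as.integer(steatosis + hypertrophy + inflammation)
}

#' Glomerular alteration grade
#'
#' Fraction of altered glomeruli (target 20 examined per mouse) mapped to an
#' ordinal grade: below 30% altered is grade 0, 30% to below 70% grade 1,
#' 70% or more grade 2 (the boundary fractions are assigned to the higher
#' grade).
#'
#' @param n_altered,n_examined counts (vectorized); `n_examined` > 0.
#' @return integer grade 0-2.
#' @export
renal_grade <- function(n_altered, n_examined) {
  if (any(n_examined == 0))
    stop_husphen("undefined_error", "'n_examined' must be > 0")
  if (any(n_altered < 0) || any(n_altered > n_examined))
    stop_husphen("validation_error", "'n_altered' must be in 0..n_examined")
  f <- n_altered / n_examined
  as.integer(ifelse(f >= 0.70, 2L, ifelse(f >= 0.30, 1L, 0L)))
}

#' Frequency table of histological scores per group
#'
#' Counts of each score level per group and percentages over the group size,
#' rounded to 2 decimals (so a 7-mouse group prints the familiar 14.29/42.86/
#' 85.71 sevenths).
#'
#' @param scores data frame with a grouping column and exactly one score
#'   column named either `nas` (levels 0-9), `renal` (levels 0-2),
#'   `saf` (levels 0-2) or `fibrosis` (levels absent/mild/moderate/severe).
#' @param group name of the grouping column (default `"group"`).
#' @return tibble `group, category, level, n, pct, pct_trunc` (rounded and
#'   truncated 2-decimal percentages; see [grade_frequency_table()]).
#' @export
score_frequencies <- function(scores, group = "group") {
  vocab_all <- list(nas = 0:9, renal = 0:2, saf = 0:2,
                    fibrosis = c("absent", "mild", "moderate", "severe"))
  kinds <- intersect(names(vocab_all), names(scores))
  if (length(kinds) != 1L)
    stop_husphen("type_error",
                 "'scores' must contain exactly one score column of %s (found: %s)",
                 paste(names(vocab_all), collapse = "/"),
                 if (length(kinds)) paste(kinds, collapse = ", ") else "none")
  kind <- kinds[[1]]
  bad <- !scores[[kind]] %in% vocab_all[[kind]]
  if (any(bad))
    stop_husphen("validation_error", "out-of-vocabulary %s score: %s",
                 kind, paste(unique(scores[[kind]][bad]), collapse = ", "))
  score_frequency_core(scores, group, vocab_all[kind])
}

#' One-tailed Pearson correlation across modalities
#'
#' Product-moment correlation between a histological score and an ultrasound
#' index (or any paired per-mouse variables), with the one-tailed p-value for
#' a positive association from the t distribution on n - 2 df (the
#' directional hypothesis being that liver damage seen on histology shows up
#' as higher ultrasound indices).
#'
#' @param x,y paired numeric (or ordinal-coded) vectors, n >= 3, no missing
#'   pairs.
#' @param alternative `"greater"` (default, positive association) or
#'   `"less"`.
#' @return tibble `r, t, df, p_one_tailed, n`.
#' @export
cross_modality_correlation <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y))
    stop_husphen("validation_error", "'x' and 'y' must be paired")
  if (anyNA(x) || anyNA(y))
    stop_husphen("validation_error", "missing pairs are not allowed")
  if (length(x) < 3)
    stop_husphen("validation_error", "need n >= 3 paired observations")
  if (sd_pop(x) == 0 || sd_pop(y) == 0)
    stop_husphen("undefined_correlation_error",
                 "zero variance in one of the variables")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = alternative)
  tibble::tibble(r = unname(ct$estimate), t = unname(ct$statistic),
                 df = unname(ct$parameter), p_one_tailed = ct$p.value,
                 n = length(x))
}
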