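comparison_result <- function(test_name, statistic, p_raw,
                              p_adjusted = NA_real_, adjustment = "none",
                              n_a, n_b, direction = NA_character_) {
  tibble::tibble(test_name = test_name, statistic = statistic,
                 p_raw = p_raw, p_adjusted = p_adjusted,
                 adjustment = adjustment, n_a = n_a, n_b = n_b,
                 direction = direction)
}

# U statistic of group a (count of (a, b) pairs with a > b, ties 1/2)
.u_stat <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Mann-Whitney U test (exact permutation or tie-corrected approximation)
#'
#' For combined sample sizes up to `exact_max_n` the two-sided p-value is
#' computed from the full permutation distribution of U (all
#' `choose(m+n, m)` group assignments of the pooled values, so ties are
#' handled exactly); larger samples use the normal approximation with tie
#' correction and continuity correction. Two-sidedness is defined by the
#' distance of U from its null mean `mn/2`.
#'
#' @param group_a,group_b numeric samples, each n >= 2.
#' @param exact_max_n switch point on the combined n (default 16).
#' @return a one-row comparison tibble: `test_name, statistic` (U of group
#'   a), `p_raw, p_adjusted, adjustment, n_a, n_b, direction`.
#' @export
mann_whitney <- function(group_a, group_b, exact_max_n = 16L) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop_husphen("validation_error", "each group needs n >= 2")
  m <- length(group_a); n <- length(group_b); N <- m + n
  pooled <- c(group_a, group_b)
  u <- .u_stat(group_a, group_b)
  center <- m * n / 2
  if (N <= exact_max_n) {
    # pooled ranks are invariant under permutation, so each assignment's U is
    # its rank-sum minus m(m+1)/2; enumerate all choose(N, m) assignments
    r_pool <- rank(pooled)
    idx <- combn(N, m)
    u_perm <- colSums(matrix(r_pool[idx], nrow = m)) - m * (m + 1) / 2
    dev <- abs(u_perm - center)
    p <- mean(dev >= abs(u - center) - 1e-12)
    method <- "mann_whitney_exact"
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    v <- (m * n / 12) * (N + 1 - tie_term)
    z <- (abs(u - center) - 0.5) / sqrt(v)
    p <- min(1, 2 * pnorm(-max(z, 0)))
    method <- "mann_whitney_approx"
  }
  comparison_result(method, u, p, n_a = m, n_b = n,
                    direction = if (u > center) "a_greater"
                                else if (u < center) "b_greater" else "none")
}

#' Wilcoxon signed-rank test for paired data
#'
#' Thin wrapper over [stats::wilcox.test()] with `paired = TRUE`, returned in
#' the same comparison-result shape as [mann_whitney()].
#'
#' @param x,y paired numeric samples of equal length (n >= 2).
#' @return a one-row comparison tibble.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop_husphen("validation_error", "'x' and 'y' must be paired, n >= 2")
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
  comparison_result("wilcoxon_signed_rank", unname(wt$statistic), wt$p.value,
                    n_a = length(x), n_b = length(y),
                    direction = if (median(x - y) > 0) "x_greater"
                                else if (median(x - y) < 0) "y_greater" else "none")
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for a family of `m` comparisons; never below the
#' raw p, and never above the Bonferroni bound `m p`.
#'
#' @param p raw p-values.
#' @param m family size (default `length(p)`).
#' @return adjusted p-values.
#' @export
sidak_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_husphen("validation_error", "p-values must be in [0, 1]")
  1 - (1 - p)^m
}

# Greenhouse-Geisser epsilon from a k x k within-subject covariance matrix,
# via an orthonormal contrast basis: eps = tr(A)^2 / ((k-1) tr(A^2))
.gg_epsilon <- function(S) {
  k <- nrow(S)
  C <- stats::contr.helmert(k)           # k x (k-1)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  A <- t(C) %*% S %*% C
  sum(diag(A))^2 / ((k - 1) * sum(A * A))
}

#' Repeated-measures two-way (mixed-design) ANOVA with Sidak post hoc
#'
#' Split-plot ANOVA for a longitudinal design: one between-subject factor
#' (diet) and one within-subject factor (age), subjects nested in diet.
#' Within-subject F tests (age and age x diet) are reported with
#' Greenhouse-Geisser-corrected fractional degrees of freedom, the epsilon
#' being estimated from the pooled within-group covariance of the
#' subject-by-timepoint matrix (complete cases). Subjects missing any
#' timepoint are dropped with a message (complete-case analysis). Per
#' timepoint, the two diet groups are then contrasted by Welch t tests with
#' Sidak adjustment over the number of timepoints.
#'
#' @param data long-format data frame.
#' @param value,subject,between,within column names (defaults `"value"`,
#'   `"mouse_id"`, `"diet"`, `"age_weeks"`).
#' @param posthoc run the per-timepoint contrasts (requires exactly 2
#'   between-group levels).
#' @return list with `anova` (tibble: effect, df1, df2, statistic, p,
#'   epsilon, df1_gg, df2_gg, p_gg), `posthoc` (tibble per timepoint),
#'   `n_subjects_used`, `n_subjects_dropped`.
#' @export
rm_mixed_anova <- function(data, value = "value", subject = "mouse_id",
                           between = "diet", within = "age_weeks",
                           posthoc = TRUE) {
  df <- data.frame(y = data[[value]],
                   S = factor(data[[subject]]),
                   B = factor(data[[between]]),
                   W = factor(data[[within]]))
  if (anyNA(df$y)) df <- df[!is.na(df$y), ]
  # a subject must sit under a single between-group level
  tab <- table(df$S, df$B) > 0
  if (any(rowSums(tab) > 1))
    stop_husphen("design_error", "subject(s) appear under both diets: %s",
                 paste(rownames(tab)[rowSums(tab) > 1], collapse = ", "))
  k <- nlevels(df$W)
  if (k < 2)
    stop_husphen("validation_error", "need >= 2 within-factor levels")
  complete <- names(which(tapply(df$W, df$S, function(w) length(unique(w))) == k))
  dropped <- setdiff(levels(df$S), complete)
  if (length(dropped)) {
    message(sprintf("dropping %d subject(s) with incomplete series: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
    df <- df[df$S %in% complete, ]
    df$S <- droplevels(df$S)
    df$B <- droplevels(df$B)
  }
  if (any(table(unique(df[c("S", "B")])$B) < 2))
    stop_husphen("validation_error", "need >= 2 complete subjects per group")

  fit <- aov(y ~ B * W + Error(S), data = df)
  s <- summary(fit)
  get_tab <- function(stratum) {
    t <- s[[stratum]][[1]]
    rownames(t) <- trimws(rownames(t))
    t
  }
  tb <- get_tab("Error: S"); tw <- get_tab("Error: Within")

  # pooled within-group covariance of the subject x time matrix
  wide <- tapply(df$y, list(df$S, df$W), mean)
  grp <- df$B[match(rownames(wide), df$S)]
  S_pool <- matrix(0, k, k); wsum <- 0
  for (g in levels(grp)) {
    X <- wide[grp == g, , drop = FALSE]
    if (nrow(X) >= 2) {
      S_pool <- S_pool + stats::cov(X) * (nrow(X) - 1)
      wsum <- wsum + nrow(X) - 1
    }
  }
  eps <- if (wsum > 0 && sum(abs(S_pool)) > 1e-12) .gg_epsilon(S_pool / wsum) else 1

  row_of <- function(t, effect, err_row, epsilon = NA_real_) {
    ss <- t[effect, "Sum Sq"]; dfe <- t[effect, "Df"]
    ssr <- t[err_row, "Sum Sq"]; dfr <- t[err_row, "Df"]
    tol <- 1e-12 * max(1, abs(sum(df$y^2)))
    if (ss <= tol) {
      f <- 0; p <- 1; pgg <- 1
    } else if (ssr <= tol) {
      f <- Inf; p <- 1e-15; pgg <- 1e-15    # perfectly deterministic effect
    } else {
      f <- (ss / dfe) / (ssr / dfr)
      p <- pf(f, dfe, dfr, lower.tail = FALSE)
      pgg <- if (!is.na(epsilon)) pf(f, dfe * epsilon, dfr * epsilon,
                                     lower.tail = FALSE) else NA_real_
    }
    tibble::tibble(effect = effect, df1 = dfe, df2 = dfr, statistic = f, p = p,
                   epsilon = epsilon,
                   df1_gg = if (is.na(epsilon)) NA_real_ else dfe * epsilon,
                   df2_gg = if (is.na(epsilon)) NA_real_ else dfr * epsilon,
                   p_gg = if (is.na(epsilon)) p else pgg)
  }
  anova_tab <- dplyr::bind_rows(
    row_of(tb, "B", "Residuals"),
    row_of(tw, "W", "Residuals", eps),
    row_of(tw, "B:W", "Residuals", eps)
  )
  anova_tab$effect <- c(between, within, paste0(within, ":", between))

  ph <- NULL
  if (posthoc && nlevels(df$B) == 2) {
    lv <- levels(df$B)
    rows <- lapply(levels(df$W), function(w) {
      a <- df$y[df$W == w & df$B == lv[1]]
      b <- df$y[df$W == w & df$B == lv[2]]
      if (sd_pop(a) == 0 && sd_pop(b) == 0) {
        # both groups constant: identical means are a null result, distinct
        # means a deterministic separation
        same <- isTRUE(all.equal(mean(a), mean(b)))
        tibble::tibble(within_level = w, estimate = mean(a) - mean(b),
                       statistic = if (same) 0 else Inf, df = NA_real_,
                       p_raw = if (same) 1 else 1e-15)
      } else {
        tt <- stats::t.test(a, b)
        tibble::tibble(within_level = w, estimate = mean(a) - mean(b),
                       statistic = unname(tt$statistic),
                       df = unname(tt$parameter), p_raw = tt$p.value)
      }
    })
    ph <- dplyr::bind_rows(rows)
    ph$p_adjusted <- sidak_adjust(ph$p_raw, m = k)
    ph$adjustment <- "sidak"
  }
  list(anova = anova_tab, posthoc = ph,
       n_subjects_used = nlevels(df$S), n_subjects_dropped = length(dropped))
}

#' Per-subject change from baseline
#'
#' Subtracts each subject's baseline (earliest within-level) value from its
#' later values; baseline rows are dropped. Used where groups already differ
#' at baseline, so comparisons run on the magnitude of change.
#'
#' @param data long-format data frame.
#' @param value,subject,within column names (defaults as in
#'   [rm_mixed_anova()]).
#' @return tibble like `data` restricted to post-baseline rows, with the
#'   value column replaced by the delta.
#' @export
change_from_baseline <- function(data, value = "value", subject = "mouse_id",
                                 within = "age_weeks") {
  base_lv <- min(data[[within]])
  out <- lapply(split(seq_len(nrow(data)), data[[subject]]), function(i) {
    sub <- data[i, , drop = FALSE]
    bi <- which(sub[[within]] == base_lv)
    if (length(bi) != 1L)
      stop_husphen("missing_data_error", "subject '%s' lacks the baseline timepoint",
                   as.character(sub[[subject]][1]))
    sub[[value]] <- sub[[value]] - sub[[value]][bi]
    sub[-bi, , drop = FALSE]
  })
  tibble::as_tibble(dplyr::bind_rows(out))
}

#' A priori sample size for a two-group mean comparison
#'
#' Normal-approximation (z-based) two-sided formula:
#' `n = ceil(2 sd^2 (z_{1-alpha/2} + z_{power})^2 / delta^2)` per group, with
#' `delta = mean_ref - mean_test`, then inflated for expected attrition. The
#' study design detects a 30% difference (reference mean 100, test mean 70)
#' with SD 20, alpha 0.05, power 0.80 and 10% attrition, giving groups of
#' 7-8.
#'
#' @param mean_ref,mean_test group means on a 100-reference scale.
#' @param sd common standard deviation (same scale).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param attrition_inflation fractional inflation for expected attrition.
#' @return list `n_per_group`, `n_inflated`, `n_raw` (pre-ceiling).
#' @export
sample_size_ttest <- function(mean_ref = 100, mean_test = 70, sd = 20,
                              alpha = 0.05, power = 0.80,
                              attrition_inflation = 0.10) {
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop_husphen("validation_error", "alpha and power must be in (0, 1)")
  assert_scalar_number(sd, "sd", 0, strict_min = TRUE)
  delta <- mean_ref - mean_test
  if (delta == 0)
    stop_husphen("infeasible_error", "zero difference between means")
  n_raw <- 2 * sd^2 * (qnorm(1 - alpha / 2) + qnorm(power))^2 / delta^2
  n <- ceiling(n_raw)
  list(n_per_group = n, n_inflated = ceiling(n * (1 + attrition_inflation)),
       n_raw = n_raw)
}

#' Significance stars at the study's thresholds
#'
#' @param p p-values.
#' @return character: `****` p < 0.0001, `***` p < 0.001, `**` p < 0.01,
#'   `*` p < 0.05, empty otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}

#' Per-group mean +/- SD summary table
#'
#' @param data data frame.
#' @param value_cols names of the numeric columns to summarize.
#' @param group_cols names of the grouping columns.
#' @return tibble: grouping columns, `variable`, `n`, `mean`, `sd` and a
#'   formatted `mean_sd` string.
#' @export
group_summary <- function(data, value_cols, group_cols) {
  long <- tidyr::pivot_longer(data[c(group_cols, value_cols)],
                              dplyr::all_of(value_cols),
                              names_to = "variable", values_to = ".v")
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_cols, "variable")))) |>
    dplyr::summarise(n = sum(!is.na(.data$.v)),
                     mean = mean(.data$.v, na.rm = TRUE),
                     sd = stats::sd(.data$.v, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(mean_sd = sprintf("%.2f ± %.2f", .data$mean, .data$sd))
}

#' Assemble the study report tables
#'
#' Combines the stage outputs into the report layout used for diet studies:
#' per-group mean +/- SD tables of the derived variables, the ordinal score
#' frequency tables, and the comparison table annotated with significance
#' stars at the thresholds 0.05 / 0.01 / 0.001 / 0.0001.
#'
#' @param cohort_derived data frame of derived per-mouse variables (required,
#'   non-empty).
#' @param value_cols numeric columns of `cohort_derived` to summarize.
#' @param group_cols grouping columns (default sex, diet, age_weeks).
#' @param score_tables optional named list of frequency tables (from
#'   [grade_frequency_table()] / [score_frequencies()]); passed through.
#' @param comparisons optional comparison tibble with a p-value column
#'   (`p_adjusted` used when present and non-NA, else `p_raw`).
#' @return list of class `"husphen_report"`: `summary`, `scores`,
#'   `comparisons` (with `stars`).
#' @export
build_report <- function(cohort_derived, value_cols,
                         group_cols = c("sex", "diet", "age_weeks"),
                         score_tables = list(), comparisons = NULL) {
  if (missing(cohort_derived) || is.null(cohort_derived))
    stop_husphen("dependency_error", "missing stage output: 'cohort_derived'")
  if (nrow(cohort_derived) == 0)
    stop_husphen("validation_error", "'cohort_derived' is empty")
  missing_cols <- setdiff(c(value_cols, group_cols), names(cohort_derived))
  if (length(missing_cols))
    stop_husphen("dependency_error", "missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
  comp <- comparisons
  if (!is.null(comp)) {
    p_use <- if ("p_adjusted" %in% names(comp) && any(!is.na(comp$p_adjusted)))
      ifelse(is.na(comp$p_adjusted), comp$p_raw, comp$p_adjusted)
    else comp$p_raw
    comp$stars <- significance_stars(p_use)
  }
  structure(list(summary = group_summary(cohort_derived, value_cols, group_cols),
                 scores = score_tables, comparisons = comp),
            class = "husphen_report")
}

#' @export
print.husphen_report <- function(x, ...) {
  cat("<husphen_report>\n-- group summary --\n")
  print(x$summary, n = 20)
  if (length(x$scores)) {
    cat("-- score tables:", paste(names(x$scores), collapse = ", "), "--\n")
  }
  if (!is.null(x$comparisons)) {
    cat("-- comparisons --\n")
    print(x$comparisons)
  }
  invisible(x)
}
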