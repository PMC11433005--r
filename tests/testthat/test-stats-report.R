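test_that("exact Mann-Whitney matches the exhaustive-permutation oracle", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_raw, 0.1)            # 2/20 assignments as extreme
  # identical groups: p = 1 by symmetry
  expect_equal(mann_whitney(c(5, 6, 7), c(5, 6, 7))$p_raw, 1.0)
  # property: all group splits with combined n <= 10, with and without ties
  set.seed(101)
  for (i in 1:12) {
    N <- sample(5:10, 1); m <- sample(2:(N - 2), 1)
    vals <- if (i %% 2) rnorm(N) else sample(1:4, N, replace = TRUE)
    a <- vals[1:m]; b <- vals[-(1:m)]
    expect_equal(mann_whitney(a, b)$p_raw, oracle_mw_p(a, b),
                 info = sprintf("case %d (m=%d, N=%d)", i, m, N))
  }
  expect_error(mann_whitney(numeric(0), 1:3), class = "validation_error")
})

test_that("exact and approximate Mann-Whitney p agree for 8 vs 8 untied data", {
  set.seed(7)
  a <- rnorm(8); b <- rnorm(8, 1)
  p_exact <- mann_whitney(a, b)$p_raw
  p_approx <- mann_whitney(a, b, exact_max_n = 0)$p_raw
  expect_lt(abs(p_exact - p_approx), 0.02)
  # and both agree with the independent reference implementation
  p_ref <- stats::wilcox.test(a, b, exact = TRUE)$p.value
  expect_equal(p_exact, p_ref, tolerance = 1e-12)
})

test_that("Sidak adjustment sits between the raw p and the Bonferroni bound", {
  p <- c(0.001, 0.01, 0.04, 0.2, 0.5)
  for (m in c(1, 3, 9, 17)) {
    adj <- sidak_adjust(p, m)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= pmin(1, m * p) + 1e-12))   # Sidak <= Bonferroni
    if (m == 1) expect_equal(adj, p)
  }
  expect_equal(sidak_adjust(0.05, 3), 1 - 0.95^3)
  bonf <- p.adjust(p, "bonferroni")                   # reference bound
  expect_true(all(sidak_adjust(p, length(p)) <= bonf + 1e-12))
})

test_that("degenerate repeated-measures designs give F = 0 or the infinity guard", {
  base <- expand.grid(mouse_id = paste0("m", 1:8), age_weeks = c(8, 16, 24))
  base$diet <- ifelse(as.integer(sub("m", "", base$mouse_id)) <= 4, "SD", "WD")
  # all values equal: every F 0, p 1
  d0 <- base; d0$value <- 5
  a0 <- rm_mixed_anova(d0)$anova
  expect_true(all(a0$statistic == 0))
  expect_true(all(a0$p == 1))
  # purely additive effects without noise: diet F -> infinity guard,
  # interaction F = 0
  d1 <- base
  d1$value <- 10 + 2 * (d1$diet == "WD") + 0.5 * d1$age_weeks
  a1 <- rm_mixed_anova(d1)$anova
  expect_true(is.infinite(a1$statistic[a1$effect == "diet"]))
  expect_lt(a1$p[a1$effect == "diet"], 1e-12)
  expect_equal(a1$statistic[a1$effect == "age_weeks:diet"], 0)
})

test_that("mixed ANOVA recovers known effects and GG-corrects within dfs", {
  set.seed(42)
  d <- expand.grid(mouse_id = paste0("m", 1:16), age_weeks = c(8, 16, 24))
  d$diet <- ifelse(as.integer(sub("m", "", d$mouse_id)) <= 8, "SD", "WD")
  d$value <- 20 + 3 * (d$diet == "WD") + 0.2 * d$age_weeks + rnorm(nrow(d))
  res <- rm_mixed_anova(d)
  expect_lt(res$anova$p[res$anova$effect == "diet"], 0.01)
  expect_lt(res$anova$p_gg[res$anova$effect == "age_weeks"], 0.001)
  eps <- res$anova$epsilon[2]
  expect_true(eps > 1 / (3 - 1) - 1e-9 && eps <= 1 + 1e-9)  # GG bounds for k=3
  expect_equal(res$anova$df1_gg[2], res$anova$df1[2] * eps)
  # post hoc: one Sidak-adjusted contrast per timepoint
  expect_equal(nrow(res$posthoc), 3)
  expect_true(all(res$posthoc$p_adjusted >= res$posthoc$p_raw))
  expect_equal(res$posthoc$p_adjusted, sidak_adjust(res$posthoc$p_raw, 3))
})

test_that("incomplete subjects are dropped and cross-diet subjects rejected", {
  d <- expand.grid(mouse_id = paste0("m", 1:8), age_weeks = c(8, 16, 24))
  d$diet <- ifelse(as.integer(sub("m", "", d$mouse_id)) <= 4, "SD", "WD")
  set.seed(1); d$value <- rnorm(nrow(d), 20)
  d_miss <- d[!(d$mouse_id == "m3" & d$age_weeks == 24), ]
  expect_message(res <- rm_mixed_anova(d_miss), "m3")
  expect_equal(res$n_subjects_used, 7)
  expect_equal(res$n_subjects_dropped, 1)
  d_bad <- d; d_bad$diet[d_bad$mouse_id == "m2" & d_bad$age_weeks == 24] <- "WD"
  expect_error(rm_mixed_anova(d_bad), class = "design_error")
})

test_that("mixed ANOVA type-I error is calibrated on null data", {
  # no effects, n = 8/group, 3 timepoints: diet rejections at alpha = 0.05
  # should land in 0.05 +/- 0.02 over 1000 simulations
  base <- expand.grid(mouse_id = paste0("m", 1:16), age_weeks = c(8, 16, 24))
  base$diet <- ifelse(as.integer(sub("m", "", base$mouse_id)) <= 8, "SD", "WD")
  set.seed(2024)
  rej <- vapply(1:1000, function(i) {
    base$value <- rnorm(nrow(base))
    rm_mixed_anova(base, posthoc = FALSE)$anova$p[1] < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03); expect_lte(mean(rej), 0.07)
})

test_that("change from baseline drops baseline rows and is shift-invariant", {
  d <- tibble::tibble(mouse_id = rep(c("a", "b"), each = 3),
                      age_weeks = rep(c(8, 16, 24), 2),
                      value = c(10, 14, 13, 20, 20, 20))
  ch <- change_from_baseline(d)
  expect_equal(ch$value[ch$mouse_id == "a"], c(4, 3))
  expect_equal(ch$value[ch$mouse_id == "b"], c(0, 0))
  expect_false(any(ch$age_weeks == 8))
  d2 <- d; d2$value[d2$mouse_id == "a"] <- d2$value[d2$mouse_id == "a"] + 100
  expect_equal(change_from_baseline(d2)$value, ch$value)
  expect_error(change_from_baseline(d[-1, ]), class = "missing_data_error")
})

test_that("a priori sample size reproduces the 7-8 per group design", {
  ss <- sample_size_ttest()
  expect_equal(ss$n_per_group, 7)
  expect_equal(ss$n_inflated, 8)
  expect_lt(abs(ss$n_raw - 6.98), 0.01)
  # n scales with sd^2 before the ceiling
  expect_equal(sample_size_ttest(sd = 40)$n_raw, 4 * ss$n_raw)
  # monotone decreasing in the detectable difference
  n_by_delta <- vapply(c(10, 20, 30, 40),
                       function(d) sample_size_ttest(mean_test = 100 - d)$n_raw,
                       numeric(1))
  expect_true(all(diff(n_by_delta) < 0))
  # monotone non-decreasing in power and sd
  expect_gte(sample_size_ttest(power = 0.9)$n_per_group, ss$n_per_group)
  expect_gte(sample_size_ttest(sd = 25)$n_per_group, ss$n_per_group)
  expect_error(sample_size_ttest(mean_test = 100), class = "infeasible_error")
})

test_that("wilcoxon signed-rank wrapper mirrors the comparison contract", {
  set.seed(3)
  x <- rnorm(10); y <- x + 1
  res <- wilcoxon_signed_rank(x, y)
  expect_equal(res$test_name, "wilcoxon_signed_rank")
  expect_lt(res$p_raw, 0.01)
  expect_equal(res$direction, "y_greater")
  expect_error(wilcoxon_signed_rank(1:3, 1:4), class = "validation_error")
})

test_that("report assembly summarizes groups and stars comparisons", {
  co <- generate_cohort(cohort_config(n_per_group = 4, ages_weeks = c(8L, 16L, 24L),
                                      seed = 3))
  comp <- mann_whitney(co$bw[co$diet == "SD" & co$age_weeks == 24],
                       co$bw[co$diet == "WD" & co$age_weeks == 24])
  rep <- build_report(co, value_cols = c("bw", "food_intake_daily"),
                      comparisons = comp)
  expect_s3_class(rep, "husphen_report")
  expect_setequal(unique(rep$summary$variable), c("bw", "food_intake_daily"))
  expect_true(all(c("mean", "sd", "mean_sd") %in% names(rep$summary)))
  expect_true(rep$comparisons$stars %in% c("", "*", "**", "***", "****"))
  expect_error(build_report(co[0, ], "bw"), class = "validation_error")
  expect_error(build_report(co, "not_a_column"), class = "dependency_error")
  expect_error(build_report(NULL, "bw"), class = "dependency_error")
})

test_that("null cohorts produce no significance stars in most seeds", {
  # zero-effect cohorts: a starred endpoint comparison should appear in
  # well under half of seeds (binomially ~5% per variable)
  starred <- vapply(1:40, function(s) {
    co <- generate_cohort(cohort_config(
      n_per_group = 8, sexes = "male", ages_weeks = c(8L, 24L), seed = s,
      effects = cohort_effects(null = TRUE)))
    endpoint <- co[co$age_weeks == 24, ]
    comp <- mann_whitney(endpoint$bw[endpoint$diet == "SD"],
                         endpoint$bw[endpoint$diet == "WD"])
    rep <- build_report(endpoint, "bw", group_cols = c("sex", "diet"),
                        comparisons = comp)
    any(rep$comparisons$stars != "")
  }, logical(1))
  expect_lte(mean(starred), 0.10)
})
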