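# shared fixture builders; everything is generated in code, no files

tiny_cohort_config <- function(...) {
  cohort_config(n_per_group = 3, ages_weeks = c(8L, 10L, 12L), seed = 42L, ...)
}

# uniform-intensity image for exact-ROI arithmetic
uniform_image <- function(value, nr = 200, nc = 200, spacing = 0.02) {
  bmode_image(matrix(value, nr, nc), spacing)
}

# one-mouse weekly records for the metabolic ops
mouse_records <- function(weeks, bw, intake_daily = rep(3, length(weeks)),
                          kcal_per_g = 3.150) {
  tibble::tibble(age_weeks = weeks, bw = bw,
                 food_intake_daily = intake_daily, kcal_per_g = kcal_per_g)
}

# brute-force two-sided Mann-Whitney p by exhaustive enumeration, written
# independently of the package's implementation (loops, no rank shortcut)
oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a); N <- length(pooled)
  u_of <- function(x, y) {
    u <- 0
    for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
  }
  u_obs <- u_of(a, b)
  center <- m * (N - m) / 2
  combs <- utils::combn(N, m)
  devs <- numeric(ncol(combs))
  for (j in seq_len(ncol(combs))) {
    i <- combs[, j]
    devs[j] <- abs(u_of(pooled[i], pooled[-i]) - center)
  }
  mean(devs >= abs(u_obs - center) - 1e-12)
}
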