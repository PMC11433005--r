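#' Effect-size configuration for the synthetic cohort generator
#'
#' Bundles every distributional parameter the cohort generator uses: baseline
#' body weight and growth slopes per sex and diet, food intake with a
#' transient hyperphagia window after the diet switch, and endpoint shifts of
#' the blood-chemistry panel under the Western-type diet (WD) relative to the
#' standard diet (SD). All values are mean/SD pairs in the variable's own
#' units (g, g/week, g/day, mg/dL, U/L, ng/mL).
#'
#' Defaults emulate a C57Bl/6J diet-induced-obesity study: males heavier than
#' females, WD roughly doubling the weekly weight-gain slope, transient
#' hyperphagia in the first two weeks on WD, and endpoint hyperglycemia,
#' hypercholesterolemia, transaminase elevation and hyperinsulinemia in the
#' WD groups.
#'
#' @param null logical; if `TRUE`, all diet effects are removed (equal slopes,
#'   zero WD shifts) while between/within-mouse variability is kept, giving a
#'   null cohort for type-I-error calibration.
#' @param zero_noise logical; if `TRUE`, every SD is set to 0 so the generator
#'   is fully deterministic given the config.
#' @return A named list of effect parameters, class `"cohort_effects"`.
#' @export
cohort_effects <- function(null = FALSE, zero_noise = FALSE) {
  eff <- list(
    bw_baseline = list(male = c(mean = 22.5, sd = 1.2),
                       female = c(mean = 18.0, sd = 1.0)),
    bw_slope = list(
      male_SD   = c(mean = 0.35, sd = 0.06),
      male_WD   = c(mean = 0.70, sd = 0.08),
      female_SD = c(mean = 0.22, sd = 0.05),
      female_WD = c(mean = 0.42, sd = 0.06)
    ),
    bw_noise_sd = 0.5,                       # residual within-mouse scatter, g
    intake_base = list(male = c(mean = 3.4, sd = 0.25),
                       female = c(mean = 3.0, sd = 0.22)),
    intake_noise_sd = 0.20,
    hyperphagia = list(weeks = c(8L, 10L), delta = c(mean = 0.8, sd = 0.2)),
    biochem_weeks = c(8L, 16L, 24L),
    endpoint_only = c("alt", "ast", "bun", "insulin", "liver_weight"),
    biochem = list(
      # base = all mice at every biochem week; wd_shift applied to WD at the
      # final (fasting) timepoint only
      glucose       = list(base = c(mean = 160, sd = 20), wd_shift = c(mean = 60, sd = 15)),
      cholesterol   = list(base = c(mean = 90,  sd = 15), wd_shift = c(mean = 70, sd = 15)),
      triglycerides = list(base = c(mean = 80,  sd = 15), wd_shift = c(mean = 30, sd = 10)),
      alt           = list(base = c(mean = 30,  sd = 8),  wd_shift = c(mean = 25, sd = 10)),
      ast           = list(base = c(mean = 60,  sd = 15), wd_shift = c(mean = 20, sd = 10)),
      bun           = list(base = c(mean = 20,  sd = 4),  wd_shift = c(mean = 2,  sd = 2)),
      insulin       = list(base = c(mean = 0.6, sd = 0.2), wd_shift = c(mean = 0.8, sd = 0.3))
    ),
    liver_weight = list(base = c(mean = 1.10, sd = 0.12), wd_shift = c(mean = 0.25, sd = 0.10)),
    bcs_wd_shift_week = 16L,                 # WD body condition score +1 from here
    kcal_per_g = c(SD = 3.150, WD = 4.2594)
  )
  if (null) {
    for (s in c("male", "female")) {
      eff$bw_slope[[paste0(s, "_WD")]] <- eff$bw_slope[[paste0(s, "_SD")]]
    }
    eff$hyperphagia$delta["mean"] <- 0
    for (a in names(eff$biochem)) eff$biochem[[a]]$wd_shift["mean"] <- 0
    eff$liver_weight$wd_shift["mean"] <- 0
    eff$bcs_wd_shift_week <- NA_integer_
  }
  if (zero_noise) {
    zap <- function(x) { x["sd"] <- 0; x }
    eff$bw_baseline <- lapply(eff$bw_baseline, zap)
    eff$bw_slope <- lapply(eff$bw_slope, zap)
    eff$bw_noise_sd <- 0
    eff$intake_base <- lapply(eff$intake_base, zap)
    eff$intake_noise_sd <- 0
    eff$hyperphagia$delta <- zap(eff$hyperphagia$delta)
    eff$biochem <- lapply(eff$biochem, function(b) lapply(b, zap))
    eff$liver_weight <- lapply(eff$liver_weight, zap)
  }
  structure(eff, class = "cohort_effects")
}

#' Configuration for a synthetic longitudinal cohort
#'
#' @param n_per_group mice per sex-by-diet group (>= 2).
#' @param sexes subset of `c("male", "female")`.
#' @param diets subset of `c("SD", "WD")` (standard vs Western-type diet).
#' @param ages_weeks strictly increasing integer vector of ages (weeks) at
#'   which body weight and intake are recorded. Default 8 to 24 weeks.
#' @param seed integer seed; identical configs with identical seeds give
#'   byte-identical cohorts.
#' @param effects a [cohort_effects()] object.
#' @param attrition_prob per-mouse probability of dropping out; a dropout
#'   removes all records after a uniformly chosen non-baseline week
#'   (missing-at-random truncation).
#' @return A validated config, class `"cohort_config"`.
#' @export
cohort_config <- function(n_per_group = 8L,
                          sexes = c("male", "female"),
                          diets = c("SD", "WD"),
                          ages_weeks = 8:24,
                          seed = 1L,
                          effects = cohort_effects(),
                          attrition_prob = 0) {
  if (!is.numeric(n_per_group) || length(n_per_group) != 1L || n_per_group < 2)
    stop_husphen("validation_error", "'n_per_group' must be a single count >= 2")
  if (!all(sexes %in% c("male", "female")) || length(sexes) < 1)
    stop_husphen("validation_error", "'sexes' must be a subset of male/female")
  if (!all(diets %in% c("SD", "WD")) || length(diets) < 1)
    stop_husphen("validation_error", "'diets' must be a subset of SD/WD")
  if (length(ages_weeks) < 1 || any(diff(ages_weeks) <= 0))
    stop_husphen("validation_error", "'ages_weeks' must be strictly increasing")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_husphen("validation_error", "'seed' must be a single integer")
  if (!inherits(effects, "cohort_effects"))
    stop_husphen("validation_error", "'effects' must be built by cohort_effects()")
  sds <- unlist(effects)[grepl("\\.sd$|noise_sd", names(unlist(effects)))]
  if (any(sds < 0, na.rm = TRUE))
    stop_husphen("validation_error", "'effects' contains a negative SD")
  if (attrition_prob < 0 || attrition_prob > 1)
    stop_husphen("validation_error", "'attrition_prob' must be in [0, 1]")
  structure(list(n_per_group = as.integer(n_per_group), sexes = sexes,
                 diets = diets, ages_weeks = as.integer(ages_weeks),
                 seed = as.integer(seed), effects = effects,
                 attrition_prob = attrition_prob),
            class = "cohort_config")
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic longitudinal diet cohort
#'
#' Draws one record per mouse per timepoint. Body weight follows a per-mouse
#' linear trend (baseline by sex, slope by sex-by-diet) plus Gaussian residual
#' noise; WD mice receive a transient hyperphagia bump in the configured
#' window and endpoint blood-chemistry shifts. The blood panel is recorded at
#' `effects$biochem_weeks` (non-fasting except the final week, which is the
#' fasting terminal bleed); ALT/AST/BUN/insulin and liver weight exist at the
#' final week only, mirroring a terminal necropsy.
#'
#' @param config a [cohort_config()].
#' @return A tibble (class `"cohort_table"`) with one row per mouse-by-week:
#'   `mouse_id, sex, diet, age_weeks, bw, bcs, food_intake_daily, kcal_per_g,
#'   glucose, cholesterol, triglycerides, alt, ast, bun, insulin, fasting,
#'   liver_weight`. Unmeasured cells are `NA`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop_husphen("validation_error", "'config' must be built by cohort_config()")
  eff <- config$effects
  ages <- config$ages_weeks
  final_wk <- ages[length(ages)]
  bio_wks <- intersect(eff$biochem_weeks, ages)

  with_seed(config$seed, {
    rows <- list()
    for (sex in config$sexes) for (diet in config$diets) {
      for (i in seq_len(config$n_per_group)) {
        id <- sprintf("%s_%s_%02d", substr(sex, 1, 1), diet, i)
        bb <- eff$bw_baseline[[sex]]
        sl <- eff$bw_slope[[paste(sex, diet, sep = "_")]]
        b0 <- rnorm(1, bb["mean"], bb["sd"])
        b1 <- rnorm(1, sl["mean"], sl["sd"])
        bw <- b0 + b1 * (ages - ages[1]) + rnorm(length(ages), 0, eff$bw_noise_sd)
        bw <- pmax(bw, 1)

        ib <- eff$intake_base[[sex]]
        intake <- rnorm(1, ib["mean"], ib["sd"]) +
          rnorm(length(ages), 0, eff$intake_noise_sd)
        if (diet == "WD") {
          hw <- eff$hyperphagia
          in_win <- ages >= hw$weeks[1] & ages <= hw$weeks[2]
          intake[in_win] <- intake[in_win] + rnorm(1, hw$delta["mean"], hw$delta["sd"])
        }
        intake <- pmax(intake, 0)

        bcs <- rep(3L, length(ages))
        if (diet == "WD" && !is.na(eff$bcs_wd_shift_week))
          bcs[ages >= eff$bcs_wd_shift_week] <- 4L
        bcs <- pmin(pmax(bcs, 1L), 5L)

        panel <- matrix(NA_real_, length(ages), length(eff$biochem),
                        dimnames = list(NULL, names(eff$biochem)))
        for (a in names(eff$biochem)) {
          spec <- eff$biochem[[a]]
          wks <- if (a %in% eff$endpoint_only) final_wk else bio_wks
          for (w in wks) {
            v <- rnorm(1, spec$base["mean"], spec$base["sd"])
            if (diet == "WD" && w == final_wk)
              v <- v + rnorm(1, spec$wd_shift["mean"], spec$wd_shift["sd"])
            panel[match(w, ages), a] <- max(v, 0)
          }
        }

        lw <- rep(NA_real_, length(ages))
        lwv <- rnorm(1, eff$liver_weight$base["mean"], eff$liver_weight$base["sd"])
        if (diet == "WD")
          lwv <- lwv + rnorm(1, eff$liver_weight$wd_shift["mean"],
                             eff$liver_weight$wd_shift["sd"])
        lw[length(ages)] <- max(lwv, 0.1)

        rows[[id]] <- tibble::tibble(
          mouse_id = id, sex = sex, diet = diet, age_weeks = ages,
          bw = bw, bcs = bcs, food_intake_daily = intake,
          kcal_per_g = unname(eff$kcal_per_g[diet]),
          glucose = panel[, "glucose"], cholesterol = panel[, "cholesterol"],
          triglycerides = panel[, "triglycerides"], alt = panel[, "alt"],
          ast = panel[, "ast"], bun = panel[, "bun"], insulin = panel[, "insulin"],
          fasting = age_weeks == final_wk & age_weeks %in% c(bio_wks, final_wk),
          liver_weight = lw
        )
      }
    }
    out <- dplyr::bind_rows(rows)
    if (config$attrition_prob > 0 && length(ages) > 1) {
      ids <- unique(out$mouse_id)
      drop <- ids[runif(length(ids)) < config$attrition_prob]
      for (id in drop) {
        last_wk <- sample(ages[-length(ages)], 1)  # survives through last_wk
        out <- out[!(out$mouse_id == id & out$age_weeks > last_wk), ]
      }
    }
    class(out) <- c("cohort_table", class(out))
    out
  })
}

#' Generate an ordinal score sheet from per-group score distributions
#'
#' Draws one ordinal grade per mouse from the categorical distribution
#' configured for its sex-by-diet group, reproducibly by the config seed.
#'
#' @param config a [cohort_config()]; group sizes and seed are taken from it.
#' @param prevalence either a single named probability vector over score
#'   levels (applied to every group), or a named list keyed by
#'   `"<sex>_<diet>"` (e.g. `"female_WD"`) of such vectors. Each vector must
#'   sum to 1 within 1e-9; names are the score levels.
#' @param score_name column name for the score (default `"score"`).
#' @return tibble with `mouse_id, sex, diet` and the score column (integer
#'   levels as given by the probability names).
#' @export
generate_score_sheet <- function(config, prevalence, score_name = "score") {
  if (!inherits(config, "cohort_config"))
    stop_husphen("validation_error", "'config' must be built by cohort_config()")
  groups <- expand.grid(sex = config$sexes, diet = config$diets,
                        stringsAsFactors = FALSE)
  get_p <- function(sex, diet) {
    p <- if (is.list(prevalence)) prevalence[[paste(sex, diet, sep = "_")]]
         else prevalence
    if (is.null(p))
      stop_husphen("validation_error", "no prevalence for group %s_%s", sex, diet)
    if (is.null(names(p)))
      stop_husphen("validation_error", "prevalence vectors must have score-level names")
    if (abs(sum(p) - 1) > 1e-9)
      stop_husphen("validation_error",
                   "prevalence for %s_%s sums to %.12f, not 1", sex, diet, sum(p))
    if (any(p < 0))
      stop_husphen("validation_error", "prevalence probabilities must be >= 0")
    p
  }
  with_seed(config$seed, {
    rows <- lapply(seq_len(nrow(groups)), function(g) {
      sex <- groups$sex[g]; diet <- groups$diet[g]
      p <- get_p(sex, diet)
      lev <- suppressWarnings(as.integer(names(p)))
      if (anyNA(lev)) lev <- names(p)
      out <- tibble::tibble(
        mouse_id = sprintf("%s_%s_%02d", substr(sex, 1, 1), diet,
                           seq_len(config$n_per_group)),
        sex = sex, diet = diet,
        score = sample(lev, config$n_per_group, replace = TRUE, prob = p)
      )
      names(out)[names(out) == "score"] <- score_name
      out
    })
    dplyr::bind_rows(rows)
  })
}
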