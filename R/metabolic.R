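#' Body-weight gain from baseline
#'
#' Gain at each week is body weight minus the body weight at the earliest
#' recorded age for that mouse, so the baseline gain is 0 by construction.
#' Used instead of absolute weight when groups differ at baseline.
#'
#' @param records data frame of one mouse's longitudinal records with columns
#'   `age_weeks` and `bw` (g).
#' @return tibble `age_weeks, bw_gain` (g), ordered by age.
#' @export
bw_gain <- function(records) {
  if (nrow(records) < 1)
    stop_husphen("validation_error", "need at least one record")
  if (anyDuplicated(records$age_weeks))
    stop_husphen("ambiguity_error",
                 "duplicate (mouse, age) rows at week(s) %s",
                 paste(unique(records$age_weeks[duplicated(records$age_weeks)]),
                       collapse = ", "))
  records <- records[order(records$age_weeks), ]
  tibble::tibble(age_weeks = records$age_weeks,
                 bw_gain = records$bw - records$bw[1])
}

#' Food efficiency ratio (FER)
#'
#' FER at each week is 100 x cumulative body-weight gain over cumulative food
#' intake from baseline. In `"grams"` mode the denominator is grams of food;
#' in `"kcal"` mode it is energy intake (grams x the diet's kcal/g). Intake
#' is accumulated as `food_intake_daily x 7` per recorded week by default
#' (`days_per_interval`), i.e. records are weekly.
#'
#' A per-interval (non-cumulative) variant is available via
#' `cumulative = FALSE`.
#'
#' @param records one mouse's records with `age_weeks`, `bw`,
#'   `food_intake_daily` (g/day) and, for kcal mode, `kcal_per_g`.
#' @param mode `"grams"` (default) or `"kcal"`.
#' @param cumulative use cumulative gain and intake (default) or per-interval.
#' @param days_per_interval days of feeding each record represents (default 7).
#' @return tibble `age_weeks, fer` (percent), baseline row dropped (no intake
#'   has accumulated yet at baseline).
#' @export
fer <- function(records, mode = c("grams", "kcal"), cumulative = TRUE,
                days_per_interval = 7) {
  mode <- match.arg(mode)
  records <- records[order(records$age_weeks), ]
  gain <- bw_gain(records)$bw_gain
  intake_g <- records$food_intake_daily * days_per_interval
  denom <- if (mode == "kcal") {
    if (is.null(records$kcal_per_g) || anyNA(records$kcal_per_g))
      stop_husphen("configuration_error", "kcal mode needs 'kcal_per_g'")
    intake_g * records$kcal_per_g
  } else intake_g
  # food eaten between baseline and week t: intervals after the baseline row
  if (cumulative) {
    cum_gain <- gain[-1]
    cum_in <- cumsum(denom[-1])
  } else {
    cum_gain <- diff(records$bw)
    cum_in <- denom[-1]
  }
  if (any(cum_in <= 0))
    stop_husphen("undefined_value_error",
                 "zero cumulative intake at week(s) %s",
                 paste(records$age_weeks[-1][cum_in <= 0], collapse = ", "))
  tibble::tibble(age_weeks = records$age_weeks[-1],
                 fer = 100 * cum_gain / cum_in)
}

#' Daily caloric intake
#'
#' @param food_intake_daily g/day of food eaten.
#' @param kcal_per_g caloric density of the assigned diet (kcal/g); the study
#'   diets are 3.150 (SD) and 4.2594 (WD).
#' @return kcal/day.
#' @export
caloric_intake <- function(food_intake_daily, kcal_per_g) {
  if (any(is.na(kcal_per_g)))
    stop_husphen("configuration_error", "missing 'kcal_per_g'")
  if (any(food_intake_daily < 0, na.rm = TRUE))
    stop_husphen("domain_error", "intake must be >= 0")
  food_intake_daily * kcal_per_g
}

#' HOMA-IR with murine unit conversions
#'
#' Insulin is converted from ng/mL to pmol/L (x 172.18) and then to uIU/mL
#' (/ 6); glucose from mg/dL to mmol/L (x 0.0555). HOMA-IR is
#' insulin (uIU/mL) x glucose (mmol/L) / 22.5. Inputs must come from fasting
#' samples (the caller asserts this).
#'
#' @param insulin_ng_mL fasting insulin, ng/mL.
#' @param glucose_mg_dL fasting glucose, mg/dL.
#' @return tibble `insulin_uIU_mL, glucose_mmol_L, homa_ir` (vectorized).
#' @export
homa_ir <- function(insulin_ng_mL, glucose_mg_dL) {
  if (any(insulin_ng_mL < 0, na.rm = TRUE) || any(glucose_mg_dL < 0, na.rm = TRUE))
    stop_husphen("domain_error", "insulin and glucose must be >= 0")
  ins <- insulin_ng_mL * 172.18 / 6
  glu <- glucose_mg_dL * 0.0555
  tibble::tibble(insulin_uIU_mL = ins, glucose_mmol_L = glu,
                 homa_ir = ins * glu / 22.5)
}

#' Flag hyperglycemia on non-fasting glucose
#'
#' The monitoring threshold is non-fasting blood glucose >= 250 mg/dL
#' (boundary inclusive).
#'
#' @param glucose_mg_dL non-fasting glucose, mg/dL.
#' @param fasting logical; must be `FALSE` (the threshold is defined for
#'   non-fasting samples only).
#' @return logical vector.
#' @export
flag_hyperglycemia <- function(glucose_mg_dL, fasting = FALSE) {
  if (any(fasting))
    stop_husphen("wrong_context_error",
                 "hyperglycemia threshold applies to non-fasting samples only")
  glucose_mg_dL >= 250
}

#' Liver-to-body-weight ratio (hepatomegaly index)
#'
#' @param liver_weight_g liver weight, g.
#' @param bw_g body weight, g (> 0).
#' @return percent, 100 x liver / body weight.
#' @export
liver_bw_ratio <- function(liver_weight_g, bw_g) {
  if (any(is.na(liver_weight_g)))
    stop_husphen("missing_data_error", "missing 'liver_weight_g'")
  if (any(bw_g <= 0, na.rm = TRUE))
    stop_husphen("domain_error", "'bw_g' must be > 0")
  100 * liver_weight_g / bw_g
}

#' Per-mouse derived metabolic table
#'
#' Convenience wrapper applying [bw_gain()], [caloric_intake()] and, at weeks
#' where the panel exists, [homa_ir()] across a whole cohort table.
#'
#' @param cohort a cohort table as produced by [generate_cohort()].
#' @return tibble, one row per mouse-by-week, with `bw_gain`,
#'   `caloric_intake_kcal` and (final fasting week) `homa_ir` columns added.
#' @export
metabolic_derive <- function(cohort) {
  out <- cohort |>
    dplyr::group_by(.data$mouse_id) |>
    dplyr::arrange(.data$age_weeks, .by_group = TRUE) |>
    dplyr::mutate(bw_gain = .data$bw - .data$bw[1]) |>
    dplyr::ungroup() |>
    dplyr::mutate(caloric_intake_kcal =
                    caloric_intake(.data$food_intake_daily, .data$kcal_per_g))
  hi <- rep(NA_real_, nrow(out))
  ok <- out$fasting & !is.na(out$insulin) & !is.na(out$glucose)
  if (any(ok)) hi[ok] <- homa_ir(out$insulin[ok], out$glucose[ok])$homa_ir
  out$homa_ir <- hi
  out
}

#' @importFrom dplyr .data
NULL
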