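#' Teichholz left-ventricular volume
#'
#' Single-diameter LV volume estimate: `(7.0 / (2.4 + D)) * D^3` with the
#' internal diameter `D` in mm, giving microliters.
#'
#' @param lvid LV internal diameter, mm (> 0). Vectorized.
#' @return volume, uL.
#' @export
teichholz_volume <- function(lvid) {
  if (any(lvid <= 0, na.rm = TRUE))
    stop_husphen("domain_error", "'lvid' must be > 0")
  (7.0 / (2.4 + lvid)) * lvid^3
}

#' Raw echocardiographic caliper set
#'
#' Validates one animal-timepoint's averaged caliper measurements from the
#' parasternal long axis: interventricular septum (IVS), LV internal diameter
#' (LVID) and LV posterior wall (LVPW), each at end-diastole (`_d`) and
#' end-systole (`_s`), plus heart rate and body weight. Calipers should be
#' the average of at least three beats; fewer trigger a warning, a systolic
#' diameter exceeding the diastolic one (no contraction) likewise warns
#' rather than errors so QC can proceed.
#'
#' @param ivs_d,ivs_s septal thickness, mm (alias SWTd for `ivs_d`).
#' @param lvid_d,lvid_s internal diameter, mm (alias LVEDD for `lvid_d`).
#' @param lvpw_d,lvpw_s posterior wall, mm (alias PWTd for `lvpw_d`).
#' @param hr heart rate, beats/min.
#' @param bw body weight, g.
#' @param n_beats_averaged beats averaged per caliper (>= 3 expected).
#' @return list of class `"echo_measures"`.
#' @export
echo_measures <- function(ivs_d, ivs_s, lvid_d, lvid_s, lvpw_d, lvpw_s,
                          hr, bw, n_beats_averaged = 3L) {
  lengths <- c(ivs_d = ivs_d, ivs_s = ivs_s, lvid_d = lvid_d, lvid_s = lvid_s,
               lvpw_d = lvpw_d, lvpw_s = lvpw_s)
  if (any(lengths <= 0))
    stop_husphen("domain_error", "all caliper lengths must be > 0")
  assert_scalar_number(hr, "hr", 0, strict_min = TRUE)
  assert_scalar_number(bw, "bw", 0, strict_min = TRUE)
  if (n_beats_averaged < 3)
    warn_husphen("beats_warning", "fewer than 3 beats averaged (%d)",
                 n_beats_averaged)
  if (lvid_s >= lvid_d)
    warn_husphen("negative_fs_warning",
                 "lvid_s >= lvid_d: ventricle not contracting as expected")
  structure(list(ivs_d = ivs_d, ivs_s = ivs_s, lvid_d = lvid_d,
                 lvid_s = lvid_s, lvpw_d = lvpw_d, lvpw_s = lvpw_s,
                 hr = hr, bw = bw,
                 n_beats_averaged = as.integer(n_beats_averaged)),
            class = "echo_measures")
}

#' Derive left-ventricular indices from calipers
#'
#' Computes, from averaged calipers (all lengths mm):
#' * LV volumes (uL), diastolic and systolic, by [teichholz_volume()];
#' * ejection fraction `EF (%) = 100 (Vol_d - Vol_s) / Vol_d`;
#' * fractional shortening `FS (%) = 100 (LVIDd - LVIDs) / LVIDd`;
#' * corrected LV mass (mg)
#'   `1.053 ((LVIDd + LVPWd + IVSd)^3 - LVIDd^3) x 0.8`
#'   (myocardial density 1.053 g/mL; x0.8 corrects cube-formula
#'   overestimation; mm^3 x g/mL gives mg);
#' * stroke volume `SV (uL) = Vol_d - Vol_s`;
#' * cardiac output `CO (mL/min) = SV x hr / 1000`;
#' * relative wall thickness `RWT = (SWTd + PWTd) / LVEDD`.
#'
#' @param m an [echo_measures()] object.
#' @return tibble of class `"echo_derived"` with one row:
#'   `lv_vol_d, lv_vol_s, ef, fs, lv_mass_corr, sv, co, rwt`.
#' @export
echo_derive <- function(m) {
  if (!inherits(m, "echo_measures"))
    stop_husphen("validation_error", "'m' must be built by echo_measures()")
  vol_d <- teichholz_volume(m$lvid_d)
  vol_s <- teichholz_volume(m$lvid_s)
  sv <- vol_d - vol_s
  tibble::tibble(
    lv_vol_d = vol_d,
    lv_vol_s = vol_s,
    ef = 100 * (vol_d - vol_s) / vol_d,
    fs = 100 * (m$lvid_d - m$lvid_s) / m$lvid_d,
    lv_mass_corr = 1.053 * ((m$lvid_d + m$lvpw_d + m$ivs_d)^3 - m$lvid_d^3) * 0.8,
    sv = sv,
    co = sv * m$hr / 1000,
    rwt = (m$ivs_d + m$lvpw_d) / m$lvid_d
  )
}

#' Allometric body-weight normalization of echo variables
#'
#' One-dimensional measures (diameters, wall thicknesses; mm) are divided by
#' `BW^(1/3)`; three-dimensional measures (volumes, mass; uL or mg) by `BW`.
#' Dimensionless indices (EF, FS, RWT) are passed through unchanged.
#'
#' @param values named numeric vector, list, or single-row data frame of echo
#'   variables (raw calipers and/or derived indices).
#' @param bw body weight, g (> 0).
#' @return same shape as `values`, with `_n` appended to the names of
#'   normalized entries (`lvid_d` -> `lvid_d_n`); dimensionless entries keep
#'   their names and values.
#' @export
echo_normalize <- function(values, bw) {
  assert_scalar_number(bw, "bw", 0, strict_min = TRUE)
  one_d <- c("ivs_d", "ivs_s", "lvid_d", "lvid_s", "lvpw_d", "lvpw_s")
  three_d <- c("lv_vol_d", "lv_vol_s", "lv_mass_corr", "sv")
  vals <- as.list(values)
  out <- vals
  for (nm in names(vals)) {
    if (nm %in% one_d) {
      out[[paste0(nm, "_n")]] <- vals[[nm]] / bw^(1 / 3)
    } else if (nm %in% three_d) {
      out[[paste0(nm, "_n")]] <- vals[[nm]] / bw
    }
    # ef, fs, rwt, co, hr: left unchanged
  }
  if (is.data.frame(values)) tibble::as_tibble(out) else out
}
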