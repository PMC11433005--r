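#' Circular region of interest
#'
#' ROIs are circles, the shape used for manual parenchymal sampling. Area is
#' nominal (mm^2); the pixel mask contains every pixel whose center lies
#' within the equivalent radius. Depth is the center row times the pixel
#' spacing (image origin top-left, rows run with depth).
#'
#' @param center `c(row, col)` in pixels (1-based).
#' @param area_mm2 nominal area, mm^2 (> 0).
#' @return object of class `"roi_spec"`.
#' @export
roi_spec <- function(center, area_mm2) {
  if (length(center) != 2L || any(!is.finite(center)))
    stop_husphen("validation_error", "'center' must be c(row, col)")
  assert_scalar_number(area_mm2, "area_mm2", 0, strict_min = TRUE)
  structure(list(center = as.numeric(center), area_mm2 = area_mm2),
            class = "roi_spec")
}

roi_mask_idx <- function(image, roi) {
  r_px <- sqrt(roi$area_mm2 / pi) / image$pixel_spacing
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  cr <- roi$center[1]; cc <- roi$center[2]
  if (cr - r_px < 1 || cr + r_px > nr || cc - r_px < 1 || cc + r_px > nc)
    stop_husphen("geometry_error", "ROI clipped by the image border")
  rows <- floor(cr - r_px):ceiling(cr + r_px)
  cols <- floor(cc - r_px):ceiling(cc + r_px)
  g <- expand.grid(row = rows, col = cols)
  keep <- (g$row - cr)^2 + (g$col - cc)^2 <= r_px^2
  g <- g[keep, ]
  cbind(g$row, g$col)
}

#' ROI intensity statistics
#'
#' Arithmetic mean and population SD (n denominator) of the pixel intensities
#' under the circular mask.
#'
#' @param image a [bmode_image()].
#' @param roi a [roi_spec()]; must lie fully inside the image and cover at
#'   least 30 pixels.
#' @return list `mean`, `sd`, `n_pixels` (a.u., a.u., count).
#' @export
roi_stats <- function(image, roi) {
  idx <- roi_mask_idx(image, roi)
  if (nrow(idx) < 30)
    stop_husphen("resolution_error",
                 "ROI covers only %d pixels (< 30); enlarge it or refine spacing",
                 nrow(idx))
  v <- image$pixels[idx]
  list(mean = mean(v), sd = sd_pop(v), n_pixels = nrow(idx))
}

roi_depth_mm <- function(image, roi) roi$center[1] * image$pixel_spacing

check_roi_area <- function(roi, nominal, tol, what) {
  if (abs(roi$area_mm2 - nominal) > tol)
    stop_husphen("roi_area_error",
                 "%s ROI area %.3f mm^2 outside %.2f +/- %.2f mm^2",
                 what, roi$area_mm2, nominal, tol)
}

check_depth_match <- function(image, roi_a, roi_b, rel_tol = 0.10) {
  da <- roi_depth_mm(image, roi_a); db <- roi_depth_mm(image, roi_b)
  if (abs(da - db) > rel_tol * max(da, db))
    stop_husphen("depth_error",
                 "ROI depths %.2f and %.2f mm differ by more than %.0f%%",
                 da, db, 100 * rel_tol)
}

#' Hepatic-renal echogenicity ratio (HR)
#'
#' Mean gray level of a liver ROI divided by that of a renal-cortex ROI on
#' the liver/kidney interface view. Both ROIs must have nominal area within
#' 0.1 +/- 0.02 mm^2 and sit at the same depth (within 10%), since
#' echogenicity ratios are only gain-independent for depth-matched samples.
#' A ratio above 1 means the liver is brighter than the cortex, the
#' sonographic signature of fatty infiltration.
#'
#' @param image a [bmode_image()] of the liver/kidney long-axis view (or a
#'   phantom).
#' @param liver_roi,cortex_roi [roi_spec()]s over liver parenchyma and renal
#'   cortex.
#' @return dimensionless ratio.
#' @export
hepatic_renal_ratio <- function(image, liver_roi, cortex_roi) {
  check_roi_area(liver_roi, 0.1, 0.02, "liver")
  check_roi_area(cortex_roi, 0.1, 0.02, "cortex")
  check_depth_match(image, liver_roi, cortex_roi)
  roi_stats(image, liver_roi)$mean / roi_stats(image, cortex_roi)$mean
}

#' Hepatic-portal vein echogenicity ratio (HPV)
#'
#' Liver echogenicity normalized to the blood pool in the portal vein lumen
#' on the axial portal view; same area (0.1 +/- 0.02 mm^2) and depth-match
#' constraints as the hepatic-renal ratio.
#'
#' @param image a [bmode_image()] of the axial portal-vein view (or phantom).
#' @param liver_roi,pv_roi [roi_spec()]s over liver parenchyma and the
#'   portal-vein lumen.
#' @return dimensionless ratio.
#' @export
hepatic_portal_ratio <- function(image, liver_roi, pv_roi) {
  check_roi_area(liver_roi, 0.1, 0.02, "liver")
  check_roi_area(pv_roi, 0.1, 0.02, "portal vein")
  check_depth_match(image, liver_roi, pv_roi)
  pv_mean <- roi_stats(image, pv_roi)$mean
  if (pv_mean == 0)
    stop_husphen("division_guard_error", "portal-vein ROI mean is 0")
  roi_stats(image, liver_roi)$mean / pv_mean
}

#' Gray-level histogram (GLH) analysis across liver planes
#'
#' One 1 +/- 0.02 mm^2 ROI per scanning plane (left lateral lobe
#' longitudinal, caudate lobe longitudinal, right median lobe axial).
#' Reports per-plane ROI mean echogenicity; tissue heterogeneity as the
#' within-ROI SD of the right median axial plane; and anisotropy as the
#' population SD (n denominator) of the three plane means.
#'
#' @param images named list of [bmode_image()]s with names
#'   `left_lobe_long`, `caudate_long`, `right_median_axial`.
#' @param rois a single [roi_spec()] used in every plane, or a named list of
#'   ROIs parallel to `images`.
#' @return list `glh_means` (named, a.u.), `heterogeneity` (a.u.),
#'   `anisotropy` (a.u.).
#' @export
glh_analysis <- function(images, rois) {
  planes <- c("left_lobe_long", "caudate_long", "right_median_axial")
  missing <- setdiff(planes, names(images))
  if (length(missing))
    stop_husphen("incomplete_set_error", "missing plane(s): %s",
                 paste(missing, collapse = ", "))
  if (inherits(rois, "roi_spec")) rois <- setNames(rep(list(rois), 3), planes)
  stats <- lapply(planes, function(p) {
    check_roi_area(rois[[p]], 1, 0.02, p)
    roi_stats(images[[p]], rois[[p]])
  })
  names(stats) <- planes
  means <- vapply(stats, `[[`, numeric(1), "mean")
  list(glh_means = means,
       heterogeneity = stats$right_median_axial$sd,
       anisotropy = sd_pop(means))
}

#' Portal-vein diameter from caliper endpoints
#'
#' @param image a [bmode_image()] of the axial portal view.
#' @param endpoints 2 x 2 matrix, rows = the two caliper points as
#'   `(row, col)` pixels.
#' @return diameter, mm (Euclidean pixel distance x spacing).
#' @export
pv_diameter <- function(image, endpoints) {
  endpoints <- as.matrix(endpoints)
  if (!all(dim(endpoints) == c(2L, 2L)))
    stop_husphen("validation_error", "'endpoints' must be a 2x2 (row, col) matrix")
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  if (any(endpoints[, 1] < 1 | endpoints[, 1] > nr |
          endpoints[, 2] < 1 | endpoints[, 2] > nc))
    stop_husphen("geometry_error", "endpoints outside the image")
  d_px <- sqrt(sum((endpoints[1, ] - endpoints[2, ])^2))
  if (d_px == 0)
    stop_husphen("degenerate_measurement_error", "coincident caliper endpoints")
  d_px * image$pixel_spacing
}

#' Validate visual steatosis grades
#'
#' Echostructure pattern 1-4 (homogeneous; diffusely increased echogenicity;
#' discrete coarsening; extensive coarsening), echogenicity relative to the
#' renal cortex 0-2 (liver darker; equal; brighter), ascites 0/1.
#'
#' @param echostructure,echogenicity_vs_cortex,ascites integer vectors.
#' @return invisibly `TRUE`; errors on any out-of-vocabulary value.
#' @export
validate_visual_grades <- function(echostructure, echogenicity_vs_cortex, ascites) {
  if (!all(echostructure %in% 1:4))
    stop_husphen("validation_error", "echostructure must be in 1..4")
  if (!all(echogenicity_vs_cortex %in% 0:2))
    stop_husphen("validation_error", "echogenicity_vs_cortex must be in 0..2")
  if (!all(ascites %in% 0:1))
    stop_husphen("validation_error", "ascites must be 0 or 1")
  invisible(TRUE)
}

#' Frequency table of visual grades per group
#'
#' Counts and percentages of each score level per group, per grading
#' category; percentages are over the group size and rounded to 2 decimals.
#'
#' @param grades data frame with a grouping column and the grade columns
#'   `echostructure`, `echogenicity_vs_cortex`, `ascites` (one row per
#'   mouse-timepoint).
#' @param group name of the grouping column (default `"group"`).
#' @return tibble `group, category, level, n, pct, pct_trunc` (`pct` rounded
#'   to 2 decimals so columns sum to ~100; `pct_trunc` truncated to 2
#'   decimals, the convention used when frequencies are printed); empty
#'   groups yield zero counts and `NaN` percentages.
#' @export
grade_frequency_table <- function(grades, group = "group") {
  validate_visual_grades(grades$echostructure, grades$echogenicity_vs_cortex,
                         grades$ascites)
  vocab <- list(echostructure = 1:4, echogenicity_vs_cortex = 0:2,
                ascites = 0:1)
  score_frequency_core(grades, group, vocab)
}

# shared counting engine for ordinal frequency tables
score_frequency_core <- function(df, group, vocab) {
  groups <- if (is.factor(df[[group]])) levels(df[[group]]) else unique(df[[group]])
  rows <- list()
  for (g in groups) {
    sub <- df[df[[group]] == g, , drop = FALSE]
    n_g <- nrow(sub)
    for (cat in names(vocab)) {
      cnt <- table(factor(sub[[cat]], levels = vocab[[cat]]))
      p <- 100 * as.integer(cnt) / n_g
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = g, category = cat, level = vocab[[cat]],
        n = as.integer(cnt),
        pct = round(p, 2),                 # rounded: columns sum to ~100
        pct_trunc = trunc(p * 100) / 100   # truncated: report print style
      )
    }
  }
  dplyr::bind_rows(rows)
}
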