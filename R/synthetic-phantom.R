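#' B-mode image container
#'
#' A minimal container for an 8-bit grayscale brightness-mode ultrasound
#' frame: an intensity matrix (rows = depth direction, top-left origin),
#' physical pixel spacing, an anatomical plane label, and optional labeled
#' region masks.
#'
#' @param pixels numeric matrix, intensities in \[0, 255\] (arbitrary units).
#' @param pixel_spacing mm per pixel (> 0), isotropic.
#' @param plane_label one of `left_lobe_long`, `caudate_long`,
#'   `right_median_axial`, `liver_kidney_long`, `portal_axial`, or `phantom`.
#' @param masks optional named list of logical matrices (same dim as
#'   `pixels`), one per labeled region.
#' @return object of class `"bmode_image"`.
#' @export
bmode_image <- function(pixels, pixel_spacing,
                        plane_label = "phantom", masks = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_husphen("validation_error", "'pixels' must be a numeric matrix")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop_husphen("validation_error", "intensities must lie in [0, 255]")
  assert_scalar_number(pixel_spacing, "pixel_spacing", 0, strict_min = TRUE)
  planes <- c("left_lobe_long", "caudate_long", "right_median_axial",
              "liver_kidney_long", "portal_axial", "phantom")
  if (!plane_label %in% planes)
    stop_husphen("validation_error", "unknown plane_label '%s'", plane_label)
  structure(list(pixels = pixels, pixel_spacing = pixel_spacing,
                 plane_label = plane_label, masks = masks),
            class = "bmode_image")
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf("<bmode_image> %dx%d px, %.3f mm/px, plane = %s, %d mask(s)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_spacing, x$plane_label,
              length(x$masks)))
  invisible(x)
}

#' Rectangular region for a phantom specification
#'
#' @param label region label, one of `liver`, `renal_cortex`, `renal_medulla`,
#'   `portal_vein`, `background`.
#' @param rows,cols integer ranges (length-2, inclusive, 1-based) of the block.
#' @param target_mean target mean intensity in \[0, 255\] a.u.
#' @param heterogeneity_sd SD (a.u.) of the slowly varying Gaussian intensity
#'   field added inside the region before speckle; 0 for a flat region.
#' @return list describing the region, consumed by [phantom_spec()].
#' @export
phantom_region <- function(label, rows, cols, target_mean, heterogeneity_sd = 0) {
  labels <- c("liver", "renal_cortex", "renal_medulla", "portal_vein", "background")
  if (!label %in% labels)
    stop_husphen("validation_error", "unknown region label '%s'", label)
  if (target_mean < 0 || target_mean > 255)
    stop_husphen("validation_error", "target_mean must be in [0, 255]")
  assert_scalar_number(heterogeneity_sd, "heterogeneity_sd", 0)
  list(label = label, rows = as.integer(rows), cols = as.integer(cols),
       target_mean = target_mean, heterogeneity_sd = heterogeneity_sd)
}

#' Speckle phantom specification
#'
#' Describes a synthetic B-mode frame: labeled rectangular tissue regions with
#' target mean echogenicity, fully developed multiplicative Rayleigh speckle
#' (multiplier scaled to unit mean, so regional expected intensity is
#' preserved), and a Gaussian point-spread-function blur.
#'
#' @param image_shape `c(rows, cols)` in pixels. Default 550 x 650, which at
#'   the default spacing is an 11 x 13 mm field of view.
#' @param pixel_spacing mm per pixel; default 0.02.
#' @param regions list of [phantom_region()]s; masks must be disjoint. Pixels
#'   not covered by any region take `background_mean`.
#' @param background_mean intensity of uncovered pixels (a.u.).
#' @param speckle one of `"rayleigh_multiplicative"` or `"none"`.
#' @param psf_sigma Gaussian PSF sigma in pixels (default 1.5).
#' @param seed integer seed; identical spec + seed gives identical images.
#' @return object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(image_shape = c(550L, 650L), pixel_spacing = 0.02,
                         regions = list(), background_mean = 40,
                         speckle = c("rayleigh_multiplicative", "none"),
                         psf_sigma = 1.5, seed = 1L) {
  speckle <- match.arg(speckle)
  if (length(image_shape) != 2L || any(image_shape < 8))
    stop_husphen("validation_error", "'image_shape' must be c(rows, cols), each >= 8")
  assert_scalar_number(pixel_spacing, "pixel_spacing", 0, strict_min = TRUE)
  assert_scalar_number(psf_sigma, "psf_sigma", 0)
  if (background_mean < 0 || background_mean > 255)
    stop_husphen("validation_error", "'background_mean' must be in [0, 255]")
  cover <- matrix(FALSE, image_shape[1], image_shape[2])
  for (r in regions) {
    if (any(r$rows < 1) || r$rows[2] > image_shape[1] ||
        any(r$cols < 1) || r$cols[2] > image_shape[2])
      stop_husphen("geometry_error", "region '%s' exceeds the image", r$label)
    blk <- cover[r$rows[1]:r$rows[2], r$cols[1]:r$cols[2]]
    if (any(blk))
      stop_husphen("geometry_error", "region masks overlap at '%s'", r$label)
    cover[r$rows[1]:r$rows[2], r$cols[1]:r$cols[2]] <- TRUE
  }
  structure(list(image_shape = as.integer(image_shape),
                 pixel_spacing = pixel_spacing, regions = regions,
                 background_mean = background_mean, speckle = speckle,
                 psf_sigma = psf_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# unit-mean Rayleigh multipliers: Rayleigh(scale s) has mean s*sqrt(pi/2),
# so s = sqrt(2/pi) gives E[m] = 1 and the speckle preserves regional means
rayleigh_unit <- function(n) sqrt(2 / pi) * sqrt(-2 * log(runif(n)))

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  size <- 2L * ceiling(3 * sigma) + 1L
  k <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma)
  EBImage::filter2(m, k, boundary = "replicate")
}

#' Generate a speckle phantom image
#'
#' Builds the piecewise-constant tissue map (plus per-region Gaussian
#' heterogeneity), applies unit-mean multiplicative Rayleigh speckle, blurs
#' with the Gaussian PSF, then clamps to \[0, 255\] and quantizes to 8 bits by
#' round-half-even. Regional empirical means converge to the configured
#' targets (relative error below ~2% for regions of a few thousand pixels).
#'
#' @param spec a [phantom_spec()].
#' @param quantize if `FALSE`, return the continuous (pre-8-bit) image; used
#'   to test mean preservation without quantization effects.
#' @return a [bmode_image()] with one logical mask per region
#'   (`plane_label = "phantom"` unless overridden via `plane_label`).
#' @param plane_label plane label to stamp on the output image.
#' @export
generate_phantom <- function(spec, quantize = TRUE, plane_label = "phantom") {
  if (!inherits(spec, "phantom_spec"))
    stop_husphen("validation_error", "'spec' must be built by phantom_spec()")
  with_seed(spec$seed, {
    nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
    base <- matrix(spec$background_mean, nr, nc)
    masks <- list()
    for (r in spec$regions) {
      rows <- r$rows[1]:r$rows[2]; cols <- r$cols[1]:r$cols[2]
      blk <- matrix(r$target_mean, length(rows), length(cols))
      if (r$heterogeneity_sd > 0) {
        # low-frequency heterogeneity: white Gaussian field smoothed at 4 px,
        # rescaled to the requested SD so "coarseness" and amplitude decouple
        h <- matrix(rnorm(length(blk)), nrow(blk))
        h <- gaussian_blur(h, 4)
        h <- h / sd_pop(as.vector(h)) * r$heterogeneity_sd
        blk <- blk + h
      }
      base[rows, cols] <- blk
      mk <- matrix(FALSE, nr, nc); mk[rows, cols] <- TRUE
      masks[[r$label]] <- mk
    }
    img <- if (spec$speckle == "rayleigh_multiplicative") {
      base * matrix(rayleigh_unit(nr * nc), nr, nc)
    } else base
    img <- gaussian_blur(img, spec$psf_sigma)
    img <- pmin(pmax(img, 0), 255)
    if (quantize) img <- round(img)  # round-half-even
    bmode_image(img, spec$pixel_spacing, plane_label = plane_label,
                masks = if (length(masks)) masks else NULL)
  })
}

#' Liver/kidney interface phantom
#'
#' Convenience geometry for hepatic-renal ratio work: on the default
#' 550 x 650 px canvas, a liver block occupies the left side and a renal
#' cortex block the right side of the same depth band, so depth-matched ROIs
#' can be placed in both tissues.
#'
#' @param liver_mean,cortex_mean target region means (a.u.).
#' @param liver_sd,cortex_sd heterogeneity SDs (a.u.).
#' @param seed integer seed.
#' @param ... passed on to [phantom_spec()] (e.g. `psf_sigma`).
#' @return a [phantom_spec()] with `liver` and `renal_cortex` regions.
#' @export
liver_kidney_phantom_spec <- function(liver_mean, cortex_mean,
                                      liver_sd = 0, cortex_sd = 0,
                                      seed = 1L, ...) {
  phantom_spec(
    regions = list(
      phantom_region("liver", rows = c(150L, 450L), cols = c(40L, 300L),
                     target_mean = liver_mean, heterogeneity_sd = liver_sd),
      phantom_region("renal_cortex", rows = c(150L, 450L), cols = c(350L, 610L),
                     target_mean = cortex_mean, heterogeneity_sd = cortex_sd)
    ),
    seed = seed, ...
  )
}
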