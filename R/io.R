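#' Write / read a cohort (or any tabular stage output) as CSV
#'
#' UTF-8, header row, ISO-style lower-snake column names as produced by the
#' generators.
#'
#' @param x data frame.
#' @param path file path.
#' @return `path`, invisibly (writer); tibble (reader).
#' @export
write_cohort_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, fileEncoding = "UTF-8"))
}

# run-length encode a label matrix (column-major) for the JSON sidecar
.rle_labels <- function(masks, dim) {
  lab <- matrix("background", dim[1], dim[2])
  for (nm in names(masks)) lab[masks[[nm]]] <- nm
  r <- rle(as.vector(lab))
  list(lengths = r$lengths, values = r$values)
}

.unrle_labels <- function(enc, dim) {
  lab <- inverse.rle(structure(list(lengths = enc$lengths,
                                    values = enc$values), class = "rle"))
  lab <- matrix(lab, dim[1], dim[2])
  labels <- setdiff(unique(enc$values), "background")
  masks <- lapply(labels, function(nm) lab == nm)
  names(masks) <- labels
  if (length(masks)) masks else NULL
}

#' Write / read a B-mode image as 8-bit grayscale PNG + JSON sidecar
#'
#' The sidecar (`<path>.json`) stores pixel spacing, plane label and the
#' region masks as a run-length-encoded label map, so the image round-trips
#' losslessly through plain-text-friendly formats.
#'
#' @param image a [bmode_image()] (intensities are rounded to 8-bit on
#'   write).
#' @param path PNG file path.
#' @return `path`, invisibly (writer); a [bmode_image()] (reader).
#' @export
write_bmode_png <- function(image, path) {
  png::writePNG(round(image$pixels) / 255, path)
  side <- list(pixel_spacing = image$pixel_spacing,
               plane_label = image$plane_label,
               dim = dim(image$pixels))
  if (!is.null(image$masks))
    side$masks_rle <- .rle_labels(image$masks, dim(image$pixels))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_bmode_png
#' @export
read_bmode_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  masks <- if (!is.null(side$masks_rle))
    .unrle_labels(side$masks_rle, side$dim) else NULL
  bmode_image(round(px * 255), side$pixel_spacing,
              plane_label = side$plane_label, masks = masks)
}

#' Write / read a Doppler trace as CSV (`time_s`, `velocity_mm_s`)
#'
#' @param trace a `doppler_trace`.
#' @param path file path.
#' @return `path`, invisibly (writer); a `doppler_trace` (reader).
#' @export
write_waveform_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[c("time_s", "velocity_mm_s")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @param hr_hint optional heart-rate hint (beats/min) to attach on read.
#' @export
read_waveform_csv <- function(path, hr_hint = NULL) {
  d <- utils::read.csv(path)
  doppler_trace(d$time_s, d$velocity_mm_s, hr_hint = hr_hint)
}
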