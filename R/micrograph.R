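#' Acquisition metadata for a micrograph
#'
#' Records the imaging conditions a micrograph was taken under. When both
#' `dose_rate` (e/A^2/s) and `exposure` (s) are given, `total_dose` is
#' checked (or filled in) as their product — e.g. ~4 e/A^2/s for 8 s gives a
#' total dose of ~32 e/A^2.
#'
#' @param magnification nominal magnification (unitless).
#' @param dose_rate electron dose rate, e/A^2/s.
#' @param exposure exposure time, seconds.
#' @param total_dose total electron dose, e/A^2.
#' @param defocus defocus, micrometres (negative = underfocus).
#' @param detector `"DED"` (direct electron detector) or `"CCD"`.
#' @return an `acquisition_metadata` list.
#' @export
acquisition_metadata <- function(magnification = NA_real_, dose_rate = NA_real_,
                                 exposure = NA_real_, total_dose = NA_real_,
                                 defocus = NA_real_, detector = c("DED", "CCD")) {
  detector <- match.arg(detector)
  if (is.finite(dose_rate) && is.finite(exposure)) {
    prod <- dose_rate * exposure
    if (is.finite(total_dose) && abs(total_dose - prod) > 1e-6 * max(1, prod))
      stop("total_dose must equal dose_rate * exposure when all three are given")
    total_dose <- prod
  }
  structure(list(magnification = magnification, dose_rate = dose_rate,
                 exposure = exposure, total_dose = total_dose,
                 defocus = defocus, detector = detector),
            class = "acquisition_metadata")
}

#' Micrograph container
#'
#' A 2-D grayscale micrograph: a numeric pixel matrix `[row, col]` = (y, x)
#' plus the physical pixel size in nm/pixel and optional acquisition metadata.
#'
#' @param pixels numeric matrix of intensities.
#' @param pixel_size physical pixel size, nm/pixel (> 0).
#' @param metadata optional [acquisition_metadata()].
#' @return a `micrograph` object.
#' @export
micrograph <- function(pixels, pixel_size, metadata = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (!all(is.finite(pixels))) stop("micrograph intensities must be finite")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a positive scalar (nm/pixel)")
  structure(list(pixels = pixels, pixel_size = as.numeric(pixel_size),
                 metadata = metadata),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<micrograph> %d x %d px @ %.4g nm/px (%.3g x %.3g um)\n",
              d[1], d[2], x$pixel_size,
              d[1] * x$pixel_size / 1000, d[2] * x$pixel_size / 1000))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$pixels)

is_micrograph <- function(x) inherits(x, "micrograph")

as_micrograph <- function(x, pixel_size, metadata = NULL) {
  if (is_micrograph(x)) x else micrograph(x, pixel_size, metadata)
}

#' Segmentation mask container
#'
#' A per-class probability grid aligned to a micrograph plus its binarization.
#' The binary grid is always `probability >= threshold`.
#'
#' @param class_name structure class the mask refers to.
#' @param probability numeric matrix in `[0, 1]`, same shape as the source
#'   micrograph.
#' @param threshold binarization threshold.
#' @return a `segmentation_mask` object with elements `class_name`,
#'   `probability`, `binary`, `threshold`.
#' @export
segmentation_mask <- function(class_name, probability, threshold = 0.5) {
  if (!is.matrix(probability)) stop("probability must be a matrix")
  if (min(probability) < -1e-9 || max(probability) > 1 + 1e-9)
    stop("probability values must lie in [0, 1]")
  structure(list(class_name = class_name,
                 probability = probability,
                 binary = (probability >= threshold) * 1L,
                 threshold = threshold),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> class '%s', %d x %d px, threshold %.2f, %.2f%% positive\n",
              x$class_name, nrow(x$binary), ncol(x$binary), x$threshold,
              100 * mean(x$binary)))
  invisible(x)
}

## coerce plain binary matrix to a segmentation mask
as_mask <- function(x, class_name = "unknown", threshold = 0.5) {
  if (inherits(x, "segmentation_mask")) return(x)
  assert_binary(x)
  segmentation_mask(class_name, (x > 0) * 1, threshold)
}
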