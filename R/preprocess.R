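## Image conditioning applied before annotation/prediction and before Hough
## sizing: percentile-clipped 8-bit normalization, Gaussian FFT bandpass
## (feature sizes filter_small..filter_large pass), mean-pooling binning,
## and 3x3 median despeckling.

#' Preprocessing configuration
#'
#' Defaults follow the lipoprotein-detection recipe: bandpass with large
#' structure size 50 px and small structure size 2 px, 4x binning (0.55 ->
#' 2.2 nm/pixel), percentile normalization at (0.1, 99.9).
#'
#' @param filter_large largest passed structure size, pixels.
#' @param filter_small smallest passed structure size, pixels.
#' @param bin_factor integer binning factor, one of 1, 2, 4, 8.
#' @param normalize_percentiles length-2 clipping percentiles in percent.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(filter_large = 50, filter_small = 2,
                              bin_factor = 4L,
                              normalize_percentiles = c(0.1, 99.9)) {
  if (!(filter_large > filter_small && filter_small > 0))
    stop("need filter_large > filter_small > 0")
  if (!bin_factor %in% c(1L, 2L, 4L, 8L)) stop("bin_factor must be 1, 2, 4 or 8")
  structure(list(filter_large = filter_large, filter_small = filter_small,
                 bin_factor = as.integer(bin_factor),
                 normalize_percentiles = normalize_percentiles),
            class = "preprocess_config")
}

#' Percentile-clipped 8-bit normalization
#'
#' Intensities are clipped at the given percentiles and mapped linearly onto
#' `[0, 255]`. A constant image cannot be scaled and yields flat mid-grey
#' (128) with a warning.
#'
#' @param m a [micrograph()] or numeric matrix.
#' @param percentiles length-2 clipping percentiles, percent.
#' @return object of the same type with intensities in `[0, 255]`;
#'   pixel size unchanged.
#' @export
normalize_to_8bit <- function(m, percentiles = c(0.1, 99.9)) {
  x <- if (is_micrograph(m)) m$pixels else m
  q <- quantile(x, probs = percentiles / 100, names = FALSE, type = 7)
  if (q[2] <= q[1]) {
    warning("constant (or degenerate-range) image; returning flat mid-grey")
    out <- matrix(128, nrow(x), ncol(x))
  } else {
    out <- clamp((x - q[1]) / (q[2] - q[1]), 0, 1) * 255
  }
  if (is_micrograph(m)) micrograph(out, m$pixel_size, m$metadata) else out
}

## Gaussian band transfer function at frequency f (cycles/pixel).
## Sharpness constant chosen so that sizes outside [filter_small,
## filter_large] are attenuated by >= 90% while the geometric mid-band
## keeps >= 80% amplitude.
BANDPASS_SHARPNESS <- 2.2

bandpass_gain <- function(f, filter_large, filter_small) {
  c2 <- BANDPASS_SHARPNESS^2
  exp(-c2 * (filter_small * f)^2 / 2) * (1 - exp(-c2 * (filter_large * f)^2 / 2))
}

#' FFT bandpass filter
#'
#' Suppresses structures larger than `filter_large` pixels (including the DC
#' offset and smooth background gradients) and smaller than `filter_small`
#' pixels, using a radially symmetric Gaussian band mask in the frequency
#' domain. The output has mean ~0; re-offsetting for display is a separate
#' step ([normalize_to_8bit()]).
#'
#' @param m a [micrograph()] or numeric matrix.
#' @param cfg a [preprocess_config()] (or use `filter_large`/`filter_small`).
#' @param filter_large,filter_small structure-size band, pixels.
#' @return filtered object of the same type, mean approximately zero.
#' @export
bandpass_filter <- function(m, cfg = NULL, filter_large = 50, filter_small = 2) {
  if (!is.null(cfg)) {
    filter_large <- cfg$filter_large; filter_small <- cfg$filter_small
  }
  x <- if (is_micrograph(m)) m$pixels else m
  if (filter_large >= min(dim(x)))
    stop("filter_large must be smaller than the smallest image dimension")
  fy <- fft_freq(nrow(x)); fx <- fft_freq(ncol(x))
  f <- sqrt(outer(fy^2, fx^2, `+`))
  H <- bandpass_gain(f, filter_large, filter_small)
  H[1, 1] <- 0  # exact DC removal
  out <- Re(fft(fft(x) * H, inverse = TRUE)) / length(x)
  if (is_micrograph(m)) micrograph(out, m$pixel_size, m$metadata) else out
}

#' Bin an image by block averaging
#'
#' Each output pixel is the mean of a `factor x factor` block; dimensions are
#' cropped down to multiples of the factor and the pixel size is multiplied
#' by it (0.55 nm at 4x -> 2.2 nm).
#'
#' @param m a [micrograph()] or numeric matrix.
#' @param factor integer >= 1.
#' @return binned object of the same type.
#' @export
bin_image <- function(m, factor) {
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  x <- if (is_micrograph(m)) m$pixels else m
  if (factor > min(dim(x))) stop("factor larger than image dimensions")
  if (factor > 1L) {
    H <- (nrow(x) %/% factor) * factor
    W <- (ncol(x) %/% factor) * factor
    x <- x[seq_len(H), seq_len(W), drop = FALSE]
    ## block mean via two reshapes
    x <- matrix(colMeans(matrix(x, nrow = factor)), nrow = H %/% factor)
    x <- t(matrix(colMeans(matrix(t(x), nrow = factor)), nrow = W %/% factor))
  }
  if (is_micrograph(m)) micrograph(x, m$pixel_size * factor, m$metadata) else x
}

#' 3x3 median despeckle
#'
#' Median filter over the 3x3 neighbourhood (replicated borders): removes
#' isolated single-pixel foreground ("speckle") while leaving the interior
#' of solid regions untouched. Works on intensity images and binary masks
#' alike and returns the same type.
#'
#' @param x numeric/binary matrix, [micrograph()] or [segmentation_mask()].
#' @return despeckled object of the same type.
#' @export
despeckle <- function(x) {
  if (is_micrograph(x))
    return(micrograph(median3x3(x$pixels), x$pixel_size, x$metadata))
  if (inherits(x, "segmentation_mask")) {
    b <- median3x3(x$binary * 1.0)
    out <- x
    out$binary <- (b > 0.5) * 1L
    return(out)
  }
  if (!is.matrix(x)) stop("despeckle expects a 2-D input")
  was_logical <- is.logical(x)
  out <- median3x3(x * 1.0)
  if (was_logical) out > 0.5 else out
}
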