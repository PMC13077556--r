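`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive per-image seeds from a base seed
#'
#' Deterministic expansion of one base seed into `n` independent seeds, used by
#' [simulate_dataset()] and [run_pipeline()] so a single global seed fixes
#' every stochastic stage. Seeds stay below 2^31.
#'
#' @param base_seed integer scalar.
#' @param n number of seeds to derive.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(base_seed, n) {
  stopifnot(is.numeric(base_seed), length(base_seed) == 1L, n >= 1)
  withr::with_seed(as.integer(base_seed), sample.int(.Machine$integer.max - 1L, n))
}

## FFT helpers -----------------------------------------------------------

## frequency coordinate (cycles/pixel) along an axis of length n
fft_freq <- function(n) {
  k <- c(seq(0L, floor(n / 2)), seq(-ceiling(n / 2) + 1L, -1L))
  k / n
}

## circular 2-D Gaussian convolution via FFT (periodic boundary);
## kernel is exactly unit-gain at DC.
fft_gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  d <- dim(x)
  fy <- fft_freq(d[1L]); fx <- fft_freq(d[2L])
  ## Fourier transform of a Gaussian of sd sigma (pixels)
  hy <- exp(-2 * pi^2 * sigma^2 * fy^2)
  hx <- exp(-2 * pi^2 * sigma^2 * fx^2)
  H <- outer(hy, hx)
  Re(fft(fft(x) * H, inverse = TRUE)) / length(x)
}

## cross-correlation of image with template (same size, template centred at
## [1,1] wrap-around), returns response matrix
fft_correlate <- function(x, template_f) {
  Re(fft(fft(x) * Conj(template_f), inverse = TRUE)) / length(x)
}

## clamp helper
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

assert_binary <- function(m, what = "mask") {
  v <- unique(as.vector(m))
  if (!all(v %in% c(0, 1, TRUE, FALSE)))
    stop(sprintf("%s must be binary (0/1)", what), call. = FALSE)
  invisible(TRUE)
}

## Jaccard index of two logical matrices
jaccard <- function(a, b) {
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

## recursively drop S3 classes so configs serialize as plain lists
strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else unclass(x)
}

## md5 of a canonical JSON rendering of an R object (for stage caching)
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(strip_classes(x), auto_unbox = TRUE,
                              digits = NA, null = "null"), f)
  unname(tools::md5sum(f))
}
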