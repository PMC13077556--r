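## Micrograph / mask file I/O.
##
## MRC: minimal MRC2014 reader/writer (modes 0, 1, 2, 6; little-endian,
## single 2-D section). The physical pixel size is carried in the header as
## cella/mx in Angstrom and converted to nm at this boundary. TIFF files do
## not carry a calibrated pixel size, so reading a TIFF requires an explicit
## value.

MRC_HEADER_BYTES <- 1024L

#' Read a micrograph from MRC or TIFF
#'
#' @param path file path; format inferred from the extension
#'   (`.mrc`/`.mrcs` vs `.tif`/`.tiff`).
#' @param pixel_size_override pixel size in nm/pixel. Optional for MRC
#'   (header value used when absent), mandatory for TIFF.
#' @return a [micrograph()].
#' @export
read_micrograph <- function(path, pixel_size_override = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mrc", "mrcs")) {
    m <- read_mrc(path)
    if (!is.null(pixel_size_override)) m$pixel_size <- pixel_size_override
    m
  } else if (ext %in% c("tif", "tiff")) {
    if (is.null(pixel_size_override))
      stop("TIFF files carry no calibrated pixel size; supply pixel_size_override (nm/pixel)")
    px <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(px)) == 3L) px <- px[, , 1L]
    micrograph(px * 1.0, pixel_size_override)
  } else {
    stop("unsupported micrograph format: ", ext)
  }
}

#' Write a micrograph to MRC or TIFF
#'
#' MRC output is 32-bit float with the pixel size stored in the header;
#' TIFF output is 8- or 16-bit unsigned with intensities scaled from the
#' stated range (pixel size is not representable in the file).
#'
#' @param m a [micrograph()].
#' @param path output path; format from extension.
#' @param bits for TIFF, 8 or 16.
#' @param range for TIFF, intensity range mapped onto the integer range;
#'   defaults to the image's own range.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(m, path, bits = 16L, range = NULL) {
  stopifnot(is_micrograph(m))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mrc", "mrcs")) {
    write_mrc(m, path)
  } else if (ext %in% c("tif", "tiff")) {
    r <- range %||% range(m$pixels)
    if (r[2] <= r[1]) r[2] <- r[1] + 1
    x <- clamp((m$pixels - r[1]) / (r[2] - r[1]), 0, 1)
    tiff::writeTIFF(x, path, bits.per.sample = as.integer(bits))
  } else stop("unsupported micrograph format: ", ext)
  invisible(path)
}

#' Read an MRC file
#'
#' Supports modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16); reads the
#' first section of a stack. Pixel size is `cella_x / mx` Angstrom, reported
#' in nm.
#'
#' @param path file path.
#' @return a [micrograph()].
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  dims <- readBin(con, "integer", 3L, size = 4L, endian = "little")  # nx ny nz
  mode <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (any(dims[1:2] <= 0) || dims[1] > 1e6 || dims[2] > 1e6)
    stop("corrupt MRC header: implausible dimensions")
  readBin(con, "integer", 3L, size = 4L, endian = "little")          # nxstart..
  mxyz <- readBin(con, "integer", 3L, size = 4L, endian = "little")  # mx my mz
  cella <- readBin(con, "numeric", 3L, size = 4L, endian = "little") # Angstrom
  seek(con, 92L)
  nsymbt <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  seek(con, MRC_HEADER_BYTES + nsymbt)
  n <- dims[1] * dims[2]
  v <- switch(as.character(mode),
    "0" = readBin(con, "integer", n, size = 1L, signed = TRUE, endian = "little"),
    "1" = readBin(con, "integer", n, size = 2L, signed = TRUE, endian = "little"),
    "2" = readBin(con, "numeric", n, size = 4L, endian = "little"),
    "6" = readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "little"),
    stop("unsupported MRC mode: ", mode))
  if (length(v) < n) stop("corrupt MRC file: truncated data block")
  px_A <- if (mxyz[1] > 0 && cella[1] > 0) cella[1] / mxyz[1] else NA_real_
  ## MRC stores x (column) fastest; transpose into [row, col]
  pixels <- t(matrix(as.numeric(v), nrow = dims[1], ncol = dims[2]))
  pixel_size <- if (is.finite(px_A)) px_A / 10 else
    stop("MRC header carries no pixel size; use read_micrograph(pixel_size_override=)")
  micrograph(pixels, pixel_size)
}

#' Write an MRC file (mode 2, float32)
#'
#' @param m a [micrograph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(m, path) {
  stopifnot(is_micrograph(m))
  ny <- nrow(m$pixels); nx <- ncol(m$pixels)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(c(nx, ny, 1L))                      # nx ny nz
  wi(2L)                                 # mode 2 = float32
  wi(c(0L, 0L, 0L))                      # nxstart
  wi(c(nx, ny, 1L))                      # mx my mz
  wf(c(nx, ny, 1) * m$pixel_size * 10)   # cella in Angstrom
  wf(c(90, 90, 90))                      # cellb
  wi(c(1L, 2L, 3L))                      # mapc mapr maps
  wf(c(min(m$pixels), max(m$pixels), mean(m$pixels)))
  wi(c(0L, 0L))                          # ispg, nsymbt
  wi(rep(0L, 25L))                       # extra
  wf(c(0, 0, 0))                         # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(sd(m$pixels))
  wi(0L)                                 # nlabl
  writeBin(raw(800L), con)               # labels
  writeBin(as.numeric(t(m$pixels)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Write a binary mask as PNG
#' @param mask binary matrix or [segmentation_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  if (inherits(mask, "segmentation_mask")) mask <- mask$binary
  assert_binary(mask)
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}

#' Read a binary mask from PNG
#' @param path file path.
#' @return integer 0/1 matrix.
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  (x > 0.5) * 1L
}
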