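# Image file I/O. PNG and TIFF, 8- or 16-bit, grayscale or RGB. Intensities
# are kept on the native [0, 2^k - 1] scale as doubles; files store integers.

#' Read a PNG or TIFF image
#'
#' Reads an 8- or 16-bit, single- or 3-channel PNG/TIFF file into a
#' [CSImage-class] on the native intensity scale `[0, 2^k - 1]`, recording
#' the file's bit depth.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return a [CSImage-class].
#' @seealso [writeImageFile()]
#' @export
readImageFile <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    depth <- attr(raw, "info")$bit.depth
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(raw, "bits.per.sample")
  } else {
    stop("unsupported image format: .", ext, " (use PNG or TIFF)")
  }
  d <- dim(raw)
  if (length(d) == 3L) {
    if (d[3] == 2L || d[3] > 3L)
      stop("unsupported channel count: ", d[3], " (expected 1 or 3)")
  }
  peak <- 2^depth - 1
  px <- raw * peak
  attributes(px) <- list(dim = dim(px))   # drop file metadata attributes
  csImage(px, as.integer(depth))
}

#' Write a CSImage to a PNG or TIFF file
#'
#' Intensities are clipped to `[0, 2^k - 1]`, rounded half away from zero to
#' the nearest integer, and written at the image's declared bit depth.
#' PNG output is 8-bit; use TIFF for 16-bit images.
#'
#' @param image a [CSImage-class].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
writeImageFile <- function(image, path) {
  stopifnot(is(image, "CSImage"))
  peak <- dynamicRange(image)
  # round half away from zero; values are nonnegative after clipping
  q <- floor(pmin(pmax(pixels(image), 0), peak) + 0.5)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bitDepth(image) != 8L)
      stop("PNG output supports 8-bit images only; use TIFF for ",
           bitDepth(image), "-bit")
    png::writePNG(q / peak, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!bitDepth(image) %in% c(8L, 16L))
      stop("TIFF output supports 8- or 16-bit images")
    tiff::writeTIFF(q / peak, path, bits.per.sample = bitDepth(image))
  } else {
    stop("unsupported image format: .", ext, " (use PNG or TIFF)")
  }
  invisible(path)
}
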