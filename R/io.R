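# Lossless grayscale image I/O. PNG and (uncompressed) TIFF only: the cipher
# is bijective on exact pixel values, so lossy formats are refused.

.image_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext %in% c("jpg", "jpeg")) {
    stop("JPEG is lossy and would corrupt ciphertext; use PNG or TIFF",
         call. = FALSE)
  }
  stop("unsupported image format: .", ext, " (use PNG or TIFF)", call. = FALSE)
}

#' Read an image as 8-bit grayscale
#'
#' Reads a PNG or TIFF image and returns an integer matrix of intensities
#' 0..255. Color images are converted to grayscale with the standard luma
#' weights (0.299 R + 0.587 G + 0.114 B); an alpha channel is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Integer matrix with values 0..255.
#' @export
read_gray_image <- function(path) {
  fmt <- .image_format(path)
  x <- switch(fmt,
    png = png::readPNG(path),
    tiff = tiff::readTIFF(path)
  )
  if (length(dim(x)) == 3L) {
    k <- dim(x)[3L]
    x <- if (k >= 3L) {
      0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L]
    } else {
      x[, , 1L]
    }
  }
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}

#' Write an 8-bit grayscale image
#'
#' Writes a PNG (default, lossless) or uncompressed TIFF. Lossy formats are
#' refused.
#'
#' @param img Integer matrix with values 0..255.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  .validate_image(img)
  fmt <- .image_format(path)
  x <- img / 255
  switch(fmt,
    png = png::writePNG(x, path),
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L, compression = "none")
  )
  invisible(path)
}
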