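## Grayscale PNG/TIFF input and output on the [0,255] working scale.

## The affine range of a float TIFF is stored losslessly in a second page
## as character codes of "lo hi" written with full precision.
.range_page <- function(lo, hi) {
  s <- sprintf("%.17g %.17g", lo, hi)
  matrix(utf8ToInt(s) / 255, nrow = 1)
}

.decode_range_page <- function(page) {
  s <- intToUtf8(as.integer(round(page * 255)))
  as.numeric(strsplit(s, " ")[[1]])
}

#' Read a grayscale image
#'
#' Reads an 8- or 16-bit PNG, or a TIFF, as a numeric matrix on the [0,255]
#' working scale. Multi-channel images are collapsed to luminance by channel
#' averaging (with a warning); 16-bit inputs are rescaled to [0,255] with a
#' warning. Two-page float TIFFs written by [writeImageGray()] carry their
#' affine range in the second page and are restored exactly, including
#' signed out-of-range values of sub-mode images.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return A numeric matrix (rows = y, columns = x).
#' @export
readImageGray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    if (!is.null(info) && isTRUE(info$bit.depth == 16L))
      warning("16-bit input rescaled to [0,255]")
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, info = TRUE, all = TRUE)
    if (length(pages) == 2L && nrow(pages[[2]]) == 1L) {
      rng <- .decode_range_page(pages[[2]])
      return(pages[[1]] * (rng[2] - rng[1]) + rng[1])
    }
    img <- pages[[1]]
    info <- attr(img, "info")
    if (isTRUE(info$bits.per.sample == 16L))
      warning("16-bit input rescaled to [0,255]")
  } else stop("unsupported image format: .", ext, call. = FALSE)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] > 1L) warning("multi-channel image collapsed to luminance")
    img <- apply(img, c(1, 2), mean)
  }
  matrix(as.numeric(img), nrow(img), ncol(img)) * 255
}

#' Write a grayscale image
#'
#' PNG output is 8-bit: values are clipped to [0,255] and quantized. TIFF
#' output is 32-bit float, normalized to the image's own range with the
#' range recorded in a second page, so signed and out-of-range values (as
#' in sub-mode images) survive the round trip.
#'
#' @param image numeric matrix on the [0,255] working scale.
#' @param path destination ending in .png, .tif or .tiff.
#' @return \code{path}, invisibly.
#' @export
writeImageGray <- function(image, path) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("'image' must be a numeric matrix", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    lo <- min(image); hi <- max(image)
    if (hi <= lo) hi <- lo + 1
    tiff::writeTIFF(list(matrix((image - lo) / (hi - lo), nrow(image)),
                         .range_page(lo, hi)),
                    path, bits.per.sample = 32L, reduce = FALSE)
  } else stop("unsupported image format: .", ext, call. = FALSE)
  invisible(path)
}
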