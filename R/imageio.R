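#' Read an 8-bit RGB image
#'
#' Reads PNG (via the png package) or TIFF into the package's internal image
#' representation: a numeric `H x W x 3` array on the 0-255 scale.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return Numeric `H x W x 3` array, values in 0-255.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the tiff package is required for TIFF input")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' Write an 8-bit RGB image as PNG
#'
#' @param img Numeric `H x W x 3` array, 0-255.
#' @param path Output path.
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 255) / 255, path)
  invisible(path)
}
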