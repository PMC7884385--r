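# Image file IO. Internally images are matrices with dim1 = x, dim2 = y;
# PNG files store rows = y, so the boundary transposes.

#' Read a grayscale snapshot (PNG or TIFF)
#'
#' @param path Image file; RGB(A) images are averaged to grayscale.
#' @return Numeric matrix (`width x height`), intensities in 0-1.
#' @export
read_snapshot <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3])], c(1, 2), mean)
  t(img)
}

#' Write a grayscale snapshot as PNG
#'
#' @param image Matrix (`width x height`), intensities in 0-1.
#' @param path Output file.
#' @export
write_snapshot <- function(image, path) {
  img <- t(pmin(pmax(image, 0), 1))
  png::writePNG(img, path)
  invisible(path)
}
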