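#' Read an image file as an 8-bit RGB array
#'
#' Images are represented throughout the package as numeric `H x W x 3`
#' arrays with values in `[0, 255]`, RGB channel order as loaded.
#'
#' @param path PNG (or JPEG via EBImage) file path.
#' @return numeric array `H x W x 3` in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_wbc("wbc_io_error", "no such image file: %s", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
  } else {
    eb <- EBImage::readImage(path)
    a <- aperm(EBImage::imageData(eb), c(2, 1, 3))
  }
  if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  round(a * 255)
}

#' Write an 8-bit RGB array as a PNG file
#'
#' @param img numeric `H x W x 3` array in `[0, 255]`.
#' @param path output file path (directories are created as needed).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({
    png::writePNG(clip01(img / 255), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_wbc("wbc_io_error", "cannot write image to %s", path)
  invisible(path)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

assert_image <- function(img, what = "img") {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3)
    stop_wbc("wbc_shape_error", "%s must be an H x W x 3 array", what)
  invisible(img)
}
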