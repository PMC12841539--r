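#' Raster image containers
#'
#' Images are plain integer arrays of 8-bit intensities in `[0, 255]`:
#' a `height x width` matrix for single-channel images, or a
#' `height x width x 3` array (R, G, B) for colour images. These helpers
#' validate, read and write them; all other functions in the package accept
#' and return these containers.
#'
#' @param img matrix or 3-d array of intensities in `[0, 255]`.
#' @return `as_raster()` returns the validated integer array.
#' @export
as_raster <- function(img) {
  if (is.data.frame(img)) img <- as.matrix(img)
  d <- dim(img)
  if (is.null(d) || !(length(d) == 2L || (length(d) == 3L && d[3] %in% c(1L, 3L)))) {
    stop("image must be a height x width matrix or height x width x {1,3} array")
  }
  if (length(d) == 3L && d[3] == 1L) {
    img <- img[, , 1L]
    d <- dim(img)
  }
  if (anyNA(img)) stop("image contains missing values")
  if (min(img) < 0 || max(img) > 255) stop("intensities must lie in [0, 255]")
  storage.mode(img) <- "integer"
  img
}

#' @rdname as_raster
#' @export
n_channels <- function(img) {
  d <- dim(img)
  if (length(d) == 2L) 1L else d[3]
}

#' Read / write 8-bit images
#'
#' Thin wrappers around the png and tiff packages that convert between files
#' and the package's integer `[0, 255]` containers. The format is chosen from
#' the file extension (`.png`, `.tif`/`.tiff`).
#'
#' @param path file path.
#' @param img image array (see [as_raster()]); for `write_label_map()` an
#'   integer label matrix which is stored as a 16-bit grayscale TIFF.
#' @return `read_image()` returns an integer raster array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(x)) == 3L && dim(x)[3] == 4L) x <- x[, , 1:3] # drop alpha
  as_raster(round(x * 255))
}

#' @rdname read_image
#' @export
write_image <- function(img, path) {
  img <- as_raster(img)
  ext <- tolower(tools::file_ext(path))
  x <- img / 255
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}

#' @rdname read_image
#' @export
write_label_map <- function(img, path) {
  storage.mode(img) <- "integer"
  if (min(img) < 0) stop("label maps must be non-negative; merge boundaries first")
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname read_image
#' @export
read_label_map <- function(path) {
  x <- tiff::readTIFF(path)
  m <- round(x * 65535)
  storage.mode(m) <- "integer"
  m
}
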