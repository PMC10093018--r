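#' Construct an intensity image
#'
#' An `intensity_image` is a height x width (grayscale) or
#' height x width x 3 array of finite values in \[0, 1\]. All pipeline
#' stages operate on this representation; files read from disk are
#' normalised to it (8/16-bit integers divided by their maximum
#' representable value).
#'
#' @param pixels numeric matrix or 3-d array with third dimension 3.
#' @return an object of class `intensity_image`.
#' @export
intensity_image <- function(pixels) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  if (!is.array(pixels) || !(length(dim(pixels)) %in% c(2L, 3L)))
    stop("pixels must be a matrix or 3-d array")
  if (length(dim(pixels)) == 2L) pixels <- array(pixels, c(dim(pixels), 1L))
  d <- dim(pixels)
  if (d[1] < 1 || d[2] < 1) stop("empty image")
  if (!(d[3] %in% c(1L, 3L))) stop("channels must be 1 or 3, got ", d[3])
  if (!all(is.finite(pixels))) stop("pixel values must be finite")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("pixel values must lie in [0, 1]")
  structure(pixels, class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<intensity_image %d x %d x %d, range [%.3f, %.3f]>\n",
              d[1], d[2], d[3], min(x), max(x)))
  invisible(x)
}

im_channels <- function(img) dim(img)[3]

# Strip class/dim bookkeeping to a plain h x w x c array.
im_array <- function(img) {
  a <- unclass(img)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  a
}

#' Convert an image to single-channel luminance
#'
#' 3-channel images are reduced with Rec. 601 luma weights
#' (0.299, 0.587, 0.114); grayscale images pass through.
#'
#' @param img an [intensity_image()].
#' @return a numeric matrix (height x width).
#' @export
to_grayscale <- function(img) {
  a <- im_array(img)
  if (dim(a)[3] == 1L) return(a[, , 1L])
  0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L]
}

# Replicate a grayscale matrix to n channels.
gray_to_channels <- function(m, channels) {
  if (channels == 1L) intensity_image(m)
  else intensity_image(array(rep(m, 3L), c(dim(m), 3L)))
}

#' Read an image file as an intensity image
#'
#' Supports PNG and TIFF. Values are normalised to \[0, 1\]; alpha channels
#' are dropped; 2-channel (gray+alpha) files keep the gray plane.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return an [intensity_image()].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (supported: png, tif, tiff)")
  )
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] == 2L) a <- a[, , 1L]
    else if (dim(a)[3] == 4L) a <- a[, , 1:3]
  }
  intensity_image(clip01(a))
}

#' Write an intensity image to file
#'
#' @param img an [intensity_image()].
#' @param path output path ending in .png, .tif or .tiff.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  a <- im_array(img)
  if (dim(a)[3] == 1L) a <- a[, , 1L]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(a, path),
    tif = ,
    tiff = tiff::writeTIFF(a, path, bits.per.sample = 16L),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}
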