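# Raster IO: grayscale matrices (rows = y, cols = x) in [0,1].
# EBImage stores images as (x, y[, channel]) so matrices are transposed
# on the way in and out.

#' Read a raster image as a grayscale matrix
#'
#' PNG/TIFF/JPEG rasters are read through EBImage; colour images are
#' converted to luminance.
#'
#' @param path Path to the raster file.
#' @return Numeric matrix (height x width) with intensities in `[0, 1]`.
#' @export
load_image <- function(path) {
  img <- EBImage::readImage(path)
  if (length(dim(img)) == 3L) {
    img <- EBImage::channel(img, "gray")
  }
  t(EBImage::imageData(img))
}

#' Write a grayscale matrix as a PNG image
#'
#' @param pixels Numeric matrix (height x width), clipped to `[0, 1]`.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
save_image <- function(pixels, path) {
  EBImage::writeImage(EBImage::Image(t(clamp(pixels, 0, 1))), path)
  invisible(path)
}

# pixel window of a box under the 0-based half-open convention;
# returns 1-based inclusive row/col ranges clipped to the frame
box_window <- function(x, y, w, h, width, height) {
  c0 <- max(floor(x), 0) + 1L
  c1 <- min(ceiling(x + w), width)
  r0 <- max(floor(y), 0) + 1L
  r1 <- min(ceiling(y + h), height)
  if (c1 < c0 || r1 < r0) return(NULL)
  list(rows = r0:r1, cols = c0:c1)
}
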