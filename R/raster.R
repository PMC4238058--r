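#' Raster image with physical pixel size
#'
#' The basic unit of all image operations: a 2D grid of finite, non-negative
#' fluorescence intensities (camera counts) together with the physical pixel
#' size in micrometers per pixel. Rows index the y (vertical) direction and
#' columns the x (horizontal) direction; pixel coordinates reported elsewhere
#' in the package are 0-based with the origin at the top-left pixel center.
#'
#' @param values numeric matrix of intensities (counts). All values must be
#'   finite; dimensions must be at least 1 x 1.
#' @param pixel_size physical size of one pixel in micrometers (um/px).
#' @return An object of class `raster_image`: a list with elements `values`
#'   and `pixel_size`.
#' @examples
#' img <- raster_image(matrix(100, 8, 8), pixel_size = 0.16)
#' dim(img$values)
#' @export
raster_image <- function(values, pixel_size = 0.16) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("image values must be numeric")
  if (nrow(values) < 1L || ncol(values) < 1L) stop("image must be at least 1 x 1")
  if (!all(is.finite(values))) stop("image contains non-finite values")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || !is.finite(pixel_size) ||
      pixel_size <= 0)
    stop("pixel_size must be a single positive number (um/px)")
  structure(list(values = values, pixel_size = pixel_size), class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  v <- x$values
  cat(sprintf("raster_image: %d x %d px (%.3g x %.3g um), pixel_size %.4g um/px\n",
              nrow(v), ncol(v), nrow(v) * x$pixel_size, ncol(v) * x$pixel_size,
              x$pixel_size))
  cat(sprintf("  intensity range [%.4g, %.4g], mean %.4g\n",
              min(v), max(v), mean(v)))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$values)

#' @export
as.matrix.raster_image <- function(x, ...) x$values

# Coerce a matrix or raster_image to raster_image.
as_raster <- function(x, pixel_size = 0.16) {
  if (inherits(x, "raster_image")) return(x)
  raster_image(x, pixel_size = pixel_size)
}
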