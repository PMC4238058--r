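#' Pixel-by-pixel flat-field correction factors
#'
#' Builds a flat-field (uneven illumination and detector sensitivity)
#' correction field from a background-subtracted image of a homogeneous
#' fluorescent bilayer: the reference is normalized to its maximum so that the
#' factors lie in (0, 1] with `max(factors) == 1`. The reference is
#' median-filtered first (default radius 3 px) so single hot pixels do not set
#' the maximum.
#'
#' @param reference a [raster_image()] (or matrix) of a homogeneous bilayer,
#'   already background-subtracted; must be strictly positive.
#' @param smooth_radius median-filter radius in pixels; 0 disables smoothing.
#' @return An object of class `correction_field` with elements `factors`
#'   (matrix in (0, 1]) and `smooth_radius`.
#' @export
compute_flatfield <- function(reference, smooth_radius = 3L) {
  m <- as_raster(reference)$values
  if (any(m <= 0))
    stop("reference has non-positive pixels; subtract the background first")
  if (smooth_radius > 0) {
    # EBImage's median filter operates on [0, 1] data
    mx <- max(m)
    m <- EBImage::medianFilter(m / mx, smooth_radius) * mx
  }
  structure(list(factors = m / max(m), smooth_radius = smooth_radius),
            class = "correction_field")
}

#' Background-subtract and flat-field correct an image
#'
#' Computes `(image - background) / factors`, clipping the result at zero.
#' Pixels whose correction factor falls below `floor` are not amplified
#' further: the factor is floored and the pixel is flagged invalid in the
#' `valid` attribute of the returned image.
#'
#' @param image a [raster_image()] or matrix.
#' @param background per-pixel background image (same shape), a scalar, or
#'   `NULL` for no subtraction.
#' @param field a `correction_field` from [compute_flatfield()], or `NULL`.
#' @param floor lower guard on correction factors.
#' @return A [raster_image()]; attribute `valid` is a logical matrix marking
#'   pixels corrected with a factor above the floor.
#' @export
correct_image <- function(image, background = NULL, field = NULL, floor = 0.01) {
  img <- as_raster(image)
  m <- img$values
  if (!is.null(background)) {
    b <- if (inherits(background, "raster_image")) background$values
         else background
    if (is.matrix(b) && !identical(dim(b), dim(m)))
      stop("background shape does not match image")
    m <- m - b
  }
  valid <- matrix(TRUE, nrow(m), ncol(m))
  if (!is.null(field)) {
    f <- field$factors
    if (!identical(dim(f), dim(m)))
      stop("correction field shape does not match image")
    if (any(f <= 0)) stop("correction factors must be positive")
    valid <- f >= floor
    m <- m / pmax(f, floor)
  }
  out <- raster_image(pmax(m, 0), img$pixel_size)
  attr(out, "valid") <- valid
  out
}

#' Rolling-ball local background flattening
#'
#' Estimates the local background by grayscale morphological opening with a
#' flat disc structuring element of the given radius and subtracts it, the
#' classical rolling-ball flattening used before thresholding images with
#' uneven local background. Features smaller than the disc are preserved;
#' a constant image maps to zero everywhere.
#'
#' @param image a [raster_image()] or matrix.
#' @param radius disc radius in pixels (>= 1); must not exceed the shorter
#'   image side.
#' @return A [raster_image()] of the flattened image (pointwise `>= 0` and
#'   `<=` the input).
#' @export
rolling_ball <- function(image, radius = 50L) {
  img <- as_raster(image)
  m <- img$values
  if (radius < 1) stop("radius must be at least 1")
  if (2 * radius + 1 > min(dim(m)))
    stop("radius larger than the shorter image side")
  kern <- EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "disc")
  # EBImage grayscale morphology operates on [0, 1] data; an affine rescale
  # commutes with min/max so the opening is exact
  lo <- min(m); hi <- max(m)
  if (hi == lo) return(raster_image(matrix(0, nrow(m), ncol(m)), img$pixel_size))
  bg <- EBImage::opening((m - lo) / (hi - lo), kern) * (hi - lo) + lo
  raster_image(pmax(m - bg, 0), img$pixel_size)
}
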