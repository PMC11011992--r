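#' En-face angiogram container
#'
#' Wraps a 2-D grayscale intensity matrix together with its physical scan
#' geometry and acquisition metadata. The default geometry is the common
#' 3 x 3 mm fovea-centered scan; the pixel pitch is always derived from the
#' extent and the raster size, never assumed.
#'
#' @param pixels Numeric matrix of intensities (rows = y, columns = x).
#'   Any input depth is accepted; [to_eight_bit()] normalizes to 0-255.
#' @param extent_mm Physical side lengths in mm, length-2 numeric
#'   `c(height, width)` or a single value used for both axes.
#' @param plexus Capillary plexus the slab was projected from: `"SCP"`
#'   (superficial) or `"DCP"` (deep).
#' @param meta Named list of free-form labels (eye id, timepoint,
#'   laterality, ...).
#'
#' @return An object of class `enface_angiogram`: a list with elements
#'   `pixels`, `height_px`, `width_px`, `extent_mm`, `plexus`, `meta`.
#' @examples
#' img <- enface_angiogram(matrix(runif(32 * 32), 32, 32))
#' pixel_pitch_um(img)
#' @export
enface_angiogram <- function(pixels, extent_mm = c(3, 3),
                             plexus = c("SCP", "DCP"), meta = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    oq_error("pixels must be a numeric matrix", "octaquant_bad_image")
  if (any(!is.finite(pixels)))
    oq_error("pixel intensities must be finite", "octaquant_nonfinite")
  if (nrow(pixels) < 16L || ncol(pixels) < 16L)
    oq_error("image must be at least 16 x 16 pixels", "octaquant_bad_image")
  if (length(extent_mm) == 1L) extent_mm <- rep(extent_mm, 2L)
  if (length(extent_mm) != 2L || any(!is.finite(extent_mm)) || any(extent_mm <= 0))
    oq_error("extent_mm must be two positive lengths", "octaquant_bad_geometry")
  plexus <- match.arg(plexus)
  structure(
    list(pixels = pixels,
         height_px = nrow(pixels), width_px = ncol(pixels),
         extent_mm = as.numeric(extent_mm),
         plexus = plexus, meta = meta),
    class = "enface_angiogram")
}

#' @export
print.enface_angiogram <- function(x, ...) {
  cat(sprintf("<enface_angiogram> %d x %d px, %.2f x %.2f mm, plexus %s\n",
              x$height_px, x$width_px, x$extent_mm[1], x$extent_mm[2], x$plexus))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Convert an angiogram to 8-bit depth
#'
#' Linear min-max rescale of the intensities to integers in 0-255, the
#' depth at which all downstream thresholding operates. The minimum maps to
#' 0 and the maximum to 255; a constant image maps to all zeros. No
#' resampling is performed: the raster keeps its native size and the pixel
#' pitch is always recomputed from the physical extent.
#'
#' @param image An [enface_angiogram()].
#' @return An `enface_angiogram` with integer intensities in 0-255.
#' @export
to_eight_bit <- function(image) {
  stopifnot(inherits(image, "enface_angiogram"))
  px <- image$pixels
  if (any(!is.finite(px)))
    oq_error("pixel intensities must be finite", "octaquant_nonfinite")
  rng <- range(px)
  out <- if (rng[1] == rng[2]) {
    matrix(0, nrow(px), ncol(px))
  } else {
    round((px - rng[1]) / (rng[2] - rng[1]) * 255)
  }
  image$pixels <- out
  image$meta$bit_depth <- "8-bit"
  image
}

#' Physical pixel pitch in micrometres
#'
#' The edge length of one pixel along each axis, `extent_mm * 1000 /
#' n_pixels`. A 3 mm scan over a 585-pixel axis gives 5.13 um.
#'
#' @param image An [enface_angiogram()].
#' @return Named numeric `c(y = , x = )`, in um per pixel.
#' @export
pixel_pitch_um <- function(image) {
  stopifnot(inherits(image, "enface_angiogram"))
  if (image$height_px == 0L || image$width_px == 0L)
    oq_error("zero-size image has no pixel pitch", "octaquant_bad_geometry")
  c(y = image$extent_mm[1] * 1000 / image$height_px,
    x = image$extent_mm[2] * 1000 / image$width_px)
}

# Mean of the two axis pitches; the scans are square to within one pixel so
# the two differ only in the fourth decimal.
isotropic_pitch_um <- function(image) mean(pixel_pitch_um(image))

oq_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "octaquant_error", "error")))
}
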