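#' Vessel area density
#'
#' Fraction of angiogram pixels flagged as perfused in the binary vessel
#' map: `VAD = n_binary_px / n_total_px`, in `[0, 1]`.
#'
#' @param binary A `binary_vessel_map` or logical matrix.
#' @return Numeric fraction.
#' @export
compute_vad <- function(binary) {
  m <- as_mask(binary)
  sum(m) / length(m)
}

#' Vessel skeleton density
#'
#' Fraction of angiogram pixels on the one-pixel skeleton:
#' `VSD = n_skeleton_px / n_total_px`. Because each vessel contributes its
#' centerline only, VSD tracks total vessel length independent of caliber.
#'
#' @param skeleton A `skeleton_map` or logical matrix.
#' @return Numeric fraction.
#' @export
compute_vsd <- function(skeleton) {
  m <- as_mask(skeleton)
  sum(m) / length(m)
}

#' Vessel diameter index
#'
#' Average vessel caliber: the ratio of perfused area to skeleton length,
#' `vdi_px = n_binary_px / n_skeleton_px` (pixels), and `vdi_um = vdi_px *
#' pitch`. Undefined (NA, with `defined = FALSE`) when the skeleton is
#' empty.
#'
#' @param binary A `binary_vessel_map` or logical matrix.
#' @param skeleton A `skeleton_map` or logical matrix; must be a subset of
#'   `binary`.
#' @param pitch_um Pixel pitch in micrometres (default 3 mm / 585 px).
#' @return List with `vdi_px`, `vdi_um`, `defined`.
#' @export
compute_vdi <- function(binary, skeleton, pitch_um = 3000 / 585) {
  b <- as_mask(binary); s <- as_mask(skeleton)
  if (!all(dim(b) == dim(s)))
    oq_error("binary and skeleton masks differ in shape", "octaquant_shape_mismatch")
  if (any(s & !b))
    oq_error("skeleton is not contained in the binary map",
             "octaquant_containment")
  ns <- sum(s)
  if (ns == 0L)
    return(list(vdi_px = NA_real_, vdi_um = NA_real_, defined = FALSE))
  vdi_px <- sum(b) / ns
  list(vdi_px = vdi_px, vdi_um = vdi_px * pitch_um, defined = TRUE)
}

#' Full angiogram quantification pipeline
#'
#' Runs the complete chain: 8-bit conversion, the three binarizations
#' (global threshold, Hessian vesselness, adaptive threshold), their
#' combination, skeletonization, and the VAD/VSD/VDI metrics. The
#' configuration and all intermediate pixel counts are recorded in the
#' result for audit.
#'
#' @param image An [enface_angiogram()].
#' @param cfg A [quant_config()].
#' @param keep_maps If `TRUE`, attach the binary and skeleton maps to the
#'   result (default `FALSE` to keep results light).
#' @return An object of class `vessel_metrics`: a list with `vad`, `vsd`,
#'   `vdi_px`, `vdi_um`, `vdi_defined`, `n_binary_px`, `n_skeleton_px`,
#'   `n_total_px`, `pitch_um`, `plexus`, `meta`, `config`.
#' @examples
#' img <- enface_angiogram(matrix(runif(64 * 64, 0, 255), 64, 64))
#' m <- quantify(img)
#' c(m$vad, m$vsd)
#' @export
quantify <- function(image, cfg = quant_config(), keep_maps = FALSE) {
  img8 <- to_eight_bit(image)
  # shared speckle reduction: all three branches see one denoised 8-bit image
  img8$pixels <- switch(cfg$denoise_filter,
                        median3 = median3(img8$pixels),
                        gaussian = {
                          gk <- gauss_kernel(cfg$denoise_sigma_px, 0L)
                          round(sepconv(img8$pixels, gk, gk))
                        },
                        none = img8$pixels)
  g <- global_binarize(img8, cfg)
  h <- vesselness_binarize(img8, cfg)
  a <- adaptive_binarize(img8, cfg)
  comb <- combine_binarizations(g, h, a, cfg)
  sk <- skeletonize(comb)
  pitch <- isotropic_pitch_um(img8)
  vdi <- compute_vdi(comb, sk, pitch)
  out <- structure(
    list(vad = compute_vad(comb),
         vsd = compute_vsd(sk),
         vdi_px = vdi$vdi_px, vdi_um = vdi$vdi_um, vdi_defined = vdi$defined,
         n_binary_px = sum(comb$mask), n_skeleton_px = sum(sk$mask),
         n_total_px = length(comb$mask),
         pitch_um = pitch, plexus = image$plexus, meta = image$meta,
         config = cfg,
         branch_counts = c(global = sum(g$mask), hessian = sum(h$mask),
                           adaptive = sum(a$mask))),
    class = "vessel_metrics")
  if (keep_maps) {
    out$binary <- comb
    out$skeleton <- sk
  }
  out
}

#' @export
print.vessel_metrics <- function(x, ...) {
  cat(sprintf(
    "<vessel_metrics> VAD %.4f  VSD %.4f  VDI %.3f px (%.2f um)%s\n",
    x$vad, x$vsd,
    if (x$vdi_defined) x$vdi_px else NA, if (x$vdi_defined) x$vdi_um else NA,
    if (x$vdi_defined) "" else " [undefined: empty skeleton]"))
  invisible(x)
}
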