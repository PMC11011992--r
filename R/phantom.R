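#' Generate a synthetic capillary-network phantom with exact ground truth
#'
#' Builds a random branching vascular network as a set of straight
#' centerline segments with per-segment calibers, then rasterizes it twice:
#' once at full caliber (the truth vessel-area map) and once at one pixel
#' (the truth skeleton). The network model is a persistent random walk from
#' trunk seed points with stochastic branching - a geometric stand-in for
#' a capillary bed, not an angiogenesis model: it produces curvilinear
#' structures with controlled density and caliber, which is what the
#' quantification pipeline needs for validation.
#'
#' @param seed Integer RNG seed; the phantom is a pure function of its
#'   arguments.
#' @param field_mm Physical side length (mm) of the square field. Default 3.
#' @param dim_px Raster size in pixels (single value, square). Default 585.
#' @param n_trunks Number of trunk walks started at random field-edge
#'   points. Default 12.
#' @param branch_rate Per-step probability that a walk spawns a branch.
#'   Default 0.08.
#' @param caliber_um_range Calibers are drawn uniformly from this range
#'   (um); must stay at or above one pixel pitch. Default `c(12, 28)`.
#' @param step_px Walk step length in pixels. Default 4.
#' @param max_steps Cap on steps per walk. Default 90.
#' @param max_walks Cap on the total number of walks (trunks plus
#'   branches), which bounds the network density. Default `10 * n_trunks`.
#' @return An object of class `synthetic_truth`: list with `segments`
#'   (data.frame: x0,y0,x1,y1 in mm and caliber_um), `truth_binary`,
#'   `truth_skeleton` (logical matrices), `truth_metrics` (the VAD/VSD/VDI
#'   of the truth rasters), `field_mm`, `dim_px`, `pitch_um`, `seed`.
#' @examples
#' tr <- generate_network(seed = 1, dim_px = 128, n_trunks = 3,
#'                        caliber_um_range = c(24, 48))
#' tr$truth_metrics$vad
#' @export
generate_network <- function(seed, field_mm = 3, dim_px = 585L,
                             n_trunks = 12L, branch_rate = 0.08,
                             caliber_um_range = c(12, 28),
                             step_px = 4, max_steps = 90L,
                             max_walks = 10L * n_trunks) {
  if (field_mm <= 0 || dim_px < 16L)
    oq_error("degenerate field", "octaquant_bad_geometry")
  pitch_um <- field_mm * 1000 / dim_px
  if (any(caliber_um_range < pitch_um))
    oq_error("calibers must be at least one pixel pitch", "octaquant_bad_config")
  segments <- with_seed(seed, {
    segs <- list()
    if (n_trunks >= 1L) {
      # walk queue: each entry c(x, y, angle) in pixel coordinates
      queue <- lapply(seq_len(n_trunks), function(i) {
        edge <- sample(4L, 1L)
        pos <- runif(1, 0.05, 0.95) * dim_px
        switch(edge,
               c(pos, 1, stats::runif(1, -pi / 3, pi / 3) + pi / 2),
               c(pos, dim_px, stats::runif(1, -pi / 3, pi / 3) - pi / 2),
               c(1, pos, stats::runif(1, -pi / 3, pi / 3)),
               c(dim_px, pos, stats::runif(1, -pi / 3, pi / 3) + pi))
      })
      n_walks <- 0L
      while (length(queue) && n_walks < max_walks) {
        n_walks <- n_walks + 1L
        st <- queue[[1]]; queue <- queue[-1]
        x <- st[1]; y <- st[2]; ang <- st[3]
        caliber <- stats::runif(1, caliber_um_range[1], caliber_um_range[2])
        pts <- matrix(c(x, y), ncol = 2)
        for (k in seq_len(max_steps)) {
          ang <- ang + stats::rnorm(1, 0, 0.25)
          x2 <- x + step_px * cos(ang); y2 <- y + step_px * sin(ang)
          if (x2 < 1 || x2 > dim_px || y2 < 1 || y2 > dim_px) break
          pts <- rbind(pts, c(x2, y2))
          if (stats::runif(1) < branch_rate && length(queue) < 8L * n_trunks)
            queue <- c(queue, list(c(x2, y2, ang +
              sample(c(-1, 1), 1) * stats::runif(1, pi / 6, pi / 3))))
          x <- x2; y <- y2
        }
        if (nrow(pts) >= 2)
          segs[[length(segs) + 1L]] <- data.frame(
            x0 = pts[-nrow(pts), 1], y0 = pts[-nrow(pts), 2],
            x1 = pts[-1, 1], y1 = pts[-1, 2], caliber_um = caliber)
      }
    }
    if (length(segs)) do.call(rbind, segs)
    else data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                    y1 = numeric(0), caliber_um = numeric(0))
  })
  # convert pixel coordinates to mm for the stored segment list
  px2mm <- field_mm / dim_px
  seg_mm <- segments
  if (nrow(seg_mm)) {
    seg_mm$x0 <- seg_mm$x0 * px2mm; seg_mm$x1 <- seg_mm$x1 * px2mm
    seg_mm$y0 <- seg_mm$y0 * px2mm; seg_mm$y1 <- seg_mm$y1 * px2mm
  }
  rast <- rasterize_segments(segments, dim_px, pitch_um)
  tm <- truth_metrics(rast$binary, rast$skeleton, pitch_um)
  structure(list(segments = seg_mm, truth_binary = rast$binary,
                 truth_skeleton = rast$skeleton, truth_metrics = tm,
                 field_mm = field_mm, dim_px = as.integer(dim_px),
                 pitch_um = pitch_um, seed = seed),
            class = "synthetic_truth")
}

truth_metrics <- function(binary, skeleton, pitch_um) {
  vdi <- compute_vdi(binary, skeleton, pitch_um)
  list(vad = compute_vad(binary), vsd = compute_vsd(skeleton),
       vdi_px = vdi$vdi_px, vdi_um = vdi$vdi_um, vdi_defined = vdi$defined)
}

# Rasterize a segment table (pixel coordinates, caliber in um) into a
# full-caliber binary mask and a 1-px skeleton mask. The binary raster
# marks pixels whose center lies within caliber/2 of a segment; the
# skeleton raster draws each segment with Bresenham stepping. The skeleton
# is unioned into the binary so containment holds exactly even at 1-px
# calibers.
rasterize_segments <- function(segments, dim_px, pitch_um) {
  bin <- matrix(FALSE, dim_px, dim_px)  # rows = y, cols = x
  skel <- matrix(FALSE, dim_px, dim_px)
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    rad_px <- (s$caliber_um / pitch_um) / 2
    # bounding box with margin
    xs <- max(1L, floor(min(s$x0, s$x1) - rad_px - 1)):
          min(dim_px, ceiling(max(s$x0, s$x1) + rad_px + 1))
    ys <- max(1L, floor(min(s$y0, s$y1) - rad_px - 1)):
          min(dim_px, ceiling(max(s$y0, s$y1) + rad_px + 1))
    gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    gy <- matrix(ys, length(ys), length(xs))
    d <- point_segment_dist(gx, gy, s$x0, s$y0, s$x1, s$y1)
    hit <- d <= rad_px
    if (any(hit)) {
      sub <- bin[ys, xs, drop = FALSE]
      bin[ys, xs] <- sub | hit
    }
    # 1-px centerline
    n_steps <- max(2L, ceiling(max(abs(s$x1 - s$x0), abs(s$y1 - s$y0))) + 1L)
    lx <- round(seq(s$x0, s$x1, length.out = n_steps))
    ly <- round(seq(s$y0, s$y1, length.out = n_steps))
    ok <- lx >= 1 & lx <= dim_px & ly >= 1 & ly <= dim_px
    skel[cbind(ly[ok], lx[ok])] <- TRUE
  }
  list(binary = bin | skel, skeleton = skel)
}

point_segment_dist <- function(px, py, x0, y0, x1, y1) {
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - x0)^2 + (py - y0)^2))
  t <- pmin(1, pmax(0, ((px - x0) * dx + (py - y0) * dy) / len2))
  sqrt((px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2)
}

#' Render a phantom into a noisy en-face angiogram
#'
#' Image formation model: `background + contrast * truth_binary`, blurred
#' with an isotropic Gaussian point-spread function, then multiplied by
#' unit-mean gamma speckle (the standard multiplicative noise proxy for
#' OCT-derived images). Deterministic given `seed`.
#'
#' @param truth A `synthetic_truth` from [generate_network()].
#' @param contrast Vessel-over-background signal, in (0, 255]. Default 180.
#' @param psf_sigma_px Gaussian PSF sigma in pixels; 0 disables blur.
#'   Default 1.
#' @param speckle_level Coefficient of variation of the multiplicative
#'   gamma speckle (shape = 1/level^2); 0 disables speckle. Default 0.35.
#' @param seed Integer RNG seed for the speckle field.
#' @param background Background signal level. Default 40.
#' @return An [enface_angiogram()] carrying the phantom seed in `meta`.
#' @export
render <- function(truth, contrast = 180, psf_sigma_px = 1,
                   speckle_level = 0.35, seed = 1L, background = 40) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (contrast <= 0 || contrast > 255)
    oq_error("contrast must be in (0, 255]", "octaquant_bad_config")
  if (speckle_level < 0)
    oq_error("speckle_level must be nonnegative", "octaquant_bad_config")
  img <- background + contrast * truth$truth_binary
  if (psf_sigma_px > 0) {
    g <- gauss_kernel(psf_sigma_px, 0L)
    img <- sepconv(img, g, g)
  }
  if (speckle_level > 0) {
    shape <- 1 / speckle_level^2
    noise <- with_seed(seed,
      matrix(stats::rgamma(length(img), shape = shape, rate = shape),
             nrow(img), ncol(img)))
    img <- img * noise
  }
  enface_angiogram(img, extent_mm = truth$field_mm,
                   meta = list(id = sprintf("phantom-%d", truth$seed),
                               phantom_seed = truth$seed,
                               render_seed = seed))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
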