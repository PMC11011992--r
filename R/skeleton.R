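#' Skeletonize a binary vessel map
#'
#' Topology-preserving parallel thinning (Guo-Hall): pixels are iteratively
#' removed from the outer perimeter of the vessel area map until every
#' segment is one pixel wide. Deletion decisions are evaluated
#' simultaneously over the whole raster in two alternating subiterations,
#' which makes the result deterministic, and the deletion conditions
#' preserve 8-connectivity of foreground and 4-connectivity of background,
#' so the number of components and the loop structure of the network
#' survive thinning.
#'
#' @param binary A `binary_vessel_map` or logical matrix.
#' @return A `skeleton_map`: list with `mask` (logical matrix, a subset of
#'   the input) and `source_id`.
#' @examples
#' bar <- matrix(FALSE, 20, 60); bar[8:12, 5:55] <- TRUE
#' sk <- skeletonize(bar)
#' sum(sk$mask) < sum(bar)
#' @export
skeletonize <- function(binary) {
  mask <- as_mask(binary)
  src <- if (inherits(binary, "binary_vessel_map")) binary$source_id else NA_character_
  m <- thin_guo_hall(mask)
  structure(list(mask = m, source_id = src), class = "skeleton_map")
}

# Guo-Hall (1989) two-subiteration parallel thinning, vectorized over the
# raster. Neighbor labels around p (rows = y down, cols = x right):
#   p9 p2 p3
#   p8 p  p4
#   p7 p6 p5
thin_guo_hall <- function(m) {
  storage.mode(m) <- "logical"
  repeat {
    changed <- FALSE
    for (sub in 0:1) {
      nb <- neighbors8(m)
      p2 <- nb$p2; p3 <- nb$p3; p4 <- nb$p4; p5 <- nb$p5
      p6 <- nb$p6; p7 <- nb$p7; p8 <- nb$p8; p9 <- nb$p9
      C  <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
            (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
      N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      N  <- pmin(N1, N2)
      mcond <- if (sub == 0L) (p6 | p7 | !p9) & p8 else (p2 | p3 | !p5) & p4
      del <- m & C == 1L & N >= 2L & N <= 3L & !mcond
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# The eight shifted copies of a logical matrix (FALSE beyond the border).
neighbors8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  z_row <- rep(FALSE, nc); z_col <- rep(FALSE, nr)
  # pN holds, at each pixel, the state of its neighbor N (p2 = row above).
  p2 <- rbind(z_row, m[-nr, , drop = FALSE])
  p6 <- rbind(m[-1, , drop = FALSE], z_row)
  p4 <- cbind(m[, -1, drop = FALSE], z_col)
  p8 <- cbind(z_col, m[, -nc, drop = FALSE])
  p3 <- cbind(rbind(z_row, m[-nr, , drop = FALSE])[, -1, drop = FALSE], z_col)
  p9 <- cbind(z_col, rbind(z_row, m[-nr, , drop = FALSE])[, -nc, drop = FALSE])
  p5 <- cbind(rbind(m[-1, , drop = FALSE], z_row)[, -1, drop = FALSE], z_col)
  p7 <- cbind(z_col, rbind(m[-1, , drop = FALSE], z_row)[, -nc, drop = FALSE])
  list(p2 = p2, p3 = p3, p4 = p4, p5 = p5, p6 = p6, p7 = p7, p8 = p8, p9 = p9)
}
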