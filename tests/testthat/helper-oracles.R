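# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (nested loops, exhaustive sweeps) and share no code
# with the implementation they check.

# sliding-window local mean with reflective padding, computed pixel by pixel
brute_local_mean <- function(img, w) {
  h <- (w - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  reflect <- function(i, n) {
    # reflect without repeating the edge sample (matches pad_reflect)
    ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
  }
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    acc <- 0
    for (dr in -h:h) for (dc in -h:h)
      acc <- acc + img[reflect(r + dr, nr), reflect(cc + dc, nc)]
    out[r, cc] <- acc / w^2
  }
  out
}

# exhaustive Otsu: try every threshold, maximize between-class variance
# computed directly from the two class splits
brute_otsu <- function(px) {
  best <- -Inf; best_t <- 256L
  n <- length(px)
  for (t in 1:255) {
    lo <- px[px < t]; hi <- px[px >= t]
    if (!length(lo) || !length(hi)) next
    bcv <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; best_t <- t }
  }
  best_t
}

# Gaussian-smoothed Hessian by direct (loop) convolution and central finite
# differences, with eigenvalue extraction; returns the larger-magnitude
# eigenvalue field (negative on bright ridges)
brute_hessian_l2 <- function(img, sigma) {
  h <- max(1, ceiling(3 * sigma))
  k <- outer(-h:h, -h:h, function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  k <- k / sum(k)
  nr <- nrow(img); nc <- ncol(img)
  reflect <- function(i, n) ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
  sm <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    acc <- 0
    for (dr in -h:h) for (dc in -h:h)
      acc <- acc + k[dr + h + 1, dc + h + 1] *
        img[reflect(r + dr, nr), reflect(cc + dc, nc)]
    sm[r, cc] <- acc
  }
  l2 <- matrix(0, nr, nc)
  for (r in 2:(nr - 1)) for (cc in 2:(nc - 1)) {
    hrr <- sm[r + 1, cc] - 2 * sm[r, cc] + sm[r - 1, cc]
    hcc <- sm[r, cc + 1] - 2 * sm[r, cc] + sm[r, cc - 1]
    hrc <- (sm[r + 1, cc + 1] - sm[r + 1, cc - 1] -
              sm[r - 1, cc + 1] + sm[r - 1, cc - 1]) / 4
    disc <- sqrt(((hrr - hcc) / 2)^2 + hrc^2)
    e1 <- (hrr + hcc) / 2 + disc; e2 <- (hrr + hcc) / 2 - disc
    l2[r, cc] <- if (abs(e1) > abs(e2)) e1 else e2
  }
  l2
}

# Hodges-Lehmann by definition
brute_hl <- function(x, y) {
  d <- numeric(0)
  for (xi in x) for (yj in y) d <- c(d, xi - yj)
  median(d)
}

# Friedman chi-square from the rank-sum formula
brute_friedman <- function(grid) {
  n <- nrow(grid); k <- ncol(grid)
  R <- colSums(t(apply(grid, 1, rank)))
  12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
}

# does any on-pixel have its full 3x3 neighborhood on? (width > 1 check)
has_interior_pixel <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3) return(FALSE)
  for (r in 2:(nr - 1)) for (cc in 2:(nc - 1))
    if (all(m[(r - 1):(r + 1), (cc - 1):(cc + 1)])) return(TRUE)
  FALSE
}

random_mask <- function(nr = 32, nc = 32, p = 0.4) {
  matrix(runif(nr * nc) < p, nr, nc)
}

# small standard fixtures
fixture_bar <- function(nr = 20, nc = 60, rows = 8:12, cols = 5:55) {
  m <- matrix(FALSE, nr, nc); m[rows, cols] <- TRUE; m
}
fixture_grid <- function(n = 60, step = 12, width = 3) {
  m <- matrix(FALSE, n, n)
  for (s in seq(step, n - step, by = step)) {
    m[s:(s + width - 1), ] <- TRUE
    m[, s:(s + width - 1)] <- TRUE
  }
  m
}
fixture_blobs <- function() {
  m <- matrix(FALSE, 40, 40)
  m[5:12, 5:12] <- TRUE
  m[25:35, 22:30] <- TRUE
  m
}
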