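# Shared fixtures for the PIV tests: a brute-force spatial-domain
# correlation oracle and analytic Gaussian-spot images that allow exact
# sub-pixel displacements without interpolation.

# O(N^4) circular cross-correlation of mean-subtracted patches, shifted
# so zero lag sits at (n/2 + 1, n/2 + 1) like cross_correlate().
brute_xcorr <- function(a, b) {
  n <- nrow(a)
  a0 <- a - mean(a)
  b0 <- b - mean(b)
  raw <- matrix(0, n, n)
  idx <- seq_len(n)
  for (dy in 0:(n - 1)) {
    rows <- ((idx - 1 + dy) %% n) + 1
    for (dx in 0:(n - 1)) {
      cols <- ((idx - 1 + dx) %% n) + 1
      raw[dy + 1, dx + 1] <- sum(a0 * b0[rows, cols])
    }
  }
  shift <- ((idx - 1 + n / 2) %% n) + 1
  raw[shift, shift]
}

# Image with Gaussian spots at arbitrary (possibly fractional) centers;
# moving the centers gives an exactly displaced image.
spots_image <- function(h, w, cx, cy, sigma = 1.2, peak = 160, background = 20) {
  img <- matrix(background, h, w)
  rad <- ceiling(4 * sigma)
  for (k in seq_along(cx)) {
    j0 <- max(1, floor(cx[k]) - rad); j1 <- min(w, ceiling(cx[k]) + rad)
    i0 <- max(1, floor(cy[k]) - rad); i1 <- min(h, ceiling(cy[k]) + rad)
    if (j0 > j1 || i0 > i1) next
    jj <- j0:j1; ii <- i0:i1
    gx <- exp(-((jj - cx[k])^2) / (2 * sigma^2))
    gy <- exp(-((ii - cy[k])^2) / (2 * sigma^2))
    img[ii, jj] <- img[ii, jj] + peak * outer(gy, gx)
  }
  img
}

# Random seeded particle texture plus the same spots displaced by
# (dx, dy) pixels (no wraparound; spots near the border simply move).
texture_pair <- function(h = 140, w = 180, n_spots = 80, dx = 0, dy = 0,
                         seed = 1, sigma = 1.2) {
  set.seed(seed)
  cx <- runif(n_spots, 5, w - 5)
  cy <- runif(n_spots, 5, h - 5)
  list(a = spots_image(h, w, cx, cy, sigma),
       b = spots_image(h, w, cx + dx, cy + dy, sigma),
       cx = cx, cy = cy)
}
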