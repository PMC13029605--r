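test_that("FFT correlation matches the brute-force spatial oracle", {
  set.seed(42)
  for (k in 1:20) {
    a <- matrix(runif(16 * 16), 16, 16)
    b <- matrix(runif(16 * 16), 16, 16)
    expect_equal(max(abs(cross_correlate(a, b) - brute_xcorr(a, b))), 0,
                 tolerance = 1e-8)
  }
})

test_that("correlation peak sits at zero lag for identical patches and at the shift for rolled ones", {
  set.seed(7)
  a <- matrix(runif(32 * 32), 32, 32)
  auto <- cross_correlate(a, a)
  expect_equal(which(auto == max(auto), arr.ind = TRUE)[1, ],
               c(row = 17, col = 17))
  # circular roll by (+5 columns, +3 rows)
  roll <- function(m, dy, dx) {
    m[((seq_len(nrow(m)) - 1 - dy) %% nrow(m)) + 1,
      ((seq_len(ncol(m)) - 1 - dx) %% ncol(m)) + 1]
  }
  b <- roll(a, 3, 5)
  pl <- cross_correlate(a, b)
  expect_equal(which(pl == max(pl), arr.ind = TRUE)[1, ],
               c(row = 17 + 3, col = 17 + 5))
})

test_that("degenerate and malformed patches are handled", {
  flat <- matrix(5, 16, 16)
  set.seed(1)
  tex <- matrix(runif(256), 16, 16)
  pl <- cross_correlate(flat, tex)
  expect_true(attr(pl, "degenerate"))
  expect_error(cross_correlate(tex, matrix(0, 8, 8)), "identical shape")
  expect_error(cross_correlate(matrix(runif(15 * 15), 15, 15),
                               matrix(runif(15 * 15), 15, 15)),
               "power of two")
})

test_that("sub-pixel fit is exact on symmetric and Gaussian-sampled peaks", {
  # symmetric plane: zero sub-pixel offset
  g <- function(x, y, x0, y0, s = 1.2) exp(-((x - x0)^2 + (y - y0)^2) / (2 * s^2))
  mk_plane <- function(x0, y0) {
    n <- 16
    outer(seq_len(n) - (n / 2 + 1), seq_len(n) - (n / 2 + 1),
          function(dy, dx) g(dx, dy, x0, y0))
  }
  sym <- subpixel_peak(mk_plane(0, 0))
  expect_equal(unname(sym["dx"]), 0)
  expect_equal(unname(sym["dy"]), 0)
  # plane sampled from a Gaussian centered at +0.30 px: log-Gaussian fit is exact
  off <- subpixel_peak(mk_plane(0.30, -0.15))
  expect_equal(unname(off["dx"]), 0.30, tolerance = 0.02)
  expect_equal(unname(off["dy"]), -0.15, tolerance = 0.02)
  expect_equal(unname(attr(off, "method")["x"]), "gaussian")
  # border maximum cannot be refined
  edge <- matrix(0, 16, 16); edge[1, 5] <- 1
  res <- subpixel_peak(edge)
  expect_false(attr(res, "valid"))
  expect_true(all(is.na(res)))
})

test_that("multipass recovers rigid translations to 0.1 px", {
  # identical frames (texture in every window): zero displacement everywhere
  set.seed(1)
  noise_frame <- matrix(runif(140 * 180), 140, 180)
  f0 <- multipass_piv(noise_frame, noise_frame)
  expect_true(all(f0$valid))
  expect_equal(max(abs(f0$dx)), 0, tolerance = 1e-6)
  expect_equal(max(abs(f0$dy)), 0, tolerance = 1e-6)

  # sub-pixel translation
  tp <- texture_pair(dx = 2.5, dy = 0, seed = 2)
  fld <- multipass_piv(tp$a, tp$b)
  expect_equal(median(fld$dx[fld$valid]), 2.5, tolerance = 0.1)
  expect_equal(median(fld$dy[fld$valid]), 0, tolerance = 0.05)

  # a spread of displacements up to first_window / 4
  for (seed in 1:10) {
    set.seed(seed + 100)
    d <- runif(2, -4, 4)
    tp <- texture_pair(dx = d[1], dy = d[2], seed = seed + 100)
    fld <- multipass_piv(tp$a, tp$b)
    expect_lt(abs(median(fld$dx[fld$valid]) - d[1]), 0.1)
    expect_lt(abs(median(fld$dy[fld$valid]) - d[2]), 0.1)
  }
})

test_that("multipass resolves a linear shear field to 0.2 px per vector", {
  set.seed(31)
  h <- 140; w <- 180
  cx <- runif(300, 5, w - 5)
  cy <- runif(300, 5, h - 5)
  shear <- function(y) 3 * (y - 1) / (h - 1)  # 0 at top to 3 px at bottom
  a <- spots_image(h, w, cx, cy)
  b <- spots_image(h, w, cx + shear(cy), cy)
  fld <- multipass_piv(a, b)
  expected <- shear(fld$y)
  err <- abs(fld$dx - expected)[fld$valid]
  expect_lt(stats::quantile(err, 0.95), 0.2)
  expect_lt(max(abs(fld$dy[fld$valid])), 0.2)
})

test_that("swapping the frame order negates the displacements", {
  tp <- texture_pair(dx = 1.7, dy = -0.6, seed = 9)
  fwd <- multipass_piv(tp$a, tp$b)
  bwd <- multipass_piv(tp$b, tp$a)
  keep <- fwd$valid & bwd$valid
  expect_equal(median((fwd$dx + bwd$dx)[keep]), 0, tolerance = 0.05)
  expect_equal(median((fwd$dy + bwd$dy)[keep]), 0, tolerance = 0.05)
})

test_that("the output grid is a pure function of frame shape and config", {
  tp1 <- texture_pair(seed = 1)
  tp2 <- texture_pair(seed = 2, dx = 3)
  f1 <- multipass_piv(tp1$a, tp1$b)
  f2 <- multipass_piv(tp2$a, tp2$b)
  expect_identical(f1$x, f2$x)
  expect_identical(f1$y, f2$y)
  expect_identical(attr(f1, "nx"), attr(f2, "nx"))
  # window sizes: strictly decreasing powers of two enforced
  expect_error(piv_config(window_sizes = c(32, 32, 16)), "decreasing")
  expect_error(piv_config(window_sizes = c(48, 24, 12)), "powers of two")
  expect_error(multipass_piv(matrix(0, 32, 32), matrix(0, 32, 32)),
               "smaller than the first")
})

test_that("normalized-median validation flags exactly the planted outlier", {
  # uniform synthetic field on an 8 x 6 grid
  nx <- 8; ny <- 6
  fld <- structure(
    data.frame(x = rep(seq(8, by = 8, length.out = nx), each = ny),
               y = rep(seq(8, by = 8, length.out = ny), times = nx),
               dx = 1.5, dy = -0.5, peak = 1, peak_ratio = 5, valid = TRUE),
    nx = nx, ny = ny, window = 16, frame_dim = c(64, 80), overlap = 0.5,
    class = c("displacement_field", "data.frame"))
  clean <- validate_vectors(fld, threshold = 2)
  expect_true(all(clean$valid))  # uniform field: nothing flagged
  # plant a gross outlier mid-grid
  mid <- ny * 3 + 3
  fld$dx[mid] <- fld$dx[mid] + 10
  checked <- validate_vectors(fld, threshold = 2)
  expect_false(checked$valid[mid])
  expect_equal(sum(!checked$valid), 1)
  # threshold -> Inf disables the test
  untouched <- validate_vectors(fld, threshold = Inf)
  expect_identical(untouched$valid, fld$valid)
  # replacement: the outlier becomes the local neighbor mean
  repl <- validate_vectors(fld, threshold = 2, replace_invalid = TRUE)
  expect_equal(repl$dx[mid], 1.5, tolerance = 1e-12)
  expect_equal(repl$dy[mid], -0.5, tolerance = 1e-12)
})

test_that("velocity conversion applies the optical calibration", {
  tp <- texture_pair(dx = 1, seed = 3)
  fld <- multipass_piv(tp$a, tp$b)
  v <- to_velocity(fld, frame_rate = 57, sensor_pixel_um = 7.4,
                   magnification = 10)
  expect_equal(v$vx_mm_s, fld$dx * 0.74e-3 * 57)
  # 1 px/frame at 57 FPS with 0.74 um pixels is 0.04218 mm/s
  expect_equal(1 * 0.74e-3 * 57, 0.04218)
  v2 <- to_velocity(fld, frame_rate = 57, sensor_pixel_um = 7.4,
                    magnification = 20)
  expect_equal(v2$vx_mm_s, v$vx_mm_s / 2)
  expect_error(to_velocity(fld), "calibration")
  expect_error(to_velocity(fld, frame_rate = -1, sensor_pixel_um = 7.4,
                           magnification = 10), "positive")
})

test_that("piv_stack processes consecutive pairs at the frame rate", {
  set.seed(5)
  n_frames <- 6
  cx <- runif(120, 5, 175); cy <- runif(120, 5, 135)
  frames <- array(0, c(140, 180, n_frames))
  for (i in seq_len(n_frames)) {
    frames[, , i] <- spots_image(140, 180, cx + (i - 1) * 1.5, cy)
  }
  ds <- piv_stack(frames, frame_rate = 57, pixel_pitch_um = 0.74)
  expect_equal(dim(ds$dx)[1], n_frames - 1)
  expect_equal(ds$times_s, (0:(n_frames - 2)) / 57)
  med <- apply(ds$dx, 1, function(r) median(r[!is.na(r)]))
  expect_equal(med, rep(1.5, n_frames - 1), tolerance = 0.1)
})
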