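#' PIV configuration
#'
#' Settings for the multi-pass interrogation scheme: window sizes per
#' pass (strictly decreasing powers of two; the default 64-32-16 is the
#' standard three-pass refinement), window overlap fraction, sub-pixel
#' estimator, and the normalized-median validation threshold.
#'
#' @param window_sizes Ordered interrogation window sizes in pixels.
#' @param overlap Overlap fraction between neighboring windows, in
#'   `[0, 1)`.
#' @param subpixel Sub-pixel peak estimator; three-point Gaussian with
#'   parabolic fallback.
#' @param validation_threshold Normalized-median test threshold
#'   (dimensionless); `Inf` disables validation.
#' @param replace_invalid Replace flagged vectors by the local mean of
#'   their valid neighbors.
#' @param weighting Interrogation-window weighting: `"gaussian"`
#'   (sigma = window/4, suppresses border-truncated particle images and
#'   the sub-pixel bias they cause) or `"none"`.
#' @return A `piv_config` object.
#' @export
piv_config <- function(window_sizes = c(64, 32, 16), overlap = 0.5,
                       subpixel = "gaussian-3pt",
                       validation_threshold = 2.0, replace_invalid = TRUE,
                       weighting = c("gaussian", "none")) {
  weighting <- match.arg(weighting)
  window_sizes <- as.integer(window_sizes)
  if (any(diff(window_sizes) >= 0)) {
    stop("window_sizes must be strictly decreasing", call. = FALSE)
  }
  if (any(bitwAnd(window_sizes, window_sizes - 1L) != 0L) || any(window_sizes < 4L)) {
    stop("window_sizes must be powers of two (>= 4)", call. = FALSE)
  }
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)", call. = FALSE)
  structure(
    list(window_sizes = window_sizes, overlap = overlap,
         subpixel = subpixel, validation_threshold = validation_threshold,
         replace_invalid = replace_invalid, weighting = weighting),
    class = "piv_config"
  )
}

# Regular interrogation grid for one pass. Returns 0-based window
# top-left corners (for the C++ core) and 1-based window centers in
# pixel coordinates. Grid geometry depends only on the frame shape and
# the pass settings.
piv_grid <- function(frame_dim, window, overlap) {
  h <- frame_dim[1]; w <- frame_dim[2]
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  if (w < window || h < window) {
    stop("frame smaller than interrogation window", call. = FALSE)
  }
  x0 <- seq(0L, w - window, by = step)
  y0 <- seq(0L, h - window, by = step)
  nx <- length(x0); ny <- length(y0)
  # column-major layout: y varies fastest, matching matrix(v, ny, nx)
  gx0 <- rep(x0, each = ny)
  gy0 <- rep(y0, times = nx)
  list(x0 = gx0, y0 = gy0, cx = gx0 + window / 2 + 0.5,
       cy = gy0 + window / 2 + 0.5, nx = nx, ny = ny, window = window)
}

# Linear interpolation operator from one sorted coordinate vector to
# another (clamped at the hull); returns a dense (length(to) x
# length(from)) matrix so grid-to-grid transfer is two matrix products.
interp_operator <- function(from, to) {
  n <- length(from)
  W <- matrix(0, length(to), n)
  if (n == 1L) { W[, 1] <- 1; return(W) }
  idx <- findInterval(to, from, all.inside = TRUE)
  frac <- (to - from[idx]) / (from[idx + 1] - from[idx])
  frac <- pmin(pmax(frac, 0), 1)
  for (i in seq_along(to)) {
    W[i, idx[i]] <- 1 - frac[i]
    W[i, idx[i] + 1] <- W[i, idx[i] + 1] + frac[i]
  }
  W
}

#' FFT cross-correlation of two interrogation windows
#'
#' Circular cross-correlation of two equal square patches, computed via
#' the forward/inverse 2-D DFT of the mean-subtracted patches. The
#' returned plane is shifted so the zero-lag element sits at row/column
#' `n/2 + 1`; the peak location gives the integer displacement of `b`
#' relative to `a`.
#'
#' @param a,b Equal-sized square numeric matrices with finite values.
#' @return Correlation plane (same size). If either patch has zero
#'   variance the correlation is undefined; a zero plane with attribute
#'   `degenerate = TRUE` is returned.
#' @export
cross_correlate <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("patches must have identical shape", call. = FALSE)
  if (nrow(a) != ncol(a)) stop("patches must be square", call. = FALSE)
  n <- nrow(a)
  if (n < 4 || bitwAnd(n, n - 1L) != 0L) {
    stop("patch size must be a power of two (>= 4)", call. = FALSE)
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("patches must contain finite values", call. = FALSE)
  }
  storage.mode(a) <- "double"; storage.mode(b) <- "double"
  degenerate <- sd(a) < 1e-12 || sd(b) < 1e-12
  plane <- if (degenerate) {
    matrix(0, nrow(a), ncol(a))
  } else {
    cpp_xcorr_plane(a, b)
  }
  attr(plane, "degenerate") <- degenerate
  plane
}

#' Sub-pixel correlation peak localization
#'
#' Refines the integer peak of a (centered) correlation plane with a
#' three-point Gaussian fit per axis,
#' \eqn{\delta = (\ln c_- - \ln c_+) / (2\ln c_- - 4\ln c_0 + 2\ln c_+)},
#' falling back to a parabolic fit when any of the three samples is not
#' positive. A maximum on the plane border cannot be refined and yields
#' an invalid result.
#'
#' @param plane Correlation plane as returned by [cross_correlate()].
#' @return Numeric `c(dx, dy)` displacement in pixels relative to zero
#'   lag, with attributes `valid` and `method`
#'   (`"gaussian"`/`"parabolic"`). Border maxima give `c(NA, NA)` with
#'   `valid = FALSE`.
#' @export
subpixel_peak <- function(plane) {
  plane <- as.matrix(plane)
  n <- nrow(plane)
  k <- which.max(plane)
  pr <- (k - 1L) %% n + 1L
  pc <- (k - 1L) %/% n + 1L
  if (pr == 1L || pr == n || pc == 1L || pc == ncol(plane)) {
    out <- c(dx = NA_real_, dy = NA_real_)
    attr(out, "valid") <- FALSE
    return(out)
  }
  c0 <- plane[pr, pc]
  fit1d <- function(cm, c0, cp) {
    if (cm > 0 && c0 > 0 && cp > 0) {
      den <- 2 * log(cm) - 4 * log(c0) + 2 * log(cp)
      if (abs(den) > 0) {
        d <- (log(cm) - log(cp)) / den
        if (is.finite(d) && abs(d) < 1) return(list(d = d, method = "gaussian"))
      }
    }
    den <- 2 * (cm - 2 * c0 + cp)
    d <- if (abs(den) > 0) (cm - cp) / den else 0
    if (!is.finite(d) || abs(d) >= 1) d <- 0
    list(d = d, method = "parabolic")
  }
  fy <- fit1d(plane[pr - 1L, pc], c0, plane[pr + 1L, pc])
  fx <- fit1d(plane[pr, pc - 1L], c0, plane[pr, pc + 1L])
  center <- n / 2 + 1
  out <- c(dx = pc - center + fx$d, dy = pr - center + fy$d)
  attr(out, "valid") <- TRUE
  attr(out, "method") <- c(x = fx$method, y = fy$method)
  out
}

# Precompute everything that depends only on the frame shape and the
# configuration: per-pass grids and the grid-to-grid interpolation
# operators used to transfer displacement predictions between passes.
make_piv_plan <- function(frame_dim, config) {
  grids <- lapply(config$window_sizes, function(w)
    piv_grid(frame_dim, w, config$overlap))
  ops <- vector("list", length(grids))
  for (p in seq_len(length(grids) - 1)) {
    g <- grids[[p]]; gn <- grids[[p + 1]]
    ops[[p]] <- list(
      Wy = interp_operator(unique(g$cy), unique(gn$cy)),
      Wx = t(interp_operator(unique(g$cx), unique(gn$cx)))
    )
  }
  list(grids = grids, ops = ops)
}

# Shared multi-pass engine. Frames as numeric matrices; the plan is
# precomputed once per stack by the callers. Returns final-pass vectors.
piv_pair_core <- function(frame_a, frame_b, plan, config) {
  grids <- plan$grids
  n_pass <- length(grids)
  offx <- integer(length(grids[[1]]$x0))
  offy <- integer(length(grids[[1]]$x0))
  dx <- dy <- peak <- ratio <- valid <- NULL
  for (p in seq_len(n_pass)) {
    g <- grids[[p]]
    res <- cpp_piv_pass(frame_a, frame_b, g$x0, g$y0, g$window, offx, offy,
                        identical(config$weighting, "gaussian"))
    dx <- res[, 1]; dy <- res[, 2]
    peak <- res[, 3]; ratio <- res[, 4]
    valid <- res[, 5] == 0 & res[, 6] == 0 & !is.na(dx)
    if (g$nx >= 3 && g$ny >= 3 && is.finite(config$validation_threshold)) {
      nmt <- cpp_nmt(dx, dy, valid, g$ny, g$nx,
                     config$validation_threshold, 0.1)
      outlier <- nmt[, 1] == 1
      valid <- valid & !outlier
      replace_now <- if (p < n_pass) TRUE else config$replace_invalid
      if (replace_now) {
        bad <- !valid & !is.na(nmt[, 2])
        dx[bad] <- nmt[bad, 2]
        dy[bad] <- nmt[bad, 3]
      }
    }
    if (all(!valid) && p == n_pass) {
      if (all(res[, 5] == 1)) stop("all interrogation windows degenerate", call. = FALSE)
    }
    if (p < n_pass) {
      dxm <- matrix(ifelse(is.na(dx), 0, dx), g$ny, g$nx)
      dym <- matrix(ifelse(is.na(dy), 0, dy), g$ny, g$nx)
      op <- plan$ops[[p]]
      offx <- as.integer(round(op$Wy %*% dxm %*% op$Wx))
      offy <- as.integer(round(op$Wy %*% dym %*% op$Wx))
    }
  }
  list(dx = dx, dy = dy, peak = peak, ratio = ratio, valid = valid)
}

#' Multi-pass PIV on a single frame pair
#'
#' Runs the multi-pass interrogation scheme: the first pass correlates
#' coarse windows on a regular grid; each subsequent pass halves the
#' window size and pre-shifts the windows of `frame_b` by the rounded
#' displacement interpolated from the previous (validated) pass, so the
#' residual displacement stays small relative to the window. Vectors are
#' screened with the normalized-median test after every pass.
#'
#' @param frame_a,frame_b Grayscale frames (numeric matrices of equal
#'   shape, at least as large as the first window).
#' @param config A [piv_config()].
#' @return A `displacement_field` data frame with one row per final-pass
#'   interrogation window: window center `x`, `y` (px), displacement
#'   `dx`, `dy` (px/frame-pair, positive x rightwards / y downwards),
#'   normalized correlation `peak`, first-to-second `peak_ratio`, and
#'   `valid`. Grid shape is stored in attributes `nx`, `ny`, `window`.
#' @export
multipass_piv <- function(frame_a, frame_b, config = piv_config()) {
  frame_a <- as.matrix(frame_a); frame_b <- as.matrix(frame_b)
  if (!all(dim(frame_a) == dim(frame_b))) {
    stop("frames must have identical shape", call. = FALSE)
  }
  if (any(dim(frame_a) < config$window_sizes[1])) {
    stop("frames smaller than the first interrogation window", call. = FALSE)
  }
  storage.mode(frame_a) <- "double"; storage.mode(frame_b) <- "double"
  plan <- make_piv_plan(dim(frame_a), config)
  res <- piv_pair_core(frame_a, frame_b, plan, config)
  g <- plan$grids[[length(plan$grids)]]
  out <- data.frame(x = g$cx, y = g$cy, dx = res$dx, dy = res$dy,
                    peak = res$peak, peak_ratio = res$ratio,
                    valid = res$valid)
  structure(out, nx = g$nx, ny = g$ny, window = g$window,
            frame_dim = dim(frame_a), overlap = config$overlap,
            class = c("displacement_field", "data.frame"))
}

#' Normalized-median vector validation
#'
#' Flags outlier vectors by comparing each vector to the median of its
#' 8-neighborhood: `residual = |v - median| / (MAD + 0.1 px)` per
#' component, flagged when the residual exceeds `threshold`. Flagged
#' vectors are optionally replaced by the local mean of their valid
#' neighbors.
#'
#' @param field A `displacement_field` from [multipass_piv()].
#' @param threshold Residual threshold; `Inf` leaves the field
#'   unchanged.
#' @param replace_invalid Replace flagged vectors by the neighbor mean.
#' @return The field with updated `valid` (and possibly `dx`, `dy`).
#' @export
validate_vectors <- function(field, threshold = 2.0, replace_invalid = FALSE) {
  stopifnot(inherits(field, "displacement_field"))
  nx <- attr(field, "nx"); ny <- attr(field, "ny")
  if (nx < 3 || ny < 3) {
    warning("grid smaller than 3x3; validation skipped")
    return(field)
  }
  if (!is.finite(threshold)) return(field)
  nmt <- cpp_nmt(field$dx, field$dy, field$valid, ny, nx, threshold, 0.1)
  outlier <- nmt[, 1] == 1
  field$valid <- field$valid & !outlier
  if (replace_invalid) {
    bad <- !field$valid & !is.na(nmt[, 2])
    field$dx[bad] <- nmt[bad, 2]
    field$dy[bad] <- nmt[bad, 3]
  }
  field
}

#' Convert pixel displacements to physical velocities
#'
#' `v [mm/s] = d [px] * (sensor_pixel / magnification) * 1e-3 [mm/px] *
#' frame_rate [1/s]`. The x axis is flow-parallel (image horizontal),
#' y transverse (image vertical, downwards positive).
#'
#' @param field A `displacement_field` (single pair) or
#'   `displacement_stack` (see [piv_stack()]).
#' @param frame_rate Frames per second.
#' @param sensor_pixel_um Sensor pixel size, micrometers.
#' @param magnification Objective magnification.
#' @param camera Optionally a [camera_model()] supplying all three.
#' @return The same structure with `vx_mm_s`, `vy_mm_s` (single pair) or
#'   velocity matrices (stack), class `velocity_field` /
#'   `velocity_stack`.
#' @export
to_velocity <- function(field, frame_rate = NULL, sensor_pixel_um = NULL,
                        magnification = NULL, camera = NULL) {
  if (!is.null(camera)) {
    frame_rate <- camera$frame_rate
    sensor_pixel_um <- camera$sensor_pixel_um
    magnification <- camera$magnification
  }
  if (inherits(field, "displacement_stack")) {
    if (is.null(frame_rate)) frame_rate <- field$frame_rate
    if (is.null(sensor_pixel_um) && !is.null(field$pixel_pitch_um)) {
      sensor_pixel_um <- field$pixel_pitch_um
      magnification <- 1
    }
  }
  if (is.null(frame_rate) || is.null(sensor_pixel_um) || is.null(magnification)) {
    stop("calibration metadata (frame rate, pixel size, magnification) required",
         call. = FALSE)
  }
  if (frame_rate <= 0 || sensor_pixel_um <= 0 || magnification <= 0) {
    stop("calibration constants must be positive", call. = FALSE)
  }
  scale <- (sensor_pixel_um / magnification) * 1e-3 * frame_rate
  if (inherits(field, "displacement_field")) {
    field$vx_mm_s <- field$dx * scale
    field$vy_mm_s <- field$dy * scale
    class(field) <- c("velocity_field", class(field))
    return(field)
  }
  if (inherits(field, "displacement_stack")) {
    field$vx_mm_s <- field$dx * scale
    field$vy_mm_s <- field$dy * scale
    class(field) <- c("velocity_stack", class(field))
    return(field)
  }
  stop("unsupported input to to_velocity", call. = FALSE)
}

#' Multi-pass PIV over a whole frame stack
#'
#' Applies [multipass_piv()] to every consecutive frame pair
#' `(t, t + 1)` of a stack, so the velocity sample rate equals the
#' camera frame rate. Results are stored as matrices (one row per frame
#' pair, one column per interrogation window) for compact downstream
#' processing.
#'
#' @param stack A `frame_stack` from [render_frames()] /
#'   [read_frame_stack()], or a numeric 3-D array (height, width,
#'   frames).
#' @param config A [piv_config()].
#' @param frame_rate,pixel_pitch_um Acquisition metadata; taken from the
#'   stack when available.
#' @return A `displacement_stack`: matrices `dx`, `dy` (px/frame-pair),
#'   `valid`, pair timestamps `times_s`, the final interrogation grid,
#'   and acquisition metadata.
#' @export
piv_stack <- function(stack, config = piv_config(), frame_rate = NULL,
                      pixel_pitch_um = NULL) {
  if (inherits(stack, "frame_stack")) {
    frames <- stack$frames
    if (is.null(frame_rate)) frame_rate <- stack$frame_rate
    if (is.null(pixel_pitch_um)) pixel_pitch_um <- stack$pixel_pitch_um
  } else {
    frames <- stack
  }
  dims <- dim(frames)
  if (length(dims) != 3 || dims[3] < 2) {
    stop("stack must contain at least two frames", call. = FALSE)
  }
  plan <- make_piv_plan(dims[1:2], config)
  g <- plan$grids[[length(plan$grids)]]
  n_pairs <- dims[3] - 1L
  n_vec <- length(g$x0)
  dx <- matrix(NA_real_, n_pairs, n_vec)
  dy <- matrix(NA_real_, n_pairs, n_vec)
  valid <- matrix(FALSE, n_pairs, n_vec)
  a <- frames[, , 1]
  storage.mode(a) <- "double"
  for (i in seq_len(n_pairs)) {
    b <- frames[, , i + 1]
    storage.mode(b) <- "double"
    res <- piv_pair_core(a, b, plan, config)
    dx[i, ] <- res$dx
    dy[i, ] <- res$dy
    valid[i, ] <- res$valid
    a <- b
  }
  structure(
    list(dx = dx, dy = dy, valid = valid,
         times_s = (seq_len(n_pairs) - 1) / ifelse(is.null(frame_rate), 1, frame_rate),
         grid = list(x = g$cx, y = g$cy, nx = g$nx, ny = g$ny),
         window = g$window, frame_rate = frame_rate,
         pixel_pitch_um = pixel_pitch_um),
    class = "displacement_stack"
  )
}
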