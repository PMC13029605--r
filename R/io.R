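#' Write / read a frame stack as multi-page TIFF with JSON sidecar
#'
#' Frames are written as 8-bit grayscale pages; acquisition metadata
#' (frame rate, object-plane pixel pitch, ROI, seed) goes into a JSON
#' sidecar next to the TIFF so a stack re-read from disk carries its
#' calibration. Requires the `tiff` package.
#'
#' @param stack A `frame_stack` from [render_frames()].
#' @param path Output TIFF path.
#' @param sidecar Write the JSON sidecar (`<path>.json`).
#' @return `write_frame_stack` returns `path` invisibly;
#'   `read_frame_stack` returns a `frame_stack`.
#' @export
write_frame_stack <- function(stack, path, sidecar = TRUE) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF io", call. = FALSE)
  }
  pages <- lapply(seq_len(stack$n_frames), function(i)
    stack$frames[, , i] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  if (sidecar) {
    meta <- list(frame_rate = stack$frame_rate,
                 pixel_pitch_um = stack$pixel_pitch_um,
                 roi_px = stack$roi_px, n_frames = stack$n_frames,
                 seed = stack$seed)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF io", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- array(0L, c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) {
    pg <- pages[[i]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    frames[, , i] <- as.integer(round(pg * 255))
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  structure(
    list(frames = frames,
         frame_rate = meta$frame_rate,
         pixel_pitch_um = meta$pixel_pitch_um,
         n_frames = dim(frames)[3],
         roi_px = if (!is.null(meta$roi_px)) meta$roi_px else rev(dim(frames)[1:2]),
         condition = NULL, camera = NULL, seed = meta$seed),
    class = "frame_stack"
  )
}

#' Write / read a flow-sensor trace as CSV
#'
#' Two-column CSV (`time_s`, `flow_ml_min`).
#'
#' @param trace Data frame from [simulate_flow_sensor()] or a sensor.
#' @param path CSV path.
#' @export
write_flow_trace <- function(trace, path) {
  stopifnot(all(c("time_s", "flow_ml_min") %in% names(trace)))
  write.csv(trace[, c("time_s", "flow_ml_min")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flow_trace
#' @export
read_flow_trace <- function(path) {
  read.csv(path)
}

#' Export a velocity stack as a long-format CSV
#'
#' One row per (frame pair, interrogation window): `t_s`, `x_px`,
#' `y_px`, `vx_mm_s`, `vy_mm_s`, `valid`.
#'
#' @param vstack A `velocity_stack` from [to_velocity()].
#' @param path CSV path.
#' @export
write_velocity_fields <- function(vstack, path) {
  stopifnot(inherits(vstack, "velocity_stack"))
  n_pairs <- nrow(vstack$vx_mm_s)
  n_vec <- ncol(vstack$vx_mm_s)
  out <- data.frame(
    t_s = rep(vstack$times_s, times = n_vec),
    x_px = rep(vstack$grid$x, each = n_pairs),
    y_px = rep(vstack$grid$y, each = n_pairs),
    vx_mm_s = as.vector(vstack$vx_mm_s),
    vy_mm_s = as.vector(vstack$vy_mm_s),
    valid = as.vector(vstack$valid)
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
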