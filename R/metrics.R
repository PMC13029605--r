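#' Uniformly sampled velocity trace
#'
#' @param values Velocity samples, mm/s.
#' @param sample_rate Sampling rate, Hz (the camera frame rate for
#'   PIV-derived traces).
#' @param component `"x"` (flow-parallel) or `"y"` (transverse).
#' @return A `velocity_trace` object.
#' @export
velocity_trace <- function(values, sample_rate, component = c("x", "y")) {
  component <- match.arg(component)
  stopifnot(is.numeric(values), sample_rate > 0)
  structure(
    list(values = as.numeric(values), sample_rate = sample_rate,
         component = component),
    class = "velocity_trace"
  )
}

#' Spatially averaged velocity traces from a velocity stack
#'
#' For every frame pair, the arithmetic mean of the valid vectors'
#' velocity components inside the (optional) region of interest. Frame
#' pairs with no valid vector are filled by linear interpolation from
#' their neighbors so the trace stays uniformly sampled for the DFT;
#' their count is recorded in attribute `n_interpolated`.
#'
#' @param vstack A `velocity_stack` from [to_velocity()], or a
#'   `displacement_stack` combined with `camera`.
#' @param roi Optional `c(xmin, xmax, ymin, ymax)` in pixels selecting a
#'   subset of interrogation windows.
#' @param camera Optional [camera_model()] used to convert a
#'   displacement stack on the fly.
#' @return List with elements `x` and `y`, each a [velocity_trace()].
#' @export
spatial_mean <- function(vstack, roi = NULL, camera = NULL) {
  if (inherits(vstack, "displacement_stack") && !inherits(vstack, "velocity_stack")) {
    vstack <- to_velocity(vstack, camera = camera)
  }
  stopifnot(inherits(vstack, "velocity_stack"))
  keep <- rep(TRUE, length(vstack$grid$x))
  if (!is.null(roi)) {
    keep <- vstack$grid$x >= roi[1] & vstack$grid$x <= roi[2] &
      vstack$grid$y >= roi[3] & vstack$grid$y <= roi[4]
    if (!any(keep)) stop("ROI contains no interrogation windows", call. = FALSE)
  }
  vx <- vstack$vx_mm_s[, keep, drop = FALSE]
  vy <- vstack$vy_mm_s[, keep, drop = FALSE]
  valid <- vstack$valid[, keep, drop = FALSE]
  nv <- rowSums(valid)
  if (all(nv == 0)) stop("no valid vectors in any frame pair", call. = FALSE)
  mean_masked <- function(m) {
    s <- rowSums(ifelse(valid, m, 0))
    out <- ifelse(nv > 0, s / pmax(nv, 1), NA_real_)
    if (anyNA(out)) {
      idx <- seq_along(out)
      out <- approx(idx[!is.na(out)], out[!is.na(out)], xout = idx,
                    rule = 2)$y
    }
    out
  }
  fs <- vstack$frame_rate
  tx <- velocity_trace(mean_masked(vx), fs, "x")
  ty <- velocity_trace(mean_masked(vy), fs, "y")
  attr(tx, "n_interpolated") <- sum(nv == 0)
  attr(ty, "n_interpolated") <- sum(nv == 0)
  list(x = tx, y = ty)
}

#' Velocity range
#'
#' The primary time-domain response metric: the difference between the
#' maximum and minimum of the spatially averaged velocity trace,
#' \eqn{r = \max \bar V_i(t) - \min \bar V_i(t)}.
#'
#' @param trace A [velocity_trace()] or numeric vector.
#' @return Range in the trace's units (mm/s), always >= 0.
#' @export
velocity_range <- function(trace) {
  v <- if (inherits(trace, "velocity_trace")) trace$values else as.numeric(trace)
  if (length(v) == 0) stop("empty trace", call. = FALSE)
  max(v) - min(v)
}

#' One-sided amplitude spectrum of a velocity trace
#'
#' The trace mean is removed, then the one-sided amplitude spectrum is
#' computed as `2 |DFT| / N` for the non-DC bins (the Nyquist bin of an
#' even-length trace is not doubled); the DC bin is 0 after mean
#' removal. No taper is applied by default: for a recording spanning an
#' integer number of protocol periods the modulation line falls on an
#' exact bin and is leak-free. A Hann window is available for other
#' protocols.
#'
#' @param trace A [velocity_trace()].
#' @param window `"rectangular"` (default) or `"hann"`.
#' @return A `spectral_response`: `frequency_hz` (0 to Nyquist, spaced
#'   by `sample_rate / N`), `amplitude` (mm/s per bin), `resolution_hz`,
#'   and the trace component.
#' @export
amplitude_spectrum <- function(trace, window = c("rectangular", "hann")) {
  stopifnot(inherits(trace, "velocity_trace"))
  window <- match.arg(window)
  v <- trace$values
  n <- length(v)
  if (n < 16) stop("trace too short for spectral analysis (need >= 16 samples)",
                   call. = FALSE)
  v <- v - mean(v)
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
    v <- v * w / mean(w)
  }
  sp <- fft(v)
  n_half <- floor(n / 2)
  amp <- 2 * Mod(sp[seq_len(n_half + 1)]) / n
  amp[1] <- 0
  if (n %% 2 == 0) amp[n_half + 1] <- amp[n_half + 1] / 2
  structure(
    list(frequency_hz = (0:n_half) * trace$sample_rate / n,
         amplitude = amp, resolution_hz = trace$sample_rate / n,
         component = trace$component, n = n, window = window),
    class = "spectral_response"
  )
}

#' Dominant spectral peak in a band
#'
#' The maximum amplitude over the bins inside `[f1, f2]`, excluding the
#' DC bin; ties are broken towards the lower frequency. With the
#' standard 1 s ON / 1 s OFF protocol the dominant peak of a stimulated
#' run is expected at the 0.5 Hz modulation fundamental.
#'
#' @param spectrum A `spectral_response` from [amplitude_spectrum()].
#' @param band Frequency band `c(f1, f2)` in Hz, default 0-2 Hz.
#' @return List with `amplitude` (mm/s) and `frequency_hz`.
#' @export
dominant_peak <- function(spectrum, band = c(0, 2)) {
  stopifnot(inherits(spectrum, "spectral_response"))
  if (band[1] >= band[2]) stop("band must satisfy f1 < f2", call. = FALSE)
  nyq <- max(spectrum$frequency_hz)
  idx <- which(spectrum$frequency_hz >= band[1] &
                 spectrum$frequency_hz <= min(band[2], nyq) &
                 spectrum$frequency_hz > 0)
  if (length(idx) == 0) stop("band contains no non-DC bins", call. = FALSE)
  best <- idx[which.max(spectrum$amplitude[idx])]
  list(amplitude = spectrum$amplitude[best],
       frequency_hz = spectrum$frequency_hz[best])
}

#' Spectral band integral
#'
#' Sum of spectral amplitudes over the bins with `f1 <= f < f2`
#' (half-open, so touching bands such as 18-23 and 23-28 Hz never
#' double-count the shared edge bin and adjacent integrals add exactly).
#'
#' @param spectrum A `spectral_response`.
#' @param f1,f2 Band edges in Hz, `f1 < f2 <=` Nyquist.
#' @return Band integral `A` in mm/s (sum over bins), >= 0.
#' @export
band_integral <- function(spectrum, f1, f2) {
  stopifnot(inherits(spectrum, "spectral_response"))
  if (f1 >= f2) stop("band must satisfy f1 < f2", call. = FALSE)
  idx <- spectrum$frequency_hz >= f1 & spectrum$frequency_hz < f2
  sum(spectrum$amplitude[idx])
}

#' Replicate aggregation (mean and SEM)
#'
#' @param values Metric values across independent replicates (n >= 2).
#' @return List with `n`, `mean`, and `sem` (sample standard deviation
#'   with denominator n - 1, divided by sqrt(n)).
#' @export
aggregate_replicates <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("SEM undefined for fewer than 2 replicates", call. = FALSE)
  list(n = n, mean = mean(values), sem = sd(values) / sqrt(n))
}

#' Calibration metrics from a flow-sensor trace
#'
#' Quantifies the stimulation response of a measured (or simulated)
#' flow-rate signal: means over the ON and OFF protocol phases, their
#' difference (the modulation amplitude), and the residual offset of the
#' late-OFF plateau relative to a baseline. The residual is the mean of
#' the final 20% of each OFF phase after the first, minus the baseline;
#' the baseline defaults to the final 20% of the first OFF phase (there
#' is no pre-stimulation segment since the schedule opens ON).
#'
#' @param trace Data frame with columns `time_s`, `flow_ml_min`.
#' @param protocol A [stimulus_protocol()].
#' @param baseline Optional baseline flow, mL/min.
#' @return List with `mean_on`, `mean_off`, `modulation_amplitude`,
#'   `residual_offset` (all mL/min).
#' @export
calibration_metrics <- function(trace, protocol, baseline = NULL) {
  stopifnot(inherits(protocol, "stimulus_protocol"),
            all(c("time_s", "flow_ml_min") %in% names(trace)))
  period <- protocol$on_s + protocol$off_s
  t <- trace$time_s
  if (max(t) - min(t) < 3 * period) {
    stop("trace must cover at least 3 full protocol periods", call. = FALSE)
  }
  tt <- pmin(t, protocol$total_s - 1e-12)
  on <- stimulus_state(protocol, tt) == "ON"
  mean_on <- mean(trace$flow_ml_min[on])
  mean_off <- mean(trace$flow_ml_min[!on])
  # late-OFF plateau per cycle: last 20% of each OFF phase
  cycle <- floor(tt / period)
  phase <- tt %% period
  late_off <- !on & phase >= protocol$on_s + 0.8 * protocol$off_s
  cycles <- sort(unique(cycle[late_off]))
  plateau <- vapply(cycles, function(k)
    mean(trace$flow_ml_min[late_off & cycle == k]), numeric(1))
  if (is.null(baseline)) {
    baseline <- plateau[1]
    plateau <- plateau[-1]
  }
  residual <- if (length(plateau) > 0) mean(plateau) - baseline else 0
  list(mean_on = mean_on, mean_off = mean_off,
       modulation_amplitude = mean_on - mean_off,
       residual_offset = residual)
}

#' Full response summary of one recording
#'
#' Computes the complete metric set for a pair of spatially averaged
#' velocity traces: the velocity range per component, the dominant
#' low-frequency spectral peak, and the in-band spectral integrals.
#'
#' @param traces List with `x` and `y` [velocity_trace()] elements, as
#'   returned by [spatial_mean()].
#' @param bands List of `c(f1, f2)` bands in Hz for the band integrals.
#' @param peak_band Band for the dominant-peak search, Hz.
#' @return A one-row-per-component data frame with columns `component`,
#'   `r_mm_s`, `fp_amplitude`, `fp_frequency_hz`, and one `A_f1_f2`
#'   column per band.
#' @export
response_summary <- function(traces,
                             bands = list(c(10, 15), c(18, 23), c(23, 28)),
                             peak_band = c(0, 2)) {
  rows <- lapply(c("x", "y"), function(comp) {
    tr <- traces[[comp]]
    sp <- amplitude_spectrum(tr)
    pk <- dominant_peak(sp, peak_band)
    row <- data.frame(component = comp, r_mm_s = velocity_range(tr),
                      fp_amplitude = pk$amplitude,
                      fp_frequency_hz = pk$frequency_hz)
    for (b in bands) {
      row[[sprintf("A_%g_%g", b[1], b[2])]] <- band_integral(sp, b[1], b[2])
    }
    row
  })
  do.call(rbind, rows)
}
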