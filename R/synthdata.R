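#' Spherical particle mass
#'
#' Mass of a spherical particle, \eqn{m = \frac{4}{3}\pi r^3 \rho}.
#'
#' @param radius Particle radius in meters.
#' @param density Particle density in kg/m^3.
#' @return Mass in kg.
#' @examples
#' particle_mass(3.0e-6, 1200)  # silica bead, ~1.36e-13 kg
#' particle_mass(2.5e-6, 1126)  # yeast cell,  ~7.37e-14 kg
#' @export
particle_mass <- function(radius, density) {
  if (any(radius < 0) || any(density < 0)) {
    stop("radius and density must be non-negative", call. = FALSE)
  }
  (4 / 3) * pi * radius^3 * density
}

#' Particle type for the synthetic generator
#'
#' Bundles the physical properties of a micro-particle population with
#' the phenomenological coupling parameters that control how strongly it
#' responds to the acousto-mechanical stimulus:
#' \describe{
#'   \item{coupling_longitudinal}{bulk flow-parallel velocity boost
#'     (mm/s) added while the stimulus is ON, before scaling.}
#'   \item{coupling_transverse}{dimensionless gain mapping the in-band
#'     carrier to transverse (y) velocity; 0 means no transverse
#'     response.}
#'   \item{coupling_flow_exponent}{exponent of the scaling of the
#'     stimulus response with flow rate,
#'     \eqn{(Q/Q_{ref})^{\alpha}}; 0 means flow-invariant.}
#'   \item{coupling_drive_exponent}{exponent of the scaling with the
#'     tone drive strength (see [drive_strength()]); 0 means
#'     octave-invariant.}
#'   \item{hf_lines}{data frame (`freq_hz`, `amp_mm_s`) of in-band
#'     (10-28 Hz) velocity oscillation lines injected while ON.}
#' }
#'
#' @param name Particle type label.
#' @param radius_m Radius in meters.
#' @param density_kg_m3 Density in kg/m^3.
#' @param coupling_longitudinal Longitudinal ON boost, mm/s.
#' @param coupling_transverse Transverse carrier gain (dimensionless).
#' @param coupling_flow_exponent Flow-rate scaling exponent.
#' @param coupling_drive_exponent Drive-strength scaling exponent.
#' @param hf_lines Data frame with columns `freq_hz`, `amp_mm_s`.
#' @return A `particle_type` object; `mass_kg` is derived.
#' @seealso [silica_bead_particle()], [yeast_particle()]
#' @export
particle_type <- function(name, radius_m, density_kg_m3,
                          coupling_longitudinal = 0,
                          coupling_transverse = 0,
                          coupling_flow_exponent = 0,
                          coupling_drive_exponent = 0,
                          hf_lines = data.frame(freq_hz = numeric(),
                                                amp_mm_s = numeric())) {
  if (radius_m <= 0 || density_kg_m3 <= 0) {
    stop("radius and density must be > 0", call. = FALSE)
  }
  structure(
    list(name = name, radius_m = radius_m, density_kg_m3 = density_kg_m3,
         mass_kg = particle_mass(radius_m, density_kg_m3),
         coupling_longitudinal = coupling_longitudinal,
         coupling_transverse = coupling_transverse,
         coupling_flow_exponent = coupling_flow_exponent,
         coupling_drive_exponent = coupling_drive_exponent,
         hf_lines = hf_lines),
    class = "particle_type"
  )
}

#' Built-in particle presets
#'
#' `silica_bead_particle()` models a rigid, density-matched bead: its
#' stimulus response is stable (invariant to flow rate and tone octave)
#' and purely longitudinal. `yeast_particle()` models a compliant cell:
#' its response grows with flow rate and drive strength and includes a
#' transverse component at the same in-band frequencies as the
#' longitudinal carrier.
#'
#' @return A [particle_type()].
#' @export
silica_bead_particle <- function() {
  particle_type(
    name = "silica_bead", radius_m = 3.0e-6, density_kg_m3 = 1200,
    coupling_longitudinal = 0.12,
    coupling_transverse = 0,
    coupling_flow_exponent = 0,
    coupling_drive_exponent = 0,
    hf_lines = data.frame(freq_hz = c(12, 19, 25),
                          amp_mm_s = c(0.020, 0.014, 0.010))
  )
}

#' @rdname silica_bead_particle
#' @export
yeast_particle <- function() {
  particle_type(
    name = "yeast", radius_m = 2.5e-6, density_kg_m3 = 1126,
    coupling_longitudinal = 0.022,
    coupling_transverse = 0.6,
    coupling_flow_exponent = 0.45,
    coupling_drive_exponent = 1,
    hf_lines = data.frame(freq_hz = c(12, 19, 25),
                          amp_mm_s = c(0.008, 0.005, 0.004))
  )
}

#' Microchannel geometry
#'
#' Straight rectangular channel with the imaging region of interest
#' (ROI) centered on the channel axis. The channel depth is not imaged;
#' a square cross-section (depth = width) is assumed for converting
#' volumetric flow rate to mean transport speed.
#'
#' @param length_mm Channel length, mm.
#' @param width_mm Channel width, mm.
#' @param depth_mm Channel depth, mm.
#' @param roi_offset_mm Distance of the ROI from the inlet, mm.
#' @param roi_px ROI size in pixels, `c(width, height)`.
#' @return A `channel_geometry` object.
#' @export
channel_geometry <- function(length_mm = 45, width_mm = 0.40,
                             depth_mm = 0.40, roi_offset_mm = 22,
                             roi_px = c(180, 140)) {
  if (width_mm <= 0 || depth_mm <= 0) stop("width and depth must be > 0", call. = FALSE)
  structure(
    list(length_mm = length_mm, width_mm = width_mm, depth_mm = depth_mm,
         roi_offset_mm = roi_offset_mm, roi_px = as.integer(roi_px)),
    class = "channel_geometry"
  )
}

#' Camera and image-formation model
#'
#' @param frame_rate Acquisition rate, frames/s.
#' @param sensor_pixel_um Physical sensor pixel size, micrometers.
#' @param magnification Objective magnification (object-plane pixel
#'   pitch = `sensor_pixel_um / magnification`).
#' @param frame_size Full sensor size in pixels, `c(width, height)`.
#' @param exposure_ms Exposure time, ms (metadata only).
#' @param noise_sigma Additive read-noise standard deviation, grey levels.
#' @param particle_spot_sigma Rendered particle spot sigma, pixels.
#' @param background_level Background intensity, grey levels.
#' @param spot_peak Peak spot intensity above background, grey levels.
#' @return A `camera_model` object.
#' @export
camera_model <- function(frame_rate = 57, sensor_pixel_um = 7.4,
                         magnification = 10, frame_size = c(640, 480),
                         exposure_ms = 17.438, noise_sigma = 3,
                         particle_spot_sigma = 1.2, background_level = 20,
                         spot_peak = 160) {
  stopifnot(frame_rate > 0, sensor_pixel_um > 0, magnification > 0)
  structure(
    list(frame_rate = frame_rate, sensor_pixel_um = sensor_pixel_um,
         magnification = magnification, frame_size = as.integer(frame_size),
         exposure_ms = exposure_ms, noise_sigma = noise_sigma,
         particle_spot_sigma = particle_spot_sigma,
         background_level = background_level, spot_peak = spot_peak),
    class = "camera_model"
  )
}

#' Object-plane pixel pitch
#'
#' @param camera A [camera_model()].
#' @return Pixel pitch in micrometers per pixel.
#' @export
pixel_pitch_um <- function(camera) {
  camera$sensor_pixel_um / camera$magnification
}

#' Mean transport velocity from volumetric flow rate
#'
#' Converts a syringe-pump flow rate to the cross-section-averaged
#' velocity, `Q / (width * depth)` with 1 mL/min = 1000/60 mm^3/s.
#'
#' @param flow_rate Flow rate in mL/min.
#' @param geometry A [channel_geometry()].
#' @return Mean velocity in mm/s.
#' @examples
#' mean_channel_velocity(0.001, channel_geometry())  # ~0.1042 mm/s
#' @export
mean_channel_velocity <- function(flow_rate, geometry = channel_geometry()) {
  area <- geometry$width_mm * geometry$depth_mm
  if (area <= 0) stop("channel cross-section area must be > 0", call. = FALSE)
  flow_rate * (1000 / 60) / area
}

#' Drive strength of a stimulation tone
#'
#' Phenomenological map from carrier tone frequency to the mechanical
#' drive delivered to the channel, `(f / f_ref)^exponent` with the low
#' G#0 tone as reference. The default exponent 0.21 makes the G#4 tone
#' about 1.8x stronger than G#0, emulating the stronger actuator-tubing
#' coupling observed at the higher excitation frequency.
#'
#' @param tone_hz Carrier tone frequency, Hz.
#' @param exponent Scaling exponent.
#' @param reference_hz Reference tone frequency, Hz.
#' @return Dimensionless drive strength (1 at the reference tone).
#' @export
drive_strength <- function(tone_hz, exponent = 0.21, reference_hz = AMP_LOW) {
  (tone_hz / reference_hz)^exponent
}

#' Experiment condition
#'
#' One cell of the experimental campaign: a particle type at a flow
#' rate, stimulated (or not) by a protocol, with a replicate seed.
#'
#' @param particle A [particle_type()].
#' @param flow_rate Flow rate in mL/min (> 0).
#' @param protocol A [stimulus_protocol()] or `NULL` for the
#'   unstimulated control.
#' @param seed Integer replicate seed.
#' @return An `experiment_condition` object.
#' @export
experiment_condition <- function(particle, flow_rate, protocol = NULL,
                                 seed = 1L) {
  stopifnot(inherits(particle, "particle_type"), flow_rate > 0)
  if (!is.null(protocol)) stopifnot(inherits(protocol, "stimulus_protocol"))
  structure(
    list(particle = particle, flow_rate = flow_rate, protocol = protocol,
         seed = as.integer(seed)),
    class = "experiment_condition"
  )
}

# Blunt parabolic (Poiseuille-like) profile across the channel width,
# normalized to 1 at the centerline. y_um is measured within the ROI,
# whose vertical center coincides with the channel axis.
velocity_profile <- function(y_um, roi_h_um, width_mm) {
  dy_mm <- (y_um - roi_h_um / 2) / 1000
  1 - (2 * dy_mm / width_mm)^2
}

# Stimulus envelope: linear ramp towards 1 over rise_s after an ON
# onset, exponential decay with time constant decay_tau_s during OFF.
# Evaluated iteratively on the frame clock so the ramp resumes from the
# current level when phases alternate faster than the transients.
stimulus_envelope <- function(protocol, times, rise_s = 0.3, decay_tau_s = 0.3) {
  if (is.null(protocol)) return(numeric(length(times)))
  state_on <- stimulus_state(protocol, times) == "ON"
  env <- numeric(length(times))
  e <- 0
  dt <- if (length(times) > 1) times[2] - times[1] else 0
  for (i in seq_along(times)) {
    if (state_on[i]) {
      e <- min(1, e + if (rise_s > 0) dt / rise_s else 1)
    } else {
      e <- e * exp(-dt / decay_tau_s)
    }
    env[i] <- e
  }
  env
}

#' Simulate particle trajectories
#'
#' Advances `n_particles` seeded uniformly over the ROI through a steady
#' Poiseuille-like transport field plus, while the stimulus is ON, a
#' bulk longitudinal velocity boost and a sum of in-band carrier
#' oscillations. The stimulus terms are gated by the protocol schedule,
#' shaped by a rise/decay envelope, and scaled by
#' \eqn{(Q/Q_{ref})^{\alpha} d^{\beta}} where \eqn{d} is the tone drive
#' strength and \eqn{\alpha,\beta} are particle coupling exponents.
#' Particles leaving the ROI re-enter at the opposite edge so seeding
#' density stays constant.
#'
#' @param condition An [experiment_condition()].
#' @param geometry A [channel_geometry()].
#' @param camera A [camera_model()].
#' @param n_particles Number of particles in the ROI (>= 1).
#' @param duration_s Recording duration; defaults to the protocol's
#'   total duration, or 60 s for unstimulated runs.
#' @param diffusion_px Per-frame isotropic positional jitter sigma, px.
#' @param rise_s Stimulus envelope rise time, s.
#' @param decay_tau_s Stimulus envelope OFF decay constant, s.
#' @param reference_flow Reference flow rate for coupling scaling, mL/min.
#' @param seed RNG seed; defaults to the condition's replicate seed.
#' @return A `particle_trajectories` object: positions `x_um`, `y_um`
#'   (`n_particles` x `n_frames`, object-plane micrometers), frame
#'   `times_s`, and ground-truth spatially averaged velocities
#'   `vx_true`, `vy_true` (mm/s, one value per frame pair).
#' @export
simulate_trajectories <- function(condition, geometry = channel_geometry(),
                                  camera = camera_model(), n_particles = 80,
                                  duration_s = NULL, diffusion_px = 0.05,
                                  rise_s = 0.3, decay_tau_s = 0.3,
                                  reference_flow = 1e-4,
                                  seed = condition$seed) {
  stopifnot(inherits(condition, "experiment_condition"))
  if (n_particles < 1) stop("n_particles must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  protocol <- condition$protocol
  if (is.null(duration_s)) {
    duration_s <- if (!is.null(protocol)) protocol$total_s else 60
  }
  fps <- camera$frame_rate
  dt <- 1 / fps
  n_frames <- round(duration_s * fps)
  pitch <- pixel_pitch_um(camera)
  roi_w_um <- geometry$roi_px[1] * pitch
  roi_h_um <- geometry$roi_px[2] * pitch
  times <- (seq_len(n_frames) - 1) * dt

  p <- condition$particle
  v_base <- mean_channel_velocity(condition$flow_rate, geometry)
  if (is.null(protocol)) {
    scale <- 0
    env <- numeric(n_frames)
    carrier <- numeric(n_frames)
  } else {
    drive <- drive_strength(protocol$tone_hz)
    scale <- (condition$flow_rate / reference_flow)^p$coupling_flow_exponent *
      drive^p$coupling_drive_exponent
    env <- stimulus_envelope(protocol, times, rise_s, decay_tau_s)
    carrier <- numeric(n_frames)
    for (k in seq_len(nrow(p$hf_lines))) {
      carrier <- carrier +
        p$hf_lines$amp_mm_s[k] * sin(2 * pi * p$hf_lines$freq_hz[k] * times)
    }
  }

  x <- matrix(0, n_particles, n_frames)
  y <- matrix(0, n_particles, n_frames)
  x[, 1] <- runif(n_particles, 0, roi_w_um)
  y[, 1] <- runif(n_particles, 0, roi_h_um)
  vx_true <- numeric(max(n_frames - 1, 0))
  vy_true <- numeric(max(n_frames - 1, 0))
  jit_um <- diffusion_px * pitch

  for (i in seq_len(n_frames - 1)) {
    prof <- velocity_profile(y[, i], roi_h_um, geometry$width_mm)
    vx <- v_base * prof + scale * env[i] * (p$coupling_longitudinal + carrier[i])
    vy <- rep(scale * env[i] * p$coupling_transverse * carrier[i], n_particles)
    jx <- if (jit_um > 0) rnorm(n_particles, 0, jit_um) else numeric(n_particles)
    jy <- if (jit_um > 0) rnorm(n_particles, 0, jit_um) else numeric(n_particles)
    x[, i + 1] <- (x[, i] + vx * 1000 * dt + jx) %% roi_w_um
    y[, i + 1] <- (y[, i] + vy * 1000 * dt + jy) %% roi_h_um
    vx_true[i] <- mean(vx) + mean(jx) / (1000 * dt)
    vy_true[i] <- mean(vy) + mean(jy) / (1000 * dt)
  }

  structure(
    list(x_um = x, y_um = y, times_s = times, vx_true = vx_true,
         vy_true = vy_true, condition = condition, geometry = geometry,
         camera = camera, n_particles = n_particles, seed = seed),
    class = "particle_trajectories"
  )
}

#' Render trajectories into a synthetic frame stack
#'
#' Each particle becomes an isotropic Gaussian spot on a uniform
#' background; additive Gaussian read noise is applied and the result is
#' quantized to 8 bit. Acquisition metadata travels with the stack.
#'
#' @param trajectories A [simulate_trajectories()] result.
#' @param camera A [camera_model()]; defaults to the one used for the
#'   trajectories.
#' @param seed RNG seed for the read noise.
#' @return A `frame_stack`: integer array `frames` of dimension
#'   (height, width, n_frames) with values 0-255, plus `frame_rate`,
#'   `pixel_pitch_um` and the originating condition.
#' @export
render_frames <- function(trajectories, camera = trajectories$camera,
                          seed = NULL) {
  stopifnot(inherits(trajectories, "particle_trajectories"))
  if (nrow(trajectories$x_um) == 0 || ncol(trajectories$x_um) == 0) {
    stop("empty trajectory set", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  pitch <- pixel_pitch_um(camera)
  roi <- trajectories$geometry$roi_px
  frames <- cpp_render_frames(
    trajectories$x_um / pitch, trajectories$y_um / pitch,
    roi[2], roi[1], camera$particle_spot_sigma, camera$spot_peak,
    camera$background_level, camera$noise_sigma
  )
  structure(
    list(frames = frames, frame_rate = camera$frame_rate,
         pixel_pitch_um = pitch, n_frames = dim(frames)[3],
         roi_px = roi, condition = trajectories$condition,
         camera = camera, seed = seed),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("Frame stack: %d frames of %dx%d px at %g FPS (%.3g um/px)\n",
              x$n_frames, x$roi_px[1], x$roi_px[2], x$frame_rate,
              x$pixel_pitch_um))
  invisible(x)
}

#' Simulate a flow-sensor calibration trace
#'
#' Emulates the outlet flow-rate signal of a hydrodynamically driven
#' channel under ON-OFF stimulation: a first-order response `g(t)` that
#' rises towards 1 during ON phases and relaxes with time constant
#' `relaxation_tau` during OFF phases, plus an optional slowly
#' accumulating persistent offset `h(t)` emulating incomplete relaxation
#' under strong (high-octave) drive.
#'
#' @param protocol A [stimulus_protocol()].
#' @param baseline Steady pump flow rate, mL/min (> 0).
#' @param on_amplitude Flow increase at full stimulus response, mL/min.
#' @param relaxation_tau First-order time constant, s (> 0).
#' @param residual_offset Asymptotic persistent offset, mL/min.
#' @param noise_sigma Additive sensor noise sigma, mL/min.
#' @param sample_rate Sensor sampling rate, Hz (> 2x the modulation
#'   fundamental).
#' @param seed RNG seed for the noise.
#' @return Data frame with columns `time_s`, `flow_ml_min`.
#' @export
simulate_flow_sensor <- function(protocol, baseline = 0.001,
                                 on_amplitude = 2e-4, relaxation_tau = 0.15,
                                 residual_offset = 0, noise_sigma = 0,
                                 sample_rate = 50, seed = NULL) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (baseline <= 0) stop("baseline must be > 0", call. = FALSE)
  if (relaxation_tau <= 0) stop("relaxation_tau must be > 0", call. = FALSE)
  if (sample_rate <= 2 * modulation_fundamental(protocol)) {
    stop("sample_rate must exceed twice the modulation fundamental", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / sample_rate
  times <- seq(0, protocol$total_s - dt, by = dt)
  u <- as.numeric(stimulus_state(protocol, times) == "ON")
  g <- numeric(length(times))
  gi <- 0
  decay <- exp(-dt / relaxation_tau)
  for (i in seq_along(times)) {
    gi <- u[i] + (gi - u[i]) * decay
    g[i] <- gi
  }
  period <- protocol$on_s + protocol$off_s
  h <- 1 - exp(-times / (3 * period))
  flow <- baseline + on_amplitude * g + residual_offset * h
  if (noise_sigma > 0) flow <- flow + rnorm(length(flow), 0, noise_sigma)
  data.frame(time_s = times, flow_ml_min = flow)
}
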