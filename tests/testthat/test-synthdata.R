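test_that("spherical particle masses match the tabulated properties", {
  expect_equal(signif(particle_mass(3.0e-6, 1200), 3), 1.36e-13)
  expect_equal(signif(particle_mass(2.5e-6, 1126), 3), 7.37e-14)
  expect_equal(particle_mass(0, 1000), 0)
  expect_error(particle_mass(-1e-6, 1000), "non-negative")
  # presets carry the derived mass
  expect_equal(signif(silica_bead_particle()$mass_kg, 3), 1.36e-13)
  expect_equal(signif(yeast_particle()$mass_kg, 3), 7.37e-14)
})

test_that("flow rate converts linearly to mean channel velocity", {
  geom <- channel_geometry()  # 0.40 x 0.40 mm cross-section
  expect_equal(mean_channel_velocity(0.001, geom), (1000 / 60) * 0.001 / 0.16)
  expect_equal(round(mean_channel_velocity(0.001, geom), 4), 0.1042)
  expect_equal(round(mean_channel_velocity(0.0001, geom), 5), 0.01042)
  expect_equal(mean_channel_velocity(0.002, geom),
               2 * mean_channel_velocity(0.001, geom))
})

test_that("unforced particles with no flow and no diffusion stay put", {
  cond <- experiment_condition(silica_bead_particle(), 1e-12, NULL, seed = 3)
  traj <- simulate_trajectories(cond, n_particles = 10, duration_s = 1,
                                diffusion_px = 0)
  drift_um <- max(abs(traj$x_um - traj$x_um[, 1]))
  expect_lt(drift_um, 1e-6)
  expect_equal(max(abs(traj$y_um - traj$y_um[, 1])), 0)
})

test_that("steady unstimulated advection is exact per frame", {
  geom <- channel_geometry()
  cam <- camera_model(noise_sigma = 0)
  cond <- experiment_condition(yeast_particle(), 1e-3, NULL, seed = 7)
  traj <- simulate_trajectories(cond, geom, cam, n_particles = 20,
                                duration_s = 0.5, diffusion_px = 0)
  v_base <- mean_channel_velocity(1e-3, geom)
  pitch <- pixel_pitch_um(cam)
  roi_h_um <- geom$roi_px[2] * pitch
  prof <- acoustopiv:::velocity_profile(traj$y_um[, 1], roi_h_um, geom$width_mm)
  roi_w_um <- geom$roi_px[1] * pitch
  step_um <- (traj$x_um[, 2] - traj$x_um[, 1]) %% roi_w_um  # undo edge wrap
  expect_equal(step_um, v_base * prof * 1000 / cam$frame_rate,
               tolerance = 1e-12)
  # ground-truth spatial mean matches the analytic profile average
  expect_equal(traj$vx_true[1], v_base * mean(prof), tolerance = 1e-9)
})

test_that("stimulated ground-truth velocity has the 0.5 Hz square-wave structure", {
  cond <- experiment_condition(silica_bead_particle(), 1e-4,
                               protocol_preset("amp-low", 20), seed = 11)
  traj <- simulate_trajectories(cond, n_particles = 30, duration_s = 20,
                                diffusion_px = 0)
  tr <- velocity_trace(traj$vx_true, traj$camera$frame_rate, "x")
  pk <- dominant_peak(amplitude_spectrum(tr), c(0, 2))
  expect_equal(pk$frequency_hz,
               modulation_fundamental(cond$protocol),
               tolerance = amplitude_spectrum(tr)$resolution_hz)
})

test_that("particles wrap at the ROI edges and stay inside", {
  geom <- channel_geometry()
  cam <- camera_model()
  cond <- experiment_condition(yeast_particle(), 5e-3,
                               protocol_preset("amp-high", 5), seed = 5)
  traj <- simulate_trajectories(cond, geom, cam, n_particles = 40,
                                duration_s = 5)
  roi_w_um <- geom$roi_px[1] * pixel_pitch_um(cam)
  roi_h_um <- geom$roi_px[2] * pixel_pitch_um(cam)
  expect_true(all(is.finite(traj$x_um)) && all(is.finite(traj$y_um)))
  expect_true(all(traj$x_um >= 0 & traj$x_um < roi_w_um))
  expect_true(all(traj$y_um >= 0 & traj$y_um < roi_h_um))
  expect_equal(dim(traj$x_um), c(40, 5 * 57))
})

test_that("trajectories are deterministic under a fixed seed", {
  cond <- experiment_condition(yeast_particle(), 1e-3,
                               protocol_preset("amp-low", 2), seed = 99)
  t1 <- simulate_trajectories(cond, n_particles = 15, duration_s = 2)
  t2 <- simulate_trajectories(cond, n_particles = 15, duration_s = 2)
  expect_identical(t1$x_um, t2$x_um)
  expect_identical(t1$vx_true, t2$vx_true)
})

test_that("ground-truth range is drive-invariant for beads, graded for yeast", {
  flows_bead <- c(1e-4, 1e-3)
  flows_yeast <- c(1e-4, 1e-3, 5e-3)
  modes <- c("amp-low", "amp-high")
  gt_range <- function(particle, flow, mode) {
    cond <- experiment_condition(particle, flow,
                                 protocol_preset(mode, 20), seed = 1)
    traj <- simulate_trajectories(cond, n_particles = 30, duration_s = 20,
                                  diffusion_px = 0)
    velocity_range(traj$vx_true)
  }
  r_bead <- outer(flows_bead, modes,
                  Vectorize(function(f, m) gt_range(silica_bead_particle(), f, m)))
  expect_lt(max(r_bead) / min(r_bead) - 1, 0.10)

  r_yeast <- outer(flows_yeast, modes,
                   Vectorize(function(f, m) gt_range(yeast_particle(), f, m)))
  # strictly increasing with flow rate at fixed octave
  expect_true(all(diff(r_yeast[, 1]) > 0))
  expect_true(all(diff(r_yeast[, 2]) > 0))
  # strictly increasing with octave at fixed flow rate
  expect_true(all(r_yeast[, 2] > r_yeast[, 1]))
})

test_that("rendering is deterministic and reduces to the background", {
  cond <- experiment_condition(silica_bead_particle(), 1e-4, NULL, seed = 2)
  cam0 <- camera_model(noise_sigma = 0, spot_peak = 0, background_level = 20)
  traj <- simulate_trajectories(cond, camera = cam0, n_particles = 1,
                                duration_s = 0.1)
  blank <- render_frames(traj, cam0)
  expect_true(all(blank$frames == 20L))

  cam <- camera_model()
  traj2 <- simulate_trajectories(cond, camera = cam, n_particles = 10,
                                 duration_s = 0.1)
  s1 <- render_frames(traj2, cam, seed = 123)
  s2 <- render_frames(traj2, cam, seed = 123)
  expect_identical(s1$frames, s2$frames)
})

test_that("a noiseless rendered spot recovers its centroid to 0.05 px", {
  geom <- channel_geometry()
  cam <- camera_model(noise_sigma = 0)
  pitch <- pixel_pitch_um(cam)
  cond <- experiment_condition(silica_bead_particle(), 1e-9, NULL, seed = 4)
  traj <- simulate_trajectories(cond, geom, cam, n_particles = 1,
                                duration_s = 0.1, diffusion_px = 0)
  # pin the particle mid-ROI at a fractional position
  traj$x_um[] <- 90.3 * pitch
  traj$y_um[] <- 70.7 * pitch
  stack <- render_frames(traj, cam)
  img <- stack$frames[, , 1] - cam$background_level
  w <- sum(img)
  cx <- sum(t(img) * (seq_len(ncol(img)) - 1)) / w
  cy <- sum(img * (seq_len(nrow(img)) - 1)) / w
  expect_lt(abs(cx - 90.3), 0.05)
  expect_lt(abs(cy - 70.7), 0.05)
})

test_that("flow sensor trace reproduces the relaxation regimes", {
  p <- stimulus_protocol(1, 1, 20)
  # no stimulation response: constant baseline
  flat <- simulate_flow_sensor(p, baseline = 0.001, on_amplitude = 0,
                               relaxation_tau = 0.1)
  expect_equal(unique(flat$flow_ml_min), 0.001)

  # fast relaxation: the trace returns to baseline within 5 tau of OFF onset
  tau <- 0.1
  fast <- simulate_flow_sensor(p, baseline = 0.001, on_amplitude = 2e-4,
                               relaxation_tau = tau, sample_rate = 100)
  late_off <- fast$time_s %% 2 >= 1 + 5 * tau
  expect_lt(max(fast$flow_ml_min[late_off] - 0.001), 2e-4 * exp(-5) * 1.1)

  # slow relaxation: late-OFF minima stay above baseline
  slow <- simulate_flow_sensor(p, baseline = 0.001, on_amplitude = 2e-4,
                               relaxation_tau = 1.5, sample_rate = 100)
  late <- slow$time_s > 10 & stimulus_state(p, pmin(slow$time_s, 20 - 1e-9)) == "OFF"
  expect_gt(min(slow$flow_ml_min[late]), 0.001 + 1e-5)

  expect_error(simulate_flow_sensor(p, relaxation_tau = 0), "relaxation_tau")
})
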