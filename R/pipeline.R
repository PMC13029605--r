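#' Preset experimental campaign plan
#'
#' The standard condition matrix: silica beads at two flow rates and
#' yeast cells at three, each combination run as an unstimulated
#' control plus the two stimulated modes (G#0 and G#4 tone, 1 s ON /
#' 1 s OFF). The 10 stimulated rows mirror the experimental campaign;
#' the 5 controls provide the per-combination baseline.
#'
#' @param n_replicates Independent replicates per condition.
#' @param base_seed Base RNG seed; per-run seeds are derived
#'   deterministically from it.
#' @return A data frame (`particle`, `flow_rate`, `mode`) with
#'   attributes `n_replicates` and `base_seed`, class `experiment_plan`.
#' @export
campaign_plan <- function(n_replicates = 3, base_seed = 1L) {
  combos <- rbind(
    expand.grid(particle = "silica_bead", flow_rate = c(1e-4, 1e-3),
                mode = c("no-amp", "amp-low", "amp-high"),
                stringsAsFactors = FALSE),
    expand.grid(particle = "yeast", flow_rate = c(1e-4, 1e-3, 5e-3),
                mode = c("no-amp", "amp-low", "amp-high"),
                stringsAsFactors = FALSE)
  )
  combos <- combos[order(combos$particle, combos$flow_rate, combos$mode), ]
  rownames(combos) <- NULL
  structure(combos, n_replicates = as.integer(n_replicates),
            base_seed = as.integer(base_seed),
            class = c("experiment_plan", "data.frame"))
}

resolve_particle <- function(particle) {
  if (inherits(particle, "particle_type")) return(particle)
  switch(particle,
    "silica_bead" = silica_bead_particle(),
    "yeast" = yeast_particle(),
    stop("unknown particle preset: ", particle, call. = FALSE)
  )
}

#' Run one experimental condition end to end
#'
#' Generates a synthetic recording for the condition (trajectories then
#' rendered frames), extracts the velocity fields with multi-pass PIV
#' over consecutive frame pairs, spatially averages them, and computes
#' the full response metric set.
#'
#' @param particle A [particle_type()] or preset name
#'   (`"silica_bead"`, `"yeast"`).
#' @param flow_rate Flow rate, mL/min.
#' @param mode `"no-amp"`, `"amp-low"` or `"amp-high"`.
#' @param duration_s Recording duration, s.
#' @param seed Replicate seed.
#' @param n_particles Particles in the ROI.
#' @param config A [piv_config()].
#' @param camera A [camera_model()].
#' @param geometry A [channel_geometry()].
#' @param bands Band-integral presets, Hz.
#' @param keep_traces Also return the averaged velocity traces and
#'   spectra.
#' @return A list with `summary` (per-component metric data frame with
#'   condition columns prepended) and, when `keep_traces`, `traces` and
#'   `spectra`.
#' @export
run_condition <- function(particle, flow_rate, mode = "amp-low",
                          duration_s = 60, seed = 1L, n_particles = 80,
                          config = piv_config(), camera = camera_model(),
                          geometry = channel_geometry(),
                          bands = list(c(10, 15), c(18, 23), c(23, 28)),
                          keep_traces = FALSE) {
  particle <- resolve_particle(particle)
  protocol <- protocol_preset(mode, total_s = duration_s)
  cond <- experiment_condition(particle, flow_rate, protocol, seed)
  traj <- simulate_trajectories(cond, geometry, camera, n_particles,
                                duration_s = duration_s)
  stack <- render_frames(traj, camera, seed = seed + 500000L)
  dstack <- piv_stack(stack, config)
  vstack <- to_velocity(dstack, camera = camera)
  traces <- spatial_mean(vstack)
  summary <- response_summary(traces, bands = bands)
  summary <- cbind(
    data.frame(particle = particle$name, flow_rate = flow_rate,
               mode = mode, seed = seed, duration_s = duration_s),
    summary
  )
  out <- list(summary = summary)
  if (keep_traces) {
    out$traces <- traces
    out$spectra <- list(x = amplitude_spectrum(traces$x),
                        y = amplitude_spectrum(traces$y))
  }
  out
}

#' Execute an experiment plan
#'
#' Runs every condition of the plan for every replicate (each with its
#' own derived seed) through the full synthetic-video, PIV and metrics
#' chain, and aggregates replicate metrics to mean and SEM. Failures in
#' one condition are recorded in the manifest and do not stop the
#' remaining runs. Re-running with an identical plan and seed
#' reproduces the results table exactly.
#'
#' @param plan An [campaign_plan()] (or compatible data frame with
#'   `particle`, `flow_rate`, `mode` columns).
#' @param duration_s Recording duration per run, s. The default 20 s
#'   keeps a full multi-replicate campaign at desk scale; single
#'   conditions of interest can be re-run at 60 s.
#' @param n_particles Particles in the ROI.
#' @param config,camera,geometry,bands Passed to [run_condition()].
#' @return List with `results` (one row per condition x replicate x
#'   component), `aggregate` (mean and SEM per condition x component x
#'   metric), and `manifest` (seeds, configuration checksum, package
#'   version, failures).
#' @export
run_plan <- function(plan = campaign_plan(), duration_s = 20,
                     n_particles = 80, config = piv_config(),
                     camera = camera_model(), geometry = channel_geometry(),
                     bands = list(c(10, 15), c(18, 23), c(23, 28))) {
  if (nrow(plan) == 0) stop("empty plan", call. = FALSE)
  n_rep <- attr(plan, "n_replicates")
  if (is.null(n_rep)) n_rep <- 3L
  base_seed <- attr(plan, "base_seed")
  if (is.null(base_seed)) base_seed <- 1L
  results <- list()
  failures <- list()
  seeds_used <- integer(0)
  for (i in seq_len(nrow(plan))) {
    for (rep_k in seq_len(n_rep)) {
      seed <- base_seed + 1000L * i + rep_k
      seeds_used <- c(seeds_used, seed)
      res <- tryCatch(
        run_condition(plan$particle[i], plan$flow_rate[i], plan$mode[i],
                      duration_s = duration_s, seed = seed,
                      n_particles = n_particles, config = config,
                      camera = camera, geometry = geometry, bands = bands),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <- list(
          particle = plan$particle[i], flow_rate = plan$flow_rate[i],
          mode = plan$mode[i], replicate = rep_k,
          message = conditionMessage(res))
        next
      }
      row <- res$summary
      row$replicate <- rep_k
      results[[length(results) + 1]] <- row
    }
  }
  results <- if (length(results) > 0) do.call(rbind, results) else NULL
  cfg_file <- tempfile()
  saveRDS(list(config = config, camera = camera, geometry = geometry,
               bands = bands, duration_s = duration_s,
               n_particles = n_particles), cfg_file)
  manifest <- list(
    base_seed = base_seed, seeds = seeds_used, n_replicates = n_rep,
    duration_s = duration_s, n_particles = n_particles,
    config_md5 = unname(tools::md5sum(cfg_file)),
    package_version = as.character(utils::packageVersion("acoustopiv")),
    failures = failures
  )
  unlink(cfg_file)
  list(results = results, aggregate = aggregate_results(results),
       manifest = manifest)
}

# Mean and SEM per condition x component for every metric column.
aggregate_results <- function(results) {
  if (is.null(results) || nrow(results) == 0) return(NULL)
  metric_cols <- setdiff(names(results),
                         c("particle", "flow_rate", "mode", "seed",
                           "duration_s", "component", "replicate"))
  key <- interaction(results$particle, results$flow_rate, results$mode,
                     results$component, drop = TRUE)
  out <- list()
  for (g in levels(key)) {
    sub <- results[key == g, , drop = FALSE]
    row <- sub[1, c("particle", "flow_rate", "mode", "component")]
    row$n <- nrow(sub)
    for (m in metric_cols) {
      vals <- sub[[m]]
      row[[paste0(m, "_mean")]] <- mean(vals)
      row[[paste0(m, "_sem")]] <- if (nrow(sub) >= 2) {
        sd(vals) / sqrt(nrow(sub))
      } else NA_real_
    }
    out[[g]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$particle, res$flow_rate, res$mode, res$component), ]
}

#' Human-readable campaign report
#'
#' Prints the aggregated mean +/- SEM of the velocity range and dominant
#' peak per condition, grouped by particle type and flow rate, and
#' returns the aggregate table invisibly. Conditions with a single
#' replicate are reported mean-only with a warning.
#'
#' @param run Output of [run_plan()], or its `results` data frame.
#' @param component Which velocity component to print.
#' @return The aggregate data frame, invisibly.
#' @export
report <- function(run, component = "x") {
  results <- if (is.list(run) && !is.data.frame(run)) run$results else run
  if (is.null(results) || nrow(results) == 0) stop("no results to report", call. = FALSE)
  agg <- aggregate_results(results)
  agg <- agg[agg$component == component, , drop = FALSE]
  if (any(agg$n < 2)) {
    warning("some conditions have a single replicate; SEM undefined")
  }
  cat(sprintf("Campaign report (%s component, %d condition groups)\n",
              component, nrow(agg)))
  for (i in seq_len(nrow(agg))) {
    cat(sprintf(
      "  %-11s Q=%-7.4g %-8s  r = %.4f +/- %.4f mm/s   fp = %.4f +/- %.4f mm/s @ %.2f Hz\n",
      agg$particle[i], agg$flow_rate[i], agg$mode[i],
      agg$r_mm_s_mean[i], ifelse(is.na(agg$r_mm_s_sem[i]), 0, agg$r_mm_s_sem[i]),
      agg$fp_amplitude_mean[i],
      ifelse(is.na(agg$fp_amplitude_sem[i]), 0, agg$fp_amplitude_sem[i]),
      agg$fp_frequency_hz_mean[i]))
  }
  invisible(agg)
}
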