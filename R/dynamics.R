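# Overdamped Langevin (Brownian) integration with fixed-volume or
# constant-lateral-pressure (z fixed) ensemble control.

#' Integration run configuration
#'
#' @param n_steps Number of BD steps.
#' @param dt Time step in tau_d units. The default keeps the RMS free-blob
#'   displacement well below the smallest WCA diameter; on FENE overstretch
#'   a step is retried with dt/2 (up to 5 halvings).
#' @param ensemble `"NVT"` (fixed box) or `"NPxyT"` (Berendsen-style
#'   rescaling of Lx = Ly toward `lateral_pressure`; Lz always fixed, to
#'   avoid coupling chromatin tension to box fluctuations).
#' @param lateral_pressure Target lateral pressure (kT/nm^3), NPxyT only.
#' @param output_every Frame output cadence (steps).
#' @param seed Integer seed for the thermal noise.
#' @param temperature Thermal energy (kT; 0 disables noise).
#' @param stop Optional early-stop rule, `list(ref_idx, r_clust, size,
#'   check_every, post_steps)`: halt `post_steps` after the largest
#'   single-linkage cluster of the reference particles reaches `size`.
#' @param max_disp Per-step displacement cap (nm): a trial step moving any
#'   particle farther is rejected and retried with a halved time step, the
#'   same guard used for FENE overstretch. `NULL` chooses
#'   `max(0.5, 6 * RMS free step)`, far outside the thermal range, so the
#'   cap only intercepts numerical force spikes.
#' @export
run_config <- function(n_steps, dt = 1e-5, ensemble = c("NVT", "NPxyT"),
                       lateral_pressure = NULL, output_every = 500L,
                       seed = 1L, temperature = 1, stop = NULL,
                       max_disp = NULL) {
  ensemble <- match.arg(ensemble)
  stopifnot(dt > 0, n_steps >= 1, output_every >= 1)
  if (ensemble == "NPxyT" && is.null(lateral_pressure))
    stop("NPxyT requires a target lateral_pressure")
  structure(list(n_steps = as.integer(n_steps), dt = dt, ensemble = ensemble,
                 lateral_pressure = lateral_pressure,
                 output_every = as.integer(output_every),
                 seed = as.integer(seed), temperature = temperature,
                 stop = stop, max_disp = max_disp), class = "run_config")
}

#' Run Brownian dynamics
#'
#' Advances the system with per-particle overdamped Langevin updates
#' `dx = (F/gamma) dt + sqrt(2 kT dt / gamma) xi`, deterministic under the
#' configured seed, and returns the trajectory with periodic frames, box
#' dimensions, an energy report per frame and the measured lateral
#' pressure.
#'
#' @param state Initial `sim_state`.
#' @param topology A `topology`.
#' @param params Model parameters.
#' @param config A `run_config`.
#' @return A `trajectory`.
#' @export
run <- function(state, topology, params, config) {
  tab <- pair_tables(params)
  bc <- bond_constants(params, topology$bonds$class)
  gam <- particle_frictions(topology, params)
  max_disp <- config$max_disp
  if (is.null(max_disp))
    max_disp <- max(0.5, 6 * sqrt(6 * config$temperature * config$dt / min(gam)))
  stop_cfg <- config$stop
  if (is.null(stop_cfg))
    stop_cfg <- list(ref_idx = integer(0), r_clust = 0, size = 0L,
                     check_every = 1000L, post_steps = 0L)
  res <- cpp_run_bd(
    state$positions, topology$species - 1L, tab,
    topology$bonds$i - 1L, topology$bonds$j - 1L, bc$K, bc$R0^2,
    gam, box_lengths(state$box), config$dt, config$n_steps,
    config$output_every,
    as.double(config$seed), as.double(cpp_split_seed(config$seed, 7919L)),
    as.integer(config$ensemble == "NPxyT"),
    if (is.null(config$lateral_pressure)) 0 else config$lateral_pressure,
    100 * config$dt,
    as.integer(stop_cfg$ref_idx - 1L), stop_cfg$r_clust,
    as.integer(stop_cfg$size), as.integer(stop_cfg$check_every),
    as.integer(stop_cfg$post_steps), config$temperature, max_disp)
  nfr <- length(res$frames)
  final_box <- box_spec(res$Lx[nfr], res$Ly[nfr], res$Lz)
  structure(list(
    frames = res$frames,
    times = state$time + res$times,
    box = data.frame(Lx = res$Lx, Ly = res$Ly, Lz = res$Lz),
    energy = data.frame(WCA = res$energy_wca, FK = res$energy_fk,
                        FENE = res$energy_fene),
    lateral_pressure = res$lateral_pressure,
    min_sep_ratio = res$min_sep_ratio,
    n_emergency = res$n_emergency,
    stopped_at_step = res$stopped_at_step,
    config = config,
    final_state = structure(list(positions = res$final, box = final_box,
                                 time = state$time + res$times[nfr]),
                            class = "sim_state")
  ), class = "trajectory")
}

#' Advance a state by a single BD step
#'
#' @inheritParams run
#' @param dt Time step (tau_d).
#' @param seed Noise seed.
#' @export
step <- function(state, topology, params, dt = 1e-5, seed = 1L,
                 temperature = 1) {
  cfg <- run_config(n_steps = 1L, dt = dt, output_every = 1L, seed = seed,
                    temperature = temperature)
  run(state, topology, params, cfg)$final_state
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames, t = %.4g .. %.4g tau_d (%s)\n",
              length(x$frames), x$times[1], x$times[length(x$times)],
              x$config$ensemble))
  if (x$stopped_at_step > 0)
    cat(sprintf("  early stop at step %d\n", x$stopped_at_step))
  invisible(x)
}

#' Corelet self-diffusion time (the simulation time unit)
#'
#' `tau_d = d_core^2 / (6 D_core)` with `D_core = kT / gamma_core` for a
#' bare (valence-0) Corelet core. With the shipped friction convention this
#' equals 1 by construction.
#'
#' @param params Model parameters.
#' @export
estimate_tau_d <- function(params = default_parameters()) {
  core <- species_row(params, "CORE")
  d <- core$sigma
  D <- params$kT / core$gamma
  d^2 / (6 * D)
}

#' Time-averaged lateral pressure of a trajectory
#'
#' @param trajectory A `trajectory`.
#' @param equilibration_fraction Leading fraction of frames to discard.
#' @export
measure_lateral_pressure <- function(trajectory, equilibration_fraction = 0.5) {
  n <- length(trajectory$lateral_pressure)
  keep <- seq.int(floor(equilibration_fraction * n) + 1L, n)
  mean(trajectory$lateral_pressure[keep])
}
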