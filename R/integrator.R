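#' Langevin integrator parameters
#'
#' Defaults follow the production protocol: collision frequency 1 ps^-1,
#' 300 K, 5 fs time step.  The resulting free diffusion constant is
#' `D = kB T / (m gamma)`.
#'
#' @param friction Collision frequency gamma, ps^-1 (>= 0; 0 gives
#'   microcanonical velocity-Verlet dynamics).
#' @param temperature Bath temperature, K (>= 0).
#' @param timestep Integration time step, ps (> 0).
#' @param seed Base random seed (integer) used by [run_protocol()].
#' @return An object of class `integrator_params`.
#' @export
integrator_params <- function(friction = 1, temperature = 300,
                              timestep = 0.005, seed = 1L) {
  stopifnot(friction >= 0, temperature >= 0, timestep > 0)
  structure(list(friction = friction, temperature = temperature,
                 timestep = timestep, seed = as.integer(seed)),
            class = "integrator_params")
}

#' Equilibration/production protocol
#'
#' The equilibration phase keeps particles inside the corral with a
#' one-sided harmonic wall at the corral boundary; the production phase
#' removes it and records snapshots.
#'
#' @param equilibration_time ps (default 25 ns).
#' @param production_time ps (default 10 us).
#' @param n_replicas Number of independent trajectories (paper scale: 20
#'   for rod-like fences, 30 for protein fences).
#' @param snapshot_interval ps between recorded frames.
#' @return An object of class `simulation_protocol`.
#' @export
simulation_protocol <- function(equilibration_time = 25000,
                                production_time = 1e7,
                                n_replicas = 20,
                                snapshot_interval = 1000) {
  stopifnot(equilibration_time >= 0, production_time >= 0, n_replicas >= 1,
            snapshot_interval > 0)
  structure(list(equilibration_time = equilibration_time,
                 production_time = production_time,
                 n_replicas = as.integer(n_replicas),
                 snapshot_interval = snapshot_interval),
            class = "simulation_protocol")
}

#' Maxwell-Boltzmann velocities
#'
#' @param n Number of particles.
#' @param mass Mass, amu (scalar or length n).
#' @param temperature K.
#' @return n x 3 matrix of velocities, A/ps.
#' @export
maxwell_velocities <- function(n, mass, temperature) {
  s <- sqrt(.kB * temperature * .akma / mass)
  matrix(rnorm(3 * n, sd = rep(s, 3)), ncol = 3)
}

#' Propagate a particle system by BAOAB Langevin dynamics
#'
#' One call runs `n_steps` discrete Langevin updates using the BAOAB
#' splitting (half kick, half drift, Ornstein-Uhlenbeck velocity update,
#' half drift, half kick), which samples the Boltzmann distribution at the
#' bath temperature and reduces to velocity Verlet when the friction is
#' zero.  Randomness comes from R's RNG, so runs are reproducible under
#' `set.seed()`.
#'
#' @param positions,velocities N x 3 matrices (A, A/ps).
#' @param particles A [particle_spec()] or per-particle data frame.
#' @param geometry A [system_geometry()].
#' @param params An [integrator_params()].
#' @param n_steps Number of steps.
#' @param snapshot_every Record every this many steps (frame 0 = initial
#'   state).
#' @param core_grid,phix_grid Optional [grid_potential()] maps.
#' @param corral_constraint Apply the equilibration-phase one-sided wall at
#'   the corral boundary?
#' @param include_pairs,cutoff Pairwise interaction switches (see
#'   [total_energy()]).
#' @param record_velocities Keep velocity snapshots (needed for
#'   [kinetic_temperature()]).
#' @return List with `times` (ps), snapshot matrices `x`, `y`, `z` (and
#'   `vx`, `vy`, `vz` if requested; frames in rows, particles in columns),
#'   and `final_pos` / `final_vel`.
#' @export
ld_run <- function(positions, velocities, particles = particle_spec(),
                   geometry = system_geometry(),
                   params = integrator_params(),
                   n_steps, snapshot_every = n_steps,
                   core_grid = NULL, phix_grid = NULL,
                   corral_constraint = FALSE, include_pairs = TRUE,
                   cutoff = 0, record_velocities = FALSE) {
  positions <- .as_pos_matrix(positions)
  velocities <- .as_pos_matrix(velocities)
  pp <- .particle_table(particles, nrow(positions))
  sys <- .sys_clist(geometry, corral_constraint, include_pairs, cutoff)
  ld_run_cpp(positions, velocities, pp$mass, pp$charge, pp$lj_well_depth,
             pp$lj_rmin_half, sys, .grid_clist(core_grid),
             .grid_clist(phix_grid), params$timestep, params$friction,
             params$temperature, as.integer(n_steps),
             as.integer(snapshot_every), record_velocities)
}

#' Single Langevin step
#'
#' Convenience wrapper around [ld_run()] with `n_steps = 1`.
#'
#' @inheritParams ld_run
#' @return As [ld_run()].
#' @export
ld_step <- function(positions, velocities, particles = particle_spec(),
                    geometry = system_geometry(),
                    params = integrator_params(), ...) {
  ld_run(positions, velocities, particles, geometry, params, n_steps = 1,
         snapshot_every = 1, record_velocities = TRUE, ...)
}

#' Run the full equilibration/production protocol over replicas
#'
#' Each replica is seeded deterministically from the base seed, given
#' Maxwell-Boltzmann initial velocities, equilibrated with the corral
#' constraint on, then propagated without it while snapshots are recorded.
#'
#' @param system A system as returned by [make_system()] (geometry,
#'   particle table, initial positions).
#' @param protocol A [simulation_protocol()].
#' @param params An [integrator_params()]; `params$seed` is the base seed.
#' @param core_grid,phix_grid Optional [grid_potential()] maps in the
#'   simulation frame.
#' @param include_pairs,cutoff See [total_energy()].
#' @param record_velocities Keep velocities in the snapshots.
#' @return An object of class `corral_trajectories`: `times` (ps),
#'   `replicas` (list of per-replica snapshot sets), `geometry`,
#'   `particles`, `seeds`, and metadata (`scheme = "BAOAB"`, parameters).
#' @export
run_protocol <- function(system, protocol = simulation_protocol(),
                         params = integrator_params(),
                         core_grid = NULL, phix_grid = NULL,
                         include_pairs = TRUE, cutoff = 0,
                         record_velocities = FALSE) {
  dt <- params$timestep
  n_eq <- round(protocol$equilibration_time / dt)
  n_pr <- round(protocol$production_time / dt)
  snap <- max(1L, round(protocol$snapshot_interval / dt))
  seeds <- params$seed + seq_len(protocol$n_replicas) - 1L
  replicas <- vector("list", protocol$n_replicas)
  times <- NULL
  for (r in seq_len(protocol$n_replicas)) {
    set.seed(seeds[r])
    vel <- maxwell_velocities(nrow(system$positions),
                              system$particles$mass, params$temperature)
    pos <- system$positions
    if (n_eq > 0) {
      eq <- ld_run(pos, vel, system$particles, system$geometry, params,
                   n_steps = n_eq, snapshot_every = n_eq,
                   core_grid = core_grid, phix_grid = phix_grid,
                   corral_constraint = TRUE, include_pairs = include_pairs,
                   cutoff = cutoff)
      pos <- eq$final_pos
      vel <- eq$final_vel
    }
    if (n_pr > 0) {
      run <- ld_run(pos, vel, system$particles, system$geometry, params,
                    n_steps = n_pr, snapshot_every = snap,
                    core_grid = core_grid, phix_grid = phix_grid,
                    corral_constraint = FALSE,
                    include_pairs = include_pairs, cutoff = cutoff,
                    record_velocities = record_velocities)
    } else {
      run <- list(times = 0, x = matrix(pos[, 1], nrow = 1),
                  y = matrix(pos[, 2], nrow = 1),
                  z = matrix(pos[, 3], nrow = 1), final_pos = pos,
                  final_vel = vel)
    }
    times <- run$times
    replicas[[r]] <- run
  }
  structure(list(times = times, replicas = replicas,
                 geometry = system$geometry, particles = system$particles,
                 seeds = seeds, scheme = "BAOAB", params = params,
                 protocol = protocol),
            class = "corral_trajectories")
}

#' Kinetic temperature of trajectory frames
#'
#' Mean kinetic energy per degree of freedom divided by kB/2, over the
#' selected frame window of all replicas.
#'
#' @param traj A `corral_trajectories` with recorded velocities, or a
#'   single [ld_run()] result.
#' @param frames Frame indices to include (default all).
#' @return Temperature in K.
#' @export
kinetic_temperature <- function(traj, frames = NULL) {
  runs <- if (inherits(traj, "corral_trajectories")) traj$replicas
          else list(traj)
  if (is.null(runs[[1]]$vx)) stop("velocities were not recorded")
  masses <- if (inherits(traj, "corral_trajectories"))
    traj$particles$mass else NULL
  tot <- 0; ndof <- 0
  for (run in runs) {
    f <- if (is.null(frames)) seq_len(nrow(run$vx)) else frames
    if (length(f) == 0) stop("empty frame window")
    m <- if (is.null(masses)) 1043 else masses
    v2 <- run$vx[f, , drop = FALSE]^2 + run$vy[f, , drop = FALSE]^2 +
      run$vz[f, , drop = FALSE]^2      # per particle-frame: sum of 3 dof
    tot <- tot + sum(sweep(v2, 2, m, "*")) / .akma
    ndof <- ndof + 3 * length(f) * ncol(run$vx)
  }
  tot / (ndof * .kB)
}

#' Write a trajectory set to columnar text files
#'
#' One gzip-compressed CSV per replica with columns replica, time (ps),
#' particle, x, y, z, plus a plain-text metadata sidecar (seeds, scheme,
#' parameters).
#'
#' @param traj A `corral_trajectories`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trajectories <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in seq_along(traj$replicas)) {
    run <- traj$replicas[[r]]
    nf <- nrow(run$x); np <- ncol(run$x)
    df <- data.frame(replica = r,
                     time = rep(run$times, np),
                     particle = rep(seq_len(np), each = nf),
                     x = as.numeric(run$x), y = as.numeric(run$y),
                     z = as.numeric(run$z))
    con <- gzfile(file.path(dir, sprintf("replica_%03d.csv.gz", r)), "w")
    write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
    close(con)
  }
  meta <- c(sprintf("scheme = %s", traj$scheme),
            sprintf("seeds = %s", paste(traj$seeds, collapse = " ")),
            sprintf("friction = %g", traj$params$friction),
            sprintf("temperature = %g", traj$params$temperature),
            sprintf("timestep = %g", traj$params$timestep))
  writeLines(meta, file.path(dir, "metadata.txt"))
  invisible(dir)
}
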