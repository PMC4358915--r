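#' Scenario recipe for a corral simulation system
#'
#' The three study scenarios use XY boxes of 1400 x 1000 A (rod-like
#' steric fence), 1400 x 450 A (rod-like electrostatic fence), and
#' 1400 x 750 A (protein fences), all with the corral spanning
#' -475 < X < 0 A.  At 6% corral concentration and 65 A^2 per lipid these
#' give 438, 197, and 329 spheres.  `scale_factor` shrinks the box (and
#' with it the particle count) for desk-scale runs.
#'
#' @param scenario One of `"steric_rod"`, `"electrostatic_rod"`,
#'   `"protein"`.
#' @param scale_factor Dimensionless box scale (1 = study scale).
#' @param target_corral_concentration %, lipids in the corral relative to
#'   all lipids there (default 6).
#' @param area_per_lipid A^2 (default 65).
#' @param seed Integer placement seed.
#' @return An object of class `system_recipe`.
#' @export
system_recipe <- function(scenario = c("steric_rod", "electrostatic_rod",
                                       "protein"),
                          scale_factor = 1,
                          target_corral_concentration = 6,
                          area_per_lipid = 65, seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(scale_factor > 0, target_corral_concentration > 0,
            area_per_lipid > 0)
  y_width <- switch(scenario, steric_rod = 1000, electrostatic_rod = 450,
                    protein = 750)
  structure(list(scenario = scenario, scale_factor = scale_factor,
                 box_x_lo = -475 * scale_factor,
                 box_x_hi = 925 * scale_factor,
                 y_width = y_width * scale_factor,
                 target_corral_concentration = target_corral_concentration,
                 area_per_lipid = area_per_lipid, seed = as.integer(seed)),
            class = "system_recipe")
}

#' Number of particles implied by a recipe
#'
#' `round(concentration * corral_area / area_per_lipid)`.
#'
#' @param recipe A [system_recipe()].
#' @return Integer particle count.
#' @export
recipe_particle_count <- function(recipe) {
  corral_area <- (0 - recipe$box_x_lo) * recipe$y_width
  round(recipe$target_corral_concentration / 100 * corral_area /
          recipe$area_per_lipid)
}

#' Build a simulation system from a recipe
#'
#' Places the implied number of lipid spheres uniformly inside the corral
#' by rejection sampling with a minimum separation of one LJ contact
#' distance, all on the diffusion plane.
#'
#' @param recipe A [system_recipe()].
#' @param particles A [particle_spec()].
#' @param geometry Optional [system_geometry()] override; by default built
#'   from the recipe.
#' @param max_tries Rejection-sampling attempts per particle before
#'   giving up.
#' @return A list of class `corral_system`: `geometry`, `particles` (per
#'   particle data frame), `positions` (N x 3), `recipe`.
#' @export
make_system <- function(recipe, particles = particle_spec(),
                        geometry = NULL, max_tries = 2000) {
  if (is.null(geometry))
    geometry <- system_geometry(box_x_lo = recipe$box_x_lo,
                                box_x_hi = recipe$box_x_hi,
                                box_y_lo = -recipe$y_width / 2,
                                box_y_hi = recipe$y_width / 2)
  n <- recipe_particle_count(recipe)
  rmin <- 2 * particles$lj_rmin_half
  margin <- particles$lj_rmin_half
  if (!is.null(recipe$seed)) set.seed(recipe$seed)
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0
  tries <- 0
  while (placed < n) {
    x <- runif(1, geometry$box_x_lo + margin,
               geometry$corral_boundary_x - margin)
    y <- runif(1, geometry$box_y_lo + margin, geometry$box_y_hi - margin)
    ok <- placed == 0 ||
      min((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2) >=
      rmin^2
    if (ok) {
      placed <- placed + 1
      xs[placed] <- x; ys[placed] <- y
      tries <- 0
    } else {
      tries <- tries + 1
      if (tries > max_tries)
        stop("could not deposit the requested density (",
             placed, " of ", n, " placed)")
    }
  }
  pos <- cbind(xs, ys, rep(geometry$diffusion_plane_z, n))
  structure(list(geometry = geometry,
                 particles = .particle_table(particles, n),
                 positions = pos, recipe = recipe),
            class = "corral_system")
}

#' Desk-scale study profile
#'
#' The reduced profile used for trend-level runs: quarter-scale box
#' (which scales the particle count with the corral area), friction
#' reduced to 0.1 ps^-1 (raising D tenfold), 10 fs time step, 8 replicas,
#' 0.5 ns corral-constrained equilibration and 25 ns production sampled
#' every 10 ps.  The free-pool relaxation at this scale is a few hundred
#' ps; the span covers retarded relaxations up to ~20x that while the
#' sampling still resolves the initial decay, which keeps the fitted
#' plateau (and hence the mean relaxation time) of strongly blocked
#' fences well constrained.  Only relaxation-time ratios are
#' interpreted at this profile.
#'
#' @param seed Base seed.
#' @return List with `scale_factor`, `params` ([integrator_params()]) and
#'   `protocol` ([simulation_protocol()]).
#' @export
desk_profile <- function(seed = 1L) {
  list(scale_factor = 0.25,
       params = integrator_params(friction = 0.1, temperature = 300,
                                  timestep = 0.01, seed = seed),
       protocol = simulation_protocol(equilibration_time = 500,
                                      production_time = 25000,
                                      n_replicas = 8,
                                      snapshot_interval = 10))
}

#' Pseudo-filament specification
#'
#' A synthetic stand-in for protein filaments: each subunit is a row of
#' bead columns along the fence axis, with residue labels drawn
#' cyclically from `sequence` so charge assignment, burial, replication,
#' PB mapping, and burial histograms are all exercised.  The `"arch"`
#' profile raises the column bases over the middle half of the subunit
#' (with linear ramps at the ends), leaving an under-filament channel
#' even at deep burial (the actin-like shape); `"flat"` keeps the
#' underside level (septin-like blanket coverage when buried).
#'
#' @param profile `"flat"` or `"arch"`.
#' @param n_stations Bead columns per subunit.
#' @param column_height Height of each bead column, A (filament
#'   thickness).
#' @param bead_radius A.
#' @param bead_spacing Vertical bead spacing within a column, A.
#' @param arch_height Arch apex elevation of the column base, A.
#' @param translation Subunit rise along the fence axis, A.
#' @param rotation Subunit rotation about the fence axis, degrees.
#' @param sequence Residue labels cycled over the beads.
#' @return An object of class `pseudo_filament_spec`.
#' @export
pseudo_filament_spec <- function(profile = c("flat", "arch"),
                                 n_stations = 6, column_height = 30,
                                 bead_radius = 3, bead_spacing = 5,
                                 arch_height = 45, translation = 27.6,
                                 rotation = 0,
                                 sequence = c("LYS", "PHE", "GLY", "ASP",
                                              "SER", "LEU", "ARG", "TYR",
                                              "ALA", "GLU")) {
  profile <- match.arg(profile)
  stopifnot(n_stations >= 2, column_height > 0, bead_radius > 0,
            bead_spacing > 0, arch_height >= 0)
  structure(list(profile = profile, n_stations = n_stations,
                 column_height = column_height, bead_radius = bead_radius,
                 bead_spacing = bead_spacing, arch_height = arch_height,
                 translation = translation, rotation = rotation,
                 sequence = sequence),
            class = "pseudo_filament_spec")
}

#' Build one pseudo-filament subunit
#'
#' Coordinates are in the membrane frame with the lowest bead at z = 0
#' (use [bury_filament()] to set the burial depth) and the fence axis
#' along Y at X = 0.  Charges and radii come from
#' [residue_charge_table()].
#'
#' @param spec A [pseudo_filament_spec()].
#' @param path Optional PDB output path (written via [write_structure()]).
#' @return Data frame with `x`, `y`, `z`, `radius`, `charge`, `resid`,
#'   `resno`, `elety`.
#' @export
make_pseudo_filament <- function(spec = pseudo_filament_spec(),
                                 path = NULL) {
  tbl <- residue_charge_table()
  ys <- (seq_len(spec$n_stations) - 0.5) *
    spec$translation / spec$n_stations
  t_frac <- (seq_len(spec$n_stations) - 0.5) / spec$n_stations
  base <- if (spec$profile == "arch")
    spec$arch_height * pmin(1, 4 * pmin(t_frac, 1 - t_frac))
  else rep(0, spec$n_stations)
  nz <- max(2, ceiling(spec$column_height / spec$bead_spacing) + 1)
  rows <- list()
  k <- 0
  for (i in seq_len(spec$n_stations)) {
    for (j in seq_len(nz)) {
      k <- k + 1
      z <- base[i] + spec$bead_radius +
        (j - 1) * spec$column_height / (nz - 1)
      resid <- spec$sequence[(k - 1) %% length(spec$sequence) + 1]
      m <- match(resid, tbl$resid)
      rows[[k]] <- data.frame(x = 0, y = ys[i], z = z,
                              radius = tbl$radius[m],
                              charge = tbl$charge[m], resid = resid,
                              resno = k, elety = "CA",
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$z <- out$z - min(out$z)   # lowest bead at the phosphate plane
  if (!is.null(path)) write_structure(out, path)
  out
}

#' Continuum free-diffusion pool fraction
#'
#' Closed-form reference for free diffusion: the 1D diffusion equation on
#' `[box_x_lo, box_x_hi]` with reflecting walls and an initial step
#' profile filling the corral at `c0`, solved by a Fourier-cosine series;
#' the pool concentration is the average over the corral.  Terms are
#' added until the truncated tail is below `tol`.
#'
#' @param geometry A [system_geometry()].
#' @param D Diffusion constant, A^2/ps.
#' @param times ps.
#' @param c0 Initial corral concentration, %.
#' @param tol Series truncation tolerance.
#' @return Data frame with `time` and `concentration` (%).
#' @export
continuum_free_diffusion <- function(geometry, D, times, c0 = 6,
                                     tol = 1e-10) {
  L <- geometry$box_x_hi - geometry$box_x_lo
  w <- geometry$corral_boundary_x - geometry$box_x_lo
  conc <- vapply(times, function(t) {
    val <- c0 * w / L
    n <- 1
    repeat {
      ns <- n:(n + 511)
      terms <- 2 * c0 * L / (ns^2 * pi^2 * w) * sin(ns * pi * w / L)^2 *
        exp(-D * ns^2 * pi^2 * t / L^2)
      val <- val + sum(terms)
      # remaining tail is bounded by sum 2 c0 L/(pi^2 w n^2)
      bound <- 2 * c0 * L / (pi^2 * w) / max(ns) *
        exp(-D * max(ns)^2 * pi^2 * t / L^2)
      n <- max(ns) + 1
      if (bound < tol || n > 1e6) break
    }
    val
  }, numeric(1))
  data.frame(time = times, concentration = conc)
}

#' Synthetic stretched-exponential decay curve
#'
#' Evaluates `C(t) = (c0 - c_inf) exp[-(t/tau)^beta] + c_inf` on a time
#' grid and adds Gaussian noise; returned in the same form as
#' [depletion_series()] so it can be fed to
#' [fit_stretched_exponential()].
#'
#' @param c0,c_inf,tau,beta Curve parameters (%, %, ps, dimensionless).
#' @param noise_sd Gaussian noise standard deviation, % (0 = noiseless).
#' @param n_points Number of time points.
#' @param t_max Final time, ps.
#' @param n_replicas Independent noisy replicas averaged into `mean`.
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @return A `depletion_series`.
#' @export
make_decay_curve <- function(c0 = 6, c_inf = 2, tau = 1e3, beta = 1,
                             noise_sd = 0, n_points = 200,
                             t_max = 5 * tau, n_replicas = 1,
                             seed = NULL) {
  stopifnot(tau > 0, beta > 0, beta <= 2, c_inf >= 0, n_points >= 2)
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, t_max, length.out = n_points)
  backbone <- (c0 - c_inf) * exp(-(tt / tau)^beta) + c_inf
  per <- matrix(rep(backbone, n_replicas), ncol = n_replicas)
  if (noise_sd > 0)
    per <- per + matrix(rnorm(length(per), sd = noise_sd), nrow = n_points)
  structure(list(times = tt, mean = rowMeans(per), per_replica = per,
                 n_replicas = n_replicas, c0 = c0,
                 backbone = backbone),
            class = "depletion_series")
}
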