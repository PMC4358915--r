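#' Parameters of a model lipid sphere
#'
#' PIP2 is represented as a single charged Lennard-Jones sphere.  Defaults
#' are the model lipid: charge -4 e, well depth 0.5 kcal/mol, r_min/2 =
#' 5.4 A, mass 1043 amu.
#'
#' @param charge Charge in elementary charges.
#' @param lj_well_depth Lennard-Jones well depth epsilon, kcal/mol (> 0).
#' @param lj_rmin_half Half the LJ minimum distance, A (> 0).
#' @param mass Mass in amu (> 0).
#' @return An object of class `particle_spec`.
#' @export
particle_spec <- function(charge = -4, lj_well_depth = 0.5,
                          lj_rmin_half = 5.4, mass = 1043) {
  stopifnot(lj_well_depth > 0, lj_rmin_half > 0, mass > 0)
  structure(list(charge = charge, lj_well_depth = lj_well_depth,
                 lj_rmin_half = lj_rmin_half, mass = mass),
            class = "particle_spec")
}

#' Simulation box and restraint geometry
#'
#' The diffusion plane is the XY plane at `diffusion_plane_z`, held
#' `membrane_offset` A above the lipid phosphate plane.  Particles are
#' confined to the plane by a harmonic restraint and to the box by harmonic
#' hard walls; the corral is the region `x < corral_boundary_x`.
#'
#' @param box_x_lo,box_x_hi,box_y_lo,box_y_hi Box edges, A.
#' @param corral_boundary_x Fence line, A (between the x edges).
#' @param diffusion_plane_z Height of the diffusion plane in the simulation
#'   frame, A.
#' @param membrane_offset Height of the diffusion plane above the lipid
#'   phosphate plane, A.
#' @param planar_force_constant Planar restraint k, kcal/mol/A^2
#'   (`U = k dz^2`, no 1/2 prefactor).
#' @param wall_force_constant Hard-wall k, kcal/mol/A^2.
#' @return An object of class `system_geometry`.
#' @export
system_geometry <- function(box_x_lo = -475, box_x_hi = 925,
                            box_y_lo = -500, box_y_hi = 500,
                            corral_boundary_x = 0, diffusion_plane_z = 0,
                            membrane_offset = 5,
                            planar_force_constant = 0.6,
                            wall_force_constant = 100) {
  stopifnot(box_x_lo < corral_boundary_x, corral_boundary_x < box_x_hi,
            box_y_lo < box_y_hi,
            planar_force_constant > 0, wall_force_constant > 0)
  structure(list(box_x_lo = box_x_lo, box_x_hi = box_x_hi,
                 box_y_lo = box_y_lo, box_y_hi = box_y_hi,
                 corral_boundary_x = corral_boundary_x,
                 diffusion_plane_z = diffusion_plane_z,
                 membrane_offset = membrane_offset,
                 planar_force_constant = planar_force_constant,
                 wall_force_constant = wall_force_constant),
            class = "system_geometry")
}

# list consumed by the C++ engine
.sys_clist <- function(geometry, corral_constraint = FALSE,
                       include_pairs = TRUE, cutoff = 0) {
  list(box_x_lo = geometry$box_x_lo, box_x_hi = geometry$box_x_hi,
       box_y_lo = geometry$box_y_lo, box_y_hi = geometry$box_y_hi,
       wall_force_constant = geometry$wall_force_constant,
       planar_force_constant = geometry$planar_force_constant,
       diffusion_plane_z = geometry$diffusion_plane_z,
       corral_boundary_x = geometry$corral_boundary_x,
       corral_constraint = corral_constraint,
       include_pairs = include_pairs,
       cutoff = cutoff,
       coulomb_constant = .ke,
       pair_dielectric = .eps_pair)
}

#' Pair interaction between two lipid spheres
#'
#' Lennard-Jones (12-6 in r_min form) plus Coulomb with a uniform pairwise
#' dielectric of 80:
#' `U(r) = eps [ (r_min/r)^12 - 2 (r_min/r)^6 ] + k_e q1 q2 / (80 r)`.
#' Lorentz-Berthelot-style combining: `r_min = rmh1 + rmh2`,
#' `eps = sqrt(eps1 eps2)`.
#'
#' @param r Separation, A (> 0); vectorized.
#' @param p1,p2 [particle_spec()] objects.
#' @return A list with `energy` (kcal/mol), `force` (kcal/mol/A, the radial
#'   force `-dU/dr`, positive = repulsive), and the components `lj` and
#'   `coulomb`.
#' @export
#' @examples
#' pair_interaction(10.8, particle_spec(), particle_spec())$energy
pair_interaction <- function(r, p1 = particle_spec(), p2 = p1) {
  if (any(r <= 0)) stop("separation r must be positive")
  rmin <- p1$lj_rmin_half + p2$lj_rmin_half
  eps <- sqrt(p1$lj_well_depth * p2$lj_well_depth)
  s6 <- (rmin / r)^6
  lj <- eps * (s6^2 - 2 * s6)
  coul <- .ke * p1$charge * p2$charge / (.eps_pair * r)
  dlj <- eps * (-12 * s6^2 + 12 * s6) / r
  dcoul <- -coul / r
  list(energy = lj + coul, force = -(dlj + dcoul), lj = lj, coulomb = coul)
}

#' Restraint energy of a particle position
#'
#' Planar confinement `k_plane (z - z_plane)^2` plus harmonic hard walls
#' `k_wall overshoot^2` for each violated box edge (no 1/2 prefactor, the
#' CHARMM restraint convention).
#'
#' @param position Numeric length-3 (x, y, z), A.
#' @param geometry A [system_geometry()].
#' @return List with `energy` (kcal/mol), `force` (length-3, kcal/mol/A),
#'   and components `planar` and `wall`.
#' @export
restraint_energy <- function(position, geometry = system_geometry()) {
  x <- position[1]; y <- position[2]; z <- position[3]
  kp <- geometry$planar_force_constant
  kw <- geometry$wall_force_constant
  dz <- z - geometry$diffusion_plane_z
  planar <- kp * dz^2
  f <- c(0, 0, -2 * kp * dz)
  wall <- 0
  if (x < geometry$box_x_lo) {
    d <- geometry$box_x_lo - x; wall <- wall + kw * d^2; f[1] <- f[1] + 2 * kw * d
  }
  if (x > geometry$box_x_hi) {
    d <- x - geometry$box_x_hi; wall <- wall + kw * d^2; f[1] <- f[1] - 2 * kw * d
  }
  if (y < geometry$box_y_lo) {
    d <- geometry$box_y_lo - y; wall <- wall + kw * d^2; f[2] <- f[2] + 2 * kw * d
  }
  if (y > geometry$box_y_hi) {
    d <- y - geometry$box_y_hi; wall <- wall + kw * d^2; f[2] <- f[2] - 2 * kw * d
  }
  list(energy = planar + wall, force = f, planar = planar, wall = wall)
}

#' Total energy of a particle configuration
#'
#' Sums the pairwise LJ + Coulomb terms over all unordered pairs, the
#' per-particle core-repulsion and electrostatic grid terms (absent grids
#' contribute zero), and the planar/wall restraints.
#'
#' @param positions N x 3 matrix, A.
#' @param particles A [particle_spec()] applied to every particle, or a
#'   data frame with columns `charge`, `lj_well_depth`, `lj_rmin_half`,
#'   `mass` (one row per particle).
#' @param geometry A [system_geometry()].
#' @param core_grid,phix_grid Optional [grid_potential()] maps: core
#'   repulsion (kcal/mol) and static electrostatic potential
#'   (kcal/(mol e)).
#' @param include_pairs Include pairwise interactions?
#' @param cutoff Pairwise cutoff with energy shifting, A; 0 disables (the
#'   default; keep it off for production-quality energetics).
#' @return List with `breakdown` (named components plus `total`) and
#'   `forces` (N x 3, exact negative gradient).
#' @export
total_energy <- function(positions, particles = particle_spec(),
                         geometry = system_geometry(),
                         core_grid = NULL, phix_grid = NULL,
                         include_pairs = TRUE, cutoff = 0) {
  positions <- .as_pos_matrix(positions)
  pp <- .particle_table(particles, nrow(positions))
  sys <- .sys_clist(geometry, corral_constraint = FALSE,
                    include_pairs = include_pairs, cutoff = cutoff)
  res <- energy_forces_cpp(positions, pp$charge, pp$lj_well_depth,
                           pp$lj_rmin_half, sys,
                           .grid_clist(core_grid), .grid_clist(phix_grid))
  b <- as.list(res$breakdown)
  b$total <- sum(res$breakdown)
  list(breakdown = b, forces = res$forces)
}

.as_pos_matrix <- function(positions) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  storage.mode(positions) <- "double"
  stopifnot(ncol(positions) == 3)
  positions
}

.particle_table <- function(particles, n) {
  if (inherits(particles, "particle_spec")) {
    data.frame(charge = rep(particles$charge, n),
               lj_well_depth = rep(particles$lj_well_depth, n),
               lj_rmin_half = rep(particles$lj_rmin_half, n),
               mass = rep(particles$mass, n))
  } else {
    stopifnot(is.data.frame(particles), nrow(particles) == n)
    particles
  }
}
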