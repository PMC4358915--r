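#' Implicit membrane-solvent environment for Poisson-Boltzmann solves
#'
#' Three dielectric regions in the membrane frame (lipid phosphate plane at
#' `membrane_top_z`): the membrane slab of the given thickness below it
#' (dielectric 2, no salt), the solute interior of fence/protein atoms
#' (dielectric 2, no salt), and the solvent elsewhere (dielectric 80, mobile
#' 1:1 salt at `salt_concentration`).
#'
#' @param membrane_thickness A (default 36).
#' @param membrane_dielectric,solvent_dielectric,solute_dielectric
#'   Relative dielectric constants (defaults 2, 80, 2).
#' @param salt_concentration mM of 1:1 salt (default 150).
#' @param temperature K (default 300).
#' @param membrane_top_z Z of the phosphate plane in the membrane frame
#'   (default 0).
#' @return An object of class `pb_environment`.
#' @export
pb_environment <- function(membrane_thickness = 36, membrane_dielectric = 2,
                           solvent_dielectric = 80, solute_dielectric = 2,
                           salt_concentration = 150, temperature = 300,
                           membrane_top_z = 0) {
  stopifnot(membrane_thickness > 0, membrane_dielectric > 0,
            solvent_dielectric > 0, solute_dielectric > 0,
            salt_concentration >= 0, temperature > 0)
  structure(list(membrane_thickness = membrane_thickness,
                 membrane_dielectric = membrane_dielectric,
                 solvent_dielectric = solvent_dielectric,
                 solute_dielectric = solute_dielectric,
                 salt_concentration = salt_concentration,
                 temperature = temperature,
                 membrane_top_z = membrane_top_z),
            class = "pb_environment")
}

#' Debye screening parameters of the solvent
#'
#' @param env A [pb_environment()].
#' @return List with `kappa` (inverse screening length, 1/A), `length`
#'   (screening length, A; about 8 A at 150 mM), and `kap2bar` (the
#'   `eps_s kappa^2` coefficient of the linearized PB equation, 1/A^2).
#' @export
debye_parameters <- function(env = pb_environment()) {
  n_ion <- env$salt_concentration * 1e-3 * 6.02214076e23 * 1e-27  # ions/A^3
  kap2bar <- 8 * pi * .ke * n_ion / (.kB * env$temperature)
  kappa <- sqrt(kap2bar / env$solvent_dielectric)
  list(kappa = kappa,
       length = if (kappa > 0) 1 / kappa else Inf,
       kap2bar = kap2bar)
}

#' Grid focusing schedule
#'
#' The potential is first solved on a coarse grid over an enlarged domain
#' with analytic Debye-Hueckel boundary values; the coarse solution then
#' supplies Dirichlet boundary values (and the initial guess) for the fine
#' focused grid.
#'
#' @param coarse_spacing A (default 1.0).
#' @param fine_spacing A (default 0.5; must be <= coarse).
#' @param pad Extra margin of the coarse domain beyond the fine domain on
#'   every side, A.
#' @return An object of class `focusing_schedule`.
#' @export
focusing_schedule <- function(coarse_spacing = 1.0, fine_spacing = 0.5,
                              pad = 30) {
  stopifnot(fine_spacing <= coarse_spacing, fine_spacing > 0, pad >= 0)
  structure(list(coarse_spacing = coarse_spacing,
                 fine_spacing = fine_spacing, pad = pad),
            class = "focusing_schedule")
}

#' Build a core-repulsion map
#'
#' Node value 100 kcal/mol inside any atom sphere after augmenting its
#' radius by `augmentation` (default 4.16 A), zero in all lipid-accessible
#' regions.
#'
#' @param atoms Data frame with `x`, `y`, `z`, `radius`.
#' @param origin,spacing,counts Grid specification (see
#'   [grid_potential()]).
#' @param augmentation Radius augmentation, A.
#' @param height Repulsion plateau, kcal/mol (default 100).
#' @param bbox Passed to [grid_potential()] (default `"auto"`).
#' @return A [grid_potential()] with clamped boundary policy.
#' @export
build_core_map <- function(atoms, origin, spacing, counts,
                           augmentation = 4.16, height = 100,
                           bbox = "auto") {
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(all(is.finite(origin)), all(spacing > 0))
  counts <- as.integer(counts)
  am <- if (nrow(atoms) > 0)
    as.matrix(cbind(atoms$x, atoms$y, atoms$z, atoms$radius, 0))
  else matrix(0, 0, 5)
  v <- core_map_cpp(as.numeric(origin), as.numeric(spacing), counts, am,
                    augmentation, height)
  grid_potential(origin, spacing, array(v, dim = counts), clamp = TRUE,
                 bbox = bbox)
}

#' Solve the linearized Poisson-Boltzmann equation on a grid
#'
#' Finite-difference solution of
#' `div(eps grad phi) - eps_s kappa^2(r) phi = -4 pi k_e rho` with the
#' three dielectric regions of [pb_environment()], by damped red-black
#' successive over-relaxation on the 7-point stencil.  The potential is
#' returned in kcal/(mol e).
#'
#' Dirichlet boundary values come either from the screened Debye-Hueckel
#' sum over `bc_atoms` (`bc = "debye_huckel"`), from a caller-supplied
#' full-grid array whose boundary layer is held fixed (`bc = "values"`,
#' used for focusing), or from an arbitrary function of the boundary node
#' coordinates (`bc` a function, used for closed-form cross-checks).
#'
#' @param atoms Data frame with `x`, `y`, `z`, `radius`, `charge` in the
#'   membrane frame.  Atom interiors get the solute dielectric; charges are
#'   spread trilinearly.  Atoms whose centres fall outside the grid keep
#'   their dielectric role but contribute charge only through the boundary
#'   condition.
#' @param env A [pb_environment()].
#' @param origin,spacing,counts Grid specification; spacing must be
#'   isotropic.
#' @param bc Boundary condition mode (see above).
#' @param bc_atoms Charge set for the Debye-Hueckel boundary sum (default
#'   `atoms`; pass an extended set, e.g. a longer rod, when the grid is a
#'   window onto a larger periodic structure).
#' @param bc_values Full-grid numeric array for `bc = "values"`.
#' @param init Optional full-grid initial guess.
#' @param tol Convergence tolerance on the relative maximum update
#'   (default 1e-6).
#' @param maxit Maximum iterations (default 10000).
#' @param omega Over-relaxation factor (default from the grid dimensions).
#' @return A [grid_potential()] (clamp = FALSE) with attributes
#'   `iterations` and `residual`.
#' @export
solve_pb <- function(atoms, env = pb_environment(), origin, spacing, counts,
                     bc = "debye_huckel", bc_atoms = atoms,
                     bc_values = NULL, init = NULL,
                     tol = 1e-6, maxit = 10000, omega = NULL, stern = 0) {
  if (length(spacing) > 1) {
    stopifnot(length(unique(spacing)) == 1)
    spacing <- spacing[1]
  }
  counts <- as.integer(counts)
  dh <- debye_parameters(env)
  if (is.null(omega)) omega <- 2 / (1 + sin(pi / max(counts)))
  am <- .pb_atom_matrix(atoms)
  # zero out source charges that cannot be spread inside the grid
  hi <- origin + (counts - 1) * spacing
  inside <- am[, 1] > origin[1] & am[, 1] < hi[1] - spacing &
            am[, 2] > origin[2] & am[, 2] < hi[2] - spacing &
            am[, 3] > origin[3] & am[, 3] < hi[3] - spacing
  am[!inside, 5] <- 0
  bcm <- .pb_atom_matrix(bc_atoms)
  zhi <- env$membrane_top_z
  zlo <- zhi - env$membrane_thickness
  bc_mode <- 0L
  if (is.function(bc)) {
    init <- .pb_bc_function_array(bc, origin, spacing, counts, init)
    bc_mode <- 1L
  } else if (identical(bc, "values")) {
    stopifnot(!is.null(bc_values))
    if (is.null(init)) init <- bc_values
    init <- .pb_merge_boundary(bc_values, init, counts)
    bc_mode <- 1L
  } else if (!identical(bc, "debye_huckel")) {
    stop("unknown boundary condition mode")
  }
  sol <- pb_solve_cpp(as.numeric(origin), spacing, counts, am,
                      env$solute_dielectric, env$membrane_dielectric,
                      env$solvent_dielectric, zlo, zhi, dh$kap2bar,
                      .ke, bc_mode, bcm,
                      if (is.null(init)) NULL else as.numeric(init),
                      omega, tol, as.integer(maxit), stern)
  g <- grid_potential(origin, rep(spacing, 3),
                      array(sol$phi, dim = counts), clamp = FALSE)
  attr(g, "iterations") <- sol$iterations
  attr(g, "residual") <- sol$residual
  g
}

.pb_atom_matrix <- function(atoms) {
  if (is.null(atoms) || nrow(atoms) == 0) return(matrix(0, 0, 5))
  as.matrix(cbind(atoms$x, atoms$y, atoms$z, atoms$radius, atoms$charge))
}

# evaluate a user bc function on boundary nodes, keep init in the interior
.pb_bc_function_array <- function(f, origin, spacing, counts, init) {
  a <- if (is.null(init)) array(0, dim = counts) else array(init, dim = counts)
  ax <- origin[1] + (seq_len(counts[1]) - 1) * spacing
  ay <- origin[2] + (seq_len(counts[2]) - 1) * spacing
  az <- origin[3] + (seq_len(counts[3]) - 1) * spacing
  fill <- function(ix, iy, iz) {
    pts <- as.matrix(expand.grid(x = ax[ix], y = ay[iy], z = az[iz]))
    a[ix, iy, iz] <<- array(f(pts), dim = c(length(ix), length(iy),
                                            length(iz)))
  }
  n <- counts
  fill(c(1, n[1]), seq_len(n[2]), seq_len(n[3]))
  fill(seq_len(n[1]), c(1, n[2]), seq_len(n[3]))
  fill(seq_len(n[1]), seq_len(n[2]), c(1, n[3]))
  a
}

.pb_merge_boundary <- function(bc_values, init, counts) {
  a <- array(init, dim = counts)
  b <- array(bc_values, dim = counts)
  n <- counts
  a[c(1, n[1]), , ] <- b[c(1, n[1]), , ]
  a[, c(1, n[2]), ] <- b[, c(1, n[2]), ]
  a[, , c(1, n[3])] <- b[, , c(1, n[3])]
  a
}

#' Focused Poisson-Boltzmann solve
#'
#' Standard two-stage focusing: a coarse solve on a domain enlarged by
#' `schedule$pad` with Debye-Hueckel boundary values, then a fine solve on
#' the requested domain with boundary values and initial guess
#' interpolated from the coarse solution.
#'
#' @param atoms,env,bc_atoms,tol,maxit As in [solve_pb()].
#' @param origin,counts Fine-grid specification at
#'   `schedule$fine_spacing`.
#' @param schedule A [focusing_schedule()].
#' @return A [grid_potential()] as in [solve_pb()], with attribute
#'   `coarse` holding the coarse solution.
#' @export
solve_pb_focused <- function(atoms, env = pb_environment(), origin, counts,
                             schedule = focusing_schedule(),
                             bc_atoms = atoms, tol = 1e-6, maxit = 10000,
                             stern = 0) {
  hs <- schedule$coarse_spacing
  hf <- schedule$fine_spacing
  counts <- as.integer(counts)
  fine_hi <- origin + (counts - 1) * hf
  c_origin <- origin - schedule$pad
  c_counts <- as.integer(ceiling((fine_hi + schedule$pad - c_origin) / hs)) + 1L
  coarse <- solve_pb(atoms, env, c_origin, hs, c_counts,
                     bc = "debye_huckel", bc_atoms = bc_atoms,
                     tol = tol, maxit = maxit, stern = stern)
  ax <- origin[1] + (seq_len(counts[1]) - 1) * hf
  ay <- origin[2] + (seq_len(counts[2]) - 1) * hf
  az <- origin[3] + (seq_len(counts[3]) - 1) * hf
  pts <- as.matrix(expand.grid(x = ax, y = ay, z = az))
  guess <- trilinear_cpp(coarse$origin, coarse$spacing,
                         as.integer(coarse$counts),
                         as.numeric(coarse$values), pts)
  guess <- array(guess, dim = counts)
  fine <- solve_pb(atoms, env, origin, hf, counts, bc = "values",
                   bc_values = guess, init = guess, tol = tol,
                   maxit = maxit, stern = stern)
  attr(fine, "coarse") <- coarse
  fine
}

#' Electrostatic interaction profile of a test charge across a rod fence
#'
#' Solves the linearized PB equation around the rod in the implicit
#' membrane environment and evaluates `U(X) = q_test phi(X, 0, z)` along
#' the diffusion plane, referenced to zero at the far field (the outer
#' 10 A of the profile window).  The grid is a finite Y window onto the
#' infinite rod; rod charges outside the window enter through the
#' Debye-Hueckel boundary sum (documented approximation).
#'
#' @param rod Rod sphere data frame from [build_electrostatic_rod()]
#'   (simulation frame).
#' @param env A [pb_environment()].
#' @param test_charge e (default -4, the model lipid).
#' @param membrane_offset Height of the diffusion plane above the
#'   phosphate plane, A (default 5).
#' @param x_max Profile half-width, A.
#' @param y_half Solve-window half-width along the rod, A.
#' @param z_range Solve-window Z range in the membrane frame, A.
#' @param schedule A [focusing_schedule()]; set `NULL` to solve the fine
#'   grid directly with Debye-Hueckel boundaries.
#' @param tol,maxit Solver controls.
#' @return Data frame with columns `x` and `energy` (kcal/mol, far-field
#'   referenced), with attributes `barrier` (max) and `well` (-min).
#' @export
rod_interaction_profile <- function(rod, env = pb_environment(),
                                    test_charge = -4, membrane_offset = 5,
                                    x_max = 60, y_half = 43.2,
                                    z_range = c(-20, 30),
                                    schedule = focusing_schedule(),
                                    tol = 1e-6, maxit = 10000, stern = 0) {
  atoms <- rod
  atoms$z <- atoms$z + membrane_offset  # simulation -> membrane frame
  h <- if (is.null(schedule)) 0.5 else schedule$fine_spacing
  origin <- c(-x_max, -y_half, z_range[1])
  counts <- as.integer(round(c(2 * x_max, 2 * y_half,
                               diff(z_range)) / h)) + 1L
  inwin <- abs(atoms$y) <= y_half
  g <- if (is.null(schedule)) {
    solve_pb(atoms[inwin, ], env, origin, h, counts, bc_atoms = atoms,
             tol = tol, maxit = maxit, stern = stern)
  } else {
    solve_pb_focused(atoms[inwin, ], env, origin, counts, schedule,
                     bc_atoms = atoms, tol = tol, maxit = maxit,
                     stern = stern)
  }
  xs <- seq(-x_max + 2 * h, x_max - 2 * h, by = h)
  pts <- cbind(xs, 0, membrane_offset)
  u <- test_charge * grid_value_and_force(pts, g)$value
  far <- abs(xs) >= x_max - 10 - 2 * h
  u <- u - mean(u[far])
  out <- data.frame(x = xs, energy = u)
  attr(out, "barrier") <- max(u)
  attr(out, "well") <- -min(u)
  attr(out, "grid") <- g
  out
}

#' Combined potential slice on the diffusion plane
#'
#' Evaluates `U_CORE + q phi_PHIX` for a test charge on a Z slice and
#' reports whether a continuous X-crossing channel of sub-threshold
#' potential exists (flood fill on the 4-connected open-cell map).
#'
#' @param core_grid,phix_grid Optional [grid_potential()] maps sharing a
#'   frame (at least one required).
#' @param z Slice height, A.
#' @param test_charge e (default -4).
#' @param threshold Channel threshold, kcal/mol (default 7.5, the
#'   complete-blockade barrier scale).
#' @return List with `x`, `y`, `values` (nx x ny matrix), `channel`
#'   (logical), and `threshold`.
#' @export
potential_map_slice <- function(core_grid = NULL, phix_grid = NULL, z = 0,
                                test_charge = -4, threshold = 7.5) {
  ref <- if (!is.null(core_grid)) core_grid else phix_grid
  if (is.null(ref)) stop("at least one grid is required")
  ax <- grid_axes(ref)
  xs <- ax$x[-c(1, length(ax$x))]
  ys <- ax$y[-c(1, length(ax$y))]
  pts <- as.matrix(expand.grid(x = xs, y = ys))
  pts <- cbind(pts, z)
  vals <- numeric(nrow(pts))
  if (!is.null(core_grid))
    vals <- vals + grid_value_and_force(pts, core_grid)$value
  if (!is.null(phix_grid))
    vals <- vals + test_charge * grid_value_and_force(pts, phix_grid)$value
  m <- matrix(vals, nrow = length(xs))
  channel <- crossing_channel_cpp(as.logical(m < threshold),
                                  length(xs), length(ys))
  list(x = xs, y = ys, values = m, channel = channel,
       threshold = threshold)
}

#' Poisson-Boltzmann interaction energy between two solutes
#'
#' Computes `E_int = E(A+B) - E(A) - E(B)` from three focused solves on
#' the same grid, where each energy is `1/2 sum q_i phi(r_i)` over the
#' solute charges.  Because all three solves share the grid and charge
#' placement, grid self-energies cancel and the difference contains the
#' screened Coulomb interaction plus the mutual desolvation that arises
#' when the low-dielectric, ion-excluding cavities of the two solutes
#' approach each other.  This is the full PB interaction of a lipid
#' sphere with a fence, of which the `q phi` map term used during the
#' dynamics is the fixed-field approximation.
#'
#' @param atoms_a,atoms_b Data frames with `x`, `y`, `z`, `radius`,
#'   `charge` (membrane frame).
#' @param env A [pb_environment()].
#' @param origin,counts Fine-grid specification at
#'   `schedule$fine_spacing`.
#' @param schedule A [focusing_schedule()].
#' @param bc_atoms_a,bc_atoms_b Extended charge sets for the boundary
#'   sums (see [solve_pb()]).
#' @param stern Ion-exclusion (Stern) layer thickness, A.
#' @param tol,maxit Solver controls.
#' @return List with `interaction`, `e_complex`, `e_a`, `e_b` (kcal/mol).
#' @export
pb_interaction_energy <- function(atoms_a, atoms_b, env = pb_environment(),
                                  origin, counts,
                                  schedule = focusing_schedule(),
                                  bc_atoms_a = atoms_a,
                                  bc_atoms_b = atoms_b, stern = 0,
                                  tol = 1e-6, maxit = 10000) {
  solute_energy <- function(atoms, bc_atoms) {
    g <- solve_pb_focused(atoms, env, origin, counts, schedule,
                          bc_atoms = bc_atoms, tol = tol, maxit = maxit,
                          stern = stern)
    ch <- atoms[atoms$charge != 0, , drop = FALSE]
    hi <- origin + (as.numeric(counts) - 1) * schedule$fine_spacing
    inw <- ch$x > origin[1] & ch$x < hi[1] & ch$y > origin[2] &
      ch$y < hi[2] & ch$z > origin[3] & ch$z < hi[3]
    ch <- ch[inw, , drop = FALSE]
    phi <- trilinear_cpp(g$origin, g$spacing, as.integer(g$counts),
                         as.numeric(g$values),
                         as.matrix(ch[, c("x", "y", "z")]))
    0.5 * sum(ch$charge * phi)
  }
  e_a <- solute_energy(atoms_a, bc_atoms_a)
  e_b <- solute_energy(atoms_b, bc_atoms_b)
  e_ab <- solute_energy(rbind(atoms_a[, c("x", "y", "z", "radius", "charge")],
                              atoms_b[, c("x", "y", "z", "radius", "charge")]),
                        rbind(bc_atoms_a[, c("x", "y", "z", "radius",
                                             "charge")],
                              bc_atoms_b[, c("x", "y", "z", "radius",
                                             "charge")]))
  list(interaction = e_ab - e_a - e_b, e_complex = e_ab, e_a = e_a,
       e_b = e_b)
}

#' PB interaction barrier of a lipid sphere crossing a rod fence
#'
#' Evaluates the full PB interaction energy ([pb_interaction_energy()])
#' between a single lipid sphere on the diffusion plane and the rod, at
#' X = 0 (directly under the rod) relative to the far field, in the
#' implicit membrane-solvent environment.  A positive value is a barrier;
#' a negative value is a well of the reported depth.
#'
#' @param rod Rod data frame from [build_electrostatic_rod()]
#'   (simulation frame).
#' @param env A [pb_environment()].
#' @param test_charge,test_radius Lipid sphere parameters (defaults -4 e,
#'   5.4 A).
#' @param membrane_offset Diffusion-plane height above the phosphate
#'   plane, A.
#' @param x_far Far-field reference position, A.
#' @param x_max,y_half,z_range Solve-window geometry, A.
#' @param schedule,stern,tol,maxit Solver controls.
#' @return List with `barrier` (kcal/mol; negative = well), `e_at_rod`,
#'   `e_far`.
#' @export
rod_crossing_barrier <- function(rod, env = pb_environment(),
                                 test_charge = -4, test_radius = 5.4,
                                 membrane_offset = 5, x_far = 35,
                                 x_max = 45, y_half = 32.4,
                                 z_range = c(-20, 28),
                                 schedule = focusing_schedule(),
                                 stern = 0, tol = 1e-6, maxit = 10000) {
  atoms <- rod
  atoms$z <- atoms$z + membrane_offset
  h <- schedule$fine_spacing
  origin <- c(-x_max, -y_half, z_range[1])
  counts <- as.integer(round(c(2 * x_max, 2 * y_half,
                               diff(z_range)) / h)) + 1L
  inwin <- atoms[abs(atoms$y) <= y_half, ]
  lipid <- function(x) data.frame(x = x, y = 0, z = membrane_offset,
                                  radius = test_radius,
                                  charge = test_charge)
  e0 <- pb_interaction_energy(inwin, lipid(0), env, origin, counts,
                              schedule, bc_atoms_a = atoms, stern = stern,
                              tol = tol, maxit = maxit)
  ef <- pb_interaction_energy(inwin, lipid(x_far), env, origin, counts,
                              schedule, bc_atoms_a = atoms, stern = stern,
                              tol = tol, maxit = maxit)
  list(barrier = e0$interaction - ef$interaction,
       e_at_rod = e0$interaction, e_far = ef$interaction)
}
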