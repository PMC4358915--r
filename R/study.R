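#' Core-repulsion map for a steric rod fence
#'
#' Builds the rod and rasterizes its augmented-radius exclusion region on
#' a grid covering the simulation box (plus a small margin), in the
#' simulation frame.  Particles outside the automatically detected
#' non-zero region of the map short-circuit to zero energy and force.
#'
#' @param spec A [rod_fence_spec()].
#' @param geometry A [system_geometry()].
#' @param spacing Grid spacing, A (default 1; the study-scale maps use
#'   0.5).
#' @param z_range Grid Z extent in the simulation frame, A.
#' @param augmentation Radius augmentation, A (default 4.16).
#' @return A [grid_potential()] core map (clamped, auto bounding box).
#' @export
steric_fence_map <- function(spec, geometry, spacing = 1,
                             z_range = c(-8, 8), augmentation = 4.16) {
  rod <- build_steric_rod(spec)
  margin <- 4
  origin <- c(geometry$box_x_lo - margin, geometry$box_y_lo - margin,
              z_range[1])
  hi <- c(geometry$box_x_hi + margin, geometry$box_y_hi + margin,
          z_range[2])
  counts <- ceiling((hi - origin) / spacing) + 1
  build_core_map(rod, origin, spacing, counts,
                 augmentation = augmentation)
}

#' Electrostatic map for a charged rod fence
#'
#' Solves the linearized PB equation around the rod in the implicit
#' membrane environment on a window grid, zeroes the far field below
#' `zero_threshold` (it is screened to nothing within a few Debye
#' lengths), and returns the map shifted into the simulation frame with
#' an automatic bounding box so distant particles skip it.
#'
#' @param spec A [rod_fence_spec()] with non-zero `sphere_charge`.
#' @param geometry A [system_geometry()] (supplies the Y extent).
#' @param env A [pb_environment()].
#' @param spacing Grid spacing, A (default 1).
#' @param x_half Window half-width across the fence, A.
#' @param z_range Window Z extent in the membrane frame, A.
#' @param zero_threshold kcal/(mol e); far-field values below this are
#'   set to exactly zero.
#' @param stern,tol,maxit Solver controls (see [solve_pb()]).
#' @return A [grid_potential()] electrostatic map in the simulation
#'   frame (kcal/(mol e)).
#' @export
electrostatic_fence_map <- function(spec, geometry,
                                    env = pb_environment(), spacing = 1,
                                    x_half = 60, z_range = c(-15, 25),
                                    zero_threshold = 1e-3, stern = 0,
                                    tol = 1e-6, maxit = 10000) {
  rod <- build_electrostatic_rod(spec)
  rod$z <- rod$z + geometry$membrane_offset  # membrane frame
  margin <- 4
  origin <- c(-x_half, geometry$box_y_lo - margin, z_range[1])
  hi <- c(x_half, geometry$box_y_hi + margin, z_range[2])
  counts <- ceiling((hi - origin) / spacing) + 1
  g <- solve_pb(rod, env, origin, spacing, counts, bc_atoms = rod,
                tol = tol, maxit = maxit, stern = stern)
  v <- g$values
  v[abs(v) < zero_threshold] <- 0
  g2 <- grid_potential(g$origin, g$spacing, v, clamp = FALSE,
                       bbox = "auto")
  shift_grid_frame(g2, -geometry$membrane_offset)
}

#' Depletion relaxation fit for one fence scenario
#'
#' Convenience wrapper: run the protocol, extract the depletion series,
#' and fit the stretched exponential with `C0` fixed at the recipe
#' concentration.
#'
#' @param system A `corral_system` from [make_system()].
#' @param protocol,params See [run_protocol()].
#' @param core_grid,phix_grid Optional fence maps.
#' @param area_per_lipid A^2.
#' @return List with `series` (a `depletion_series`) and `fit` (a
#'   `stretched_exp_fit`).
#' @export
depletion_study <- function(system, protocol, params, core_grid = NULL,
                            phix_grid = NULL, area_per_lipid = 65) {
  traj <- run_protocol(system, protocol, params, core_grid = core_grid,
                       phix_grid = phix_grid)
  series <- depletion_series(traj, area_per_lipid = area_per_lipid)
  fit <- fit_stretched_exponential(
    series, c0 = system$recipe$target_corral_concentration)
  list(series = series, fit = fit)
}
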