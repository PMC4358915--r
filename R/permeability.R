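#' Phenomenological corral permeability model
#'
#' Fick's-law treatment of lipid leakage through a fence region: the
#' permeability is `P = k D / d` with partition coefficient `k`, bulk
#' diffusion coefficient `D`, and fence thickness `d`; the outward flux
#' per unit fence length is `F = P (C_i - C_o)`.  Defaults describe a
#' 1 um square corral with 100 kinases each producing 100 lipids per
#' second (production rate 1e4 molecules/(um^2 s)), `d` = 5 nm, `D` =
#' 1 um^2/s, inside concentration 1e5 um^-2 and bulk 3e4 um^-2, with one
#' leaky side.
#'
#' @param partition_coefficient Dimensionless k.
#' @param bulk_diffusion D, um^2/s.
#' @param fence_thickness d, nm (converted to um internally; the model
#'   mixes nm and um deliberately, so units are explicit here).
#' @param inside_concentration,outside_concentration C_i, C_o, um^-2.
#' @param production_rate molecules/(um^2 s).
#' @param corral_side um.
#' @param leaky_sides Number of leaky sides of the square corral.
#' @return An object of class `permeability_model`.
#' @export
permeability_model <- function(partition_coefficient = 1,
                               bulk_diffusion = 1, fence_thickness = 5,
                               inside_concentration = 1e5,
                               outside_concentration = 3e4,
                               production_rate = 1e4, corral_side = 1,
                               leaky_sides = 1) {
  stopifnot(bulk_diffusion > 0, fence_thickness > 0,
            inside_concentration > 0, outside_concentration > 0,
            production_rate > 0, corral_side > 0, leaky_sides >= 1)
  structure(list(partition_coefficient = partition_coefficient,
                 bulk_diffusion = bulk_diffusion,
                 fence_thickness = fence_thickness,
                 inside_concentration = inside_concentration,
                 outside_concentration = outside_concentration,
                 production_rate = production_rate,
                 corral_side = corral_side,
                 leaky_sides = as.integer(leaky_sides)),
            class = "permeability_model")
}

#' Fence permeability coefficient
#'
#' `P = k D / d` (d converted from nm to um): 200 k um/s at the defaults.
#'
#' @param model A [permeability_model()].
#' @return P in um/s.
#' @export
permeability_coefficient <- function(model = permeability_model()) {
  d_um <- model$fence_thickness * 1e-3
  if (d_um <= 0) stop("fence thickness must be positive")
  model$partition_coefficient * model$bulk_diffusion / d_um
}

#' Outward lipid flux per unit fence length
#'
#' `F = P (C_i - C_o)`: 1.4e7 k molecules/(um s) at the defaults.
#'
#' @param model A [permeability_model()].
#' @return F in molecules/(um s).
#' @export
outward_flux <- function(model = permeability_model()) {
  permeability_coefficient(model) *
    (model$inside_concentration - model$outside_concentration)
}

#' Critical partition coefficient for an effective fence
#'
#' The largest `k` for which the outward flux through the leaky perimeter
#' stays below the production inside the corral:
#' `k* = production_rate * side^2 / (F_per_k * leaky_sides * side)`,
#' where `F_per_k` is the flux evaluated at `k = 1`.  At the defaults this
#' is `1e4 / 1.4e7 ~ 7.14e-4`.
#'
#' @param model A [permeability_model()].
#' @return Dimensionless k*.
#' @export
critical_partition_coefficient <- function(model = permeability_model()) {
  m1 <- model
  m1$partition_coefficient <- 1
  f1 <- outward_flux(m1)
  if (f1 <= 0) stop("flux coefficient must be positive")
  model$production_rate * model$corral_side^2 /
    (f1 * model$leaky_sides * model$corral_side)
}
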