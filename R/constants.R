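#' Physical constants of the model's unit system
#'
#' The package works in an AKMA-like unit system: Angstrom, kcal/mol, amu,
#' elementary charge, and picosecond.  The Coulomb constant multiplies the
#' `q_i q_j / (eps_w r)` pair term, with a uniform pairwise dielectric of 80
#' (water) between lipid spheres.
#'
#' @return A list with elements `coulomb_constant` (332.0636
#'   kcal A / (mol e^2)), `boltzmann` (0.0019872041 kcal/mol/K),
#'   `water_dielectric_for_pairs` (80), `kcal_per_akma` (418.4, the
#'   conversion from kcal/mol to amu A^2/ps^2), and `avogadro`.
#' @export
#' @examples
#' corral_constants()$coulomb_constant
corral_constants <- function() {
  list(
    coulomb_constant = 332.0636,
    boltzmann = 0.0019872041,
    water_dielectric_for_pairs = 80,
    kcal_per_akma = 418.4,
    avogadro = 6.02214076e23
  )
}

.kB <- 0.0019872041
.ke <- 332.0636
.eps_pair <- 80
.akma <- 418.4
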