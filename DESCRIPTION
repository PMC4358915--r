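Package: corralsim
Title: Langevin Dynamics of Lipid Corralling by Membrane Diffusion Fences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates lateral diffusion of polyvalent anionic lipids
    (PIP2-like charged spheres) on a membrane plane in the presence of
    diffusion barriers: steric rods with gaps, elevated charged rods, and
    rigid protein filaments buried to a chosen depth. Provides a BAOAB
    Langevin integrator, implicit-membrane finite-difference linearized
    Poisson-Boltzmann grid potentials with B-spline interpolated forces,
    stretched-exponential relaxation analysis of corral depletion,
    potentials of mean force by Boltzmann inversion, charged-residue
    burial histograms, and a phenomenological Fick's-law treatment of
    corral permeability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
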