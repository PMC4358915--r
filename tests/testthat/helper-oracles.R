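# shared helpers: finite-difference force oracle, small fixture builders

fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h
    xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# smooth random grid for interpolation tests
smooth_grid <- function(n = 12, spacing = 1, seed = 42) {
  set.seed(seed)
  ax <- seq(0, (n - 1) * spacing, by = spacing)
  f <- function(x, y, z)
    sin(0.3 * x) * cos(0.25 * y) + 0.1 * z^2 / max(ax) + 0.05 * x * y / n
  vals <- outer(ax, ax, Vectorize(function(x, y) 0)) # placeholder
  vals <- array(0, c(n, n, n))
  for (k in seq_len(n))
    vals[, , k] <- outer(ax, ax, function(x, y) f(x, y, ax[k]))
  grid_potential(c(0, 0, 0), spacing, vals, clamp = FALSE)
}

# minimal PDB fixture with the given residues (one CA atom each)
write_fixture_pdb <- function(resids, path = tempfile(fileext = ".pdb"),
                              xyz = NULL) {
  n <- length(resids)
  if (is.null(xyz)) xyz <- cbind(seq_len(n) * 3.8, 0, 0)
  coords <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                       resid = resids, resno = seq_len(n), elety = "CA")
  write_structure(coords, path)
  path
}

# fabricate a trajectory container from a list of per-replica x matrices
fake_trajectories <- function(xs, ys = NULL, geometry,
                              times = seq_len(nrow(xs[[1]])) - 1) {
  reps <- lapply(seq_along(xs), function(i) {
    x <- xs[[i]]
    y <- if (is.null(ys)) matrix(0, nrow(x), ncol(x)) else ys[[i]]
    list(times = times, x = x, y = y, z = matrix(0, nrow(x), ncol(x)))
  })
  structure(list(times = times, replicas = reps, geometry = geometry,
                 particles = corralsim:::.particle_table(particle_spec(),
                                                        ncol(xs[[1]])),
                 seeds = seq_along(xs), scheme = "BAOAB",
                 params = integrator_params()),
            class = "corral_trajectories")
}
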