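test_that("pair interaction reproduces hand-evaluated LJ + Coulomb values", {
  p <- particle_spec()
  at_min <- pair_interaction(10.8, p, p)
  expect_equal(at_min$lj, -0.5)                       # r = r_min exactly
  expect_equal(at_min$energy, -0.5 + 332.0636 * 16 / (80 * 10.8),
               tolerance = 1e-12)
  at_2rmin <- pair_interaction(21.6, p, p)
  expect_equal(at_2rmin$lj, 0.5 * (2^-12 - 2 * 2^-6), tolerance = 1e-12)
  expect_equal(at_2rmin$coulomb, 332.0636 * 16 / (80 * 21.6),
               tolerance = 1e-12)
  expect_equal(at_2rmin$energy, 3.05916, tolerance = 1e-5)
  expect_error(pair_interaction(0), "positive")
})

test_that("pair interaction is symmetric and its force is -dU/dr", {
  p1 <- particle_spec(charge = -4)
  p2 <- particle_spec(charge = 2, lj_well_depth = 0.3, lj_rmin_half = 4)
  for (r in c(6, 9.4, 12, 30)) {
    expect_identical(pair_interaction(r, p1, p2)$energy,
                     pair_interaction(r, p2, p1)$energy)
    fd <- -(pair_interaction(r + 1e-6, p1, p2)$energy -
            pair_interaction(r - 1e-6, p1, p2)$energy) / 2e-6
    expect_equal(pair_interaction(r, p1, p2)$force, fd, tolerance = 1e-5)
  }
})

test_that("restraint energy follows the k*delta^2 convention", {
  geom <- system_geometry()
  expect_equal(restraint_energy(c(10, 20, 0), geom)$energy, 0)
  expect_equal(restraint_energy(c(10, 20, 1), geom)$energy, 0.6)
  over <- restraint_energy(c(geom$box_x_hi + 2, 0, 0), geom)
  expect_equal(over$wall, 400)
  # forces are exact negative gradients
  for (pos in list(c(5, 3, 1.2), c(930, -510, -0.4))) {
    fd <- -fd_gradient(function(x) restraint_energy(x, geom)$energy, pos)
    expect_equal(restraint_energy(pos, geom)$force, fd, tolerance = 1e-4)
  }
})

test_that("grid interpolation reproduces constants and linear fields", {
  vals <- array(3.7, c(8, 8, 8))
  g <- grid_potential(c(0, 0, 0), 1, vals, clamp = FALSE)
  r <- grid_value_and_force(c(3.3, 4.1, 2.7), g)
  expect_equal(r$value, 3.7)
  expect_equal(as.numeric(r$gradient), c(0, 0, 0))

  ax <- 0:9
  lin <- array(0, c(10, 10, 10))
  for (k in 1:10)
    lin[, , k] <- outer(ax, ax, function(x, y) 2 * x - 0.5 * y + 0.25 * (k - 1) + 1)
  gl <- grid_potential(c(0, 0, 0), 1, lin, clamp = FALSE)
  pt <- c(4.37, 5.12, 3.77)
  rl <- grid_value_and_force(pt, gl)
  expect_equal(rl$value, 2 * pt[1] - 0.5 * pt[2] + 0.25 * pt[3] + 1,
               tolerance = 1e-12)
  expect_equal(as.numeric(rl$gradient), c(2, -0.5, 0.25), tolerance = 1e-12)
})

test_that("grid gradient matches centred finite differences on a smooth field", {
  g <- smooth_grid(n = 14)
  set.seed(7)
  pts <- cbind(runif(20, 2, 11), runif(20, 2, 11), runif(20, 2, 11))
  res <- grid_value_and_force(pts, g)
  for (i in 1:20) {
    fd <- fd_gradient(function(p) grid_value_and_force(p, g)$value,
                      pts[i, ], h = 1e-5)
    expect_equal(as.numeric(res$gradient[i, ]), fd, tolerance = 1e-6)
  }
})

test_that("grid boundary policies: clamp for core maps, error for phi maps", {
  vals <- array(1, c(6, 6, 6))
  core <- grid_potential(c(0, 0, 0), 1, vals, clamp = TRUE)
  phi <- grid_potential(c(0, 0, 0), 1, vals, clamp = FALSE)
  outside <- c(-3, 2, 2)
  expect_equal(grid_value_and_force(outside, core)$value, 1)
  expect_error(grid_value_and_force(outside, phi), "outside")
})

test_that("total energy sums pair, grid, and restraint terms with exact forces", {
  geom <- system_geometry(box_x_lo = -50, box_x_hi = 50, box_y_lo = -50,
                          box_y_hi = 50)
  expect_equal(total_energy(c(0, 0, 0), geometry = geom)$breakdown$total, 0)
  two <- total_energy(rbind(c(0, 0, 0), c(0, 10.8, 0)), geometry = geom)
  expect_equal(two$breakdown$total, -0.5 + 332.0636 * 16 / (80 * 10.8),
               tolerance = 1e-10)
  # core grid plateau of 100 at an interior node
  cg <- grid_potential(c(-5, -5, -5), 1, array(100, c(11, 11, 11)),
                       clamp = TRUE)
  one <- total_energy(c(0, 0, 0), geometry = geom, core_grid = cg)
  expect_equal(one$breakdown$core_grid, 100)
  # breakdown components sum to the total
  pos <- rbind(c(-20, -15, 0.4), c(-8, -12, -0.3), c(4, 6, 0.1),
               c(16, 18, 0), c(51.5, 0, 0.2))   # last one past the x wall
  res <- total_energy(pos, geometry = geom)
  expect_equal(res$breakdown$total,
               sum(unlist(res$breakdown[setdiff(names(res$breakdown),
                                                "total")])),
               tolerance = 1e-12)
  # forces match finite differences of the total energy
  for (i in c(1, 5)) {
    fd <- -fd_gradient(function(p) {
      pos2 <- pos
      pos2[i, ] <- p
      total_energy(pos2, geometry = geom)$breakdown$total
    }, pos[i, ], h = 1e-4)
    expect_equal(as.numeric(res$forces[i, ]), fd, tolerance = 1e-5)
  }
  expect_error(total_energy(rbind(c(0, 0, 0), c(0, 0, 0)), geometry = geom),
               "overlapping")
})

test_that("OpenDX round-trip is exact", {
  g <- smooth_grid(n = 7, seed = 5)
  path <- tempfile(fileext = ".dx")
  write_dx(g, path)
  g2 <- read_dx(path, clamp = FALSE)
  expect_identical(g2$counts, g$counts)
  expect_equal(g2$origin, g$origin)
  expect_equal(g2$spacing, g$spacing)
  expect_identical(as.numeric(g2$values), as.numeric(g$values))
})

test_that("configuration files round-trip model objects", {
  cfg <- list(charge = -4, lj_rmin_half = 5.4, box_x_lo = -475,
              box_x_hi = 925, friction = 1, timestep = 0.005)
  path <- tempfile(fileext = ".cfg")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$charge, -4)
  expect_equal(back$box_x_lo, -475)
  objs <- system_from_config(back)
  expect_s3_class(objs$particles, "particle_spec")
  expect_equal(objs$geometry$box_x_hi, 925)
  expect_equal(objs$params$timestep, 0.005)
})
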