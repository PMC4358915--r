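# closed-form oracles for the PB solver use small grids; the full-size
# rod solves live in the acceptance suite

uniform_env <- function(salt = 0)
  pb_environment(salt_concentration = salt, membrane_dielectric = 80,
                 solute_dielectric = 80, membrane_top_z = -1e6)

test_that("core map equals the brute-force point-in-union-of-spheres indicator", {
  expect_true(all(build_core_map(data.frame(x = numeric(0), y = numeric(0),
                                            z = numeric(0),
                                            radius = numeric(0)),
                                 c(0, 0, 0), 1, c(5, 5, 5))$values == 0))
  set.seed(4)
  atoms <- data.frame(x = runif(3, 2, 10), y = runif(3, 2, 10),
                      z = runif(3, 2, 10), radius = runif(3, 1, 2.5))
  aug <- 4.16
  g <- build_core_map(atoms, c(0, 0, 0), 1, c(13, 13, 13),
                      augmentation = aug)
  ax <- grid_axes(g)
  brute <- array(0, dim = g$counts)
  for (a in seq_len(nrow(atoms))) {
    for (i in 1:13) for (j in 1:13) for (k in 1:13) {
      d2 <- (ax$x[i] - atoms$x[a])^2 + (ax$y[j] - atoms$y[a])^2 +
        (ax$z[k] - atoms$z[a])^2
      if (d2 <= (atoms$radius[a] + aug)^2) brute[i, j, k] <- 100
    }
  }
  expect_identical(as.numeric(g$values), as.numeric(brute))
  expect_true(all(g$values %in% c(0, 100)))  # union, no double counting
})

test_that("PB solution is linear in the source charges", {
  at1 <- data.frame(x = 0, y = 0, z = 0, radius = 2, charge = 1)
  at2 <- at1
  at2$charge <- 2
  gr <- function(a) solve_pb(a, uniform_env(150), c(-16, -16, -16), 1,
                             c(33, 33, 33), tol = 1e-12, maxit = 5e4)
  g1 <- gr(at1)
  g2 <- gr(at2)
  expect_lt(max(abs(g2$values - 2 * g1$values)) / max(abs(g2$values)),
            1e-8)
})

test_that("superposition: the field of two distant charges is the sum", {
  a <- data.frame(x = -8, y = 0, z = 0, radius = 1.5, charge = 1)
  b <- data.frame(x = 8, y = 3, z = 2, radius = 1.5, charge = -2)
  gr <- function(at) solve_pb(at, uniform_env(150), c(-20, -20, -20), 1,
                              c(41, 41, 41), tol = 1e-10, maxit = 5e4)
  gab <- gr(rbind(a, b))
  gsum <- gr(a)$values + gr(b)$values
  # exact up to the iterative convergence tolerance
  expect_lt(max(abs(gab$values - gsum)) / max(abs(gab$values)), 1e-4)
})

test_that("solver matches the Coulomb and Debye-Hueckel closed forms", {
  at <- data.frame(x = 0, y = 0, z = 0, radius = 0, charge = 1)
  pts <- rbind(c(4, 0, 0), c(0, 6, 0), c(5, 5, 0), c(0, 0, 8),
               c(7, 4, 3), c(10, 0, 0), c(0, 12, 0))
  r <- sqrt(rowSums(pts^2))

  g0 <- solve_pb(at, uniform_env(0), c(-32, -32, -32), 1, c(65, 65, 65))
  expect_lt(max(abs(grid_value_and_force(pts, g0)$value /
                      (332.0636 / (80 * r)) - 1)), 0.02)

  env1 <- uniform_env(150)
  kap <- debye_parameters(env1)$kappa
  expect_equal(debye_parameters(env1)$length, 7.95, tolerance = 0.01)
  g1 <- solve_pb(at, env1, c(-32, -32, -32), 1, c(65, 65, 65))
  expect_lt(max(abs(grid_value_and_force(pts, g1)$value /
                      (332.0636 * exp(-kap * r) / (80 * r)) - 1)), 0.03)
})

test_that("solver matches the image-charge form for a low-dielectric half-space", {
  q <- 1
  zq <- 8
  alpha <- (80 - 2) / (80 + 2)
  image_phi <- function(p) {
    r <- sqrt(p[, 1]^2 + p[, 2]^2 + (p[, 3] - zq)^2)
    ri <- sqrt(p[, 1]^2 + p[, 2]^2 + (p[, 3] + zq)^2)
    332.0636 / 80 * (q / r + alpha * q / ri)
  }
  env <- pb_environment(salt_concentration = 0, membrane_dielectric = 2,
                        solute_dielectric = 80, membrane_thickness = 500,
                        membrane_top_z = 0)
  at <- data.frame(x = 0, y = 0, z = zq, radius = 0, charge = q)
  g <- solve_pb(at, env, c(-25, -25, -17), 1, c(51, 51, 51),
                bc = image_phi)
  pts <- rbind(c(5, 0, 8), c(0, 6, 10), c(8, 0, 4), c(0, 0, 16),
               c(10, 5, 8), c(6, 6, 2))
  expect_lt(max(abs(grid_value_and_force(pts, g)$value /
                      image_phi(pts) - 1)), 0.03)
})

test_that("focused solve agrees with an unfocused fine solve", {
  at <- data.frame(x = 0, y = 0, z = 2, radius = 2, charge = -1)
  env <- uniform_env(150)   # exact boundary values on both routes
  origin <- c(-12, -12, -8)
  counts <- c(49, 49, 41)
  sched <- focusing_schedule(coarse_spacing = 1, fine_spacing = 0.5,
                             pad = 16)
  foc <- solve_pb_focused(at, env, origin, counts, sched)
  direct <- solve_pb(at, env, origin, 0.5, counts)
  pts <- rbind(c(3, 0, 2), c(0, 4, 4), c(-5, 2, 0), c(2, 2, 6))
  vf <- grid_value_and_force(pts, foc)$value
  vd <- grid_value_and_force(pts, direct)$value
  expect_lt(max(abs(vf / vd - 1)), 0.01)
})

test_that("rod interaction profiles: zero charge gives zero, fields are symmetric", {
  spec0 <- rod_fence_spec(fence_length = 300, opening_length = 0,
                          sphere_charge = 0, height = 5)
  sched1 <- focusing_schedule(coarse_spacing = 1, fine_spacing = 1,
                              pad = 16)
  p0 <- rod_interaction_profile(build_electrostatic_rod(spec0),
                                x_max = 30, y_half = 21.6,
                                z_range = c(-12, 20), schedule = sched1)
  expect_true(all(p0$energy == 0))

  spec <- rod_fence_spec(fence_length = 300, opening_length = 0,
                         sphere_charge = -0.5, height = 5)
  p <- rod_interaction_profile(build_electrostatic_rod(spec),
                               x_max = 30, y_half = 21.6,
                               z_range = c(-12, 20), schedule = sched1)
  mirrored <- p$energy[match(-p$x, p$x)]
  expect_equal(p$energy, mirrored, tolerance = 1e-6)
  expect_gt(attr(p, "barrier"), 0)   # repulsive for like charges
})

test_that("potential slices detect crossing channels by flood fill", {
  # empty maps: everything open
  zg <- grid_potential(c(-10, -10, -3), 1, array(0, c(21, 21, 7)),
                       clamp = TRUE)
  s0 <- potential_map_slice(core_grid = zg, z = 0)
  expect_true(s0$channel)
  expect_true(all(s0$values == 0))

  # unbroken rod blocks every crossing channel
  full <- build_steric_rod(rod_fence_spec(fence_length = 200,
                                          opening_length = 0))
  gfull <- build_core_map(full, c(-20, -60, -4), 1, c(41, 121, 9))
  expect_false(potential_map_slice(core_grid = gfull, z = 0)$channel)

  # a 20 A gap reopens it
  gap <- build_steric_rod(rod_fence_spec(fence_length = 200,
                                         opening_length = 20))
  ggap <- build_core_map(gap, c(-20, -60, -4), 1, c(41, 121, 9))
  expect_true(potential_map_slice(core_grid = ggap, z = 0)$channel)
})
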