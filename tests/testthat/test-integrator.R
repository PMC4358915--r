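big_box <- system_geometry(box_x_lo = -1e6, box_x_hi = 1e6,
                           box_y_lo = -1e6, box_y_hi = 1e6,
                           corral_boundary_x = 0)

test_that("with zero friction, temperature and force the motion is uniform", {
  pars <- integrator_params(friction = 0, temperature = 0,
                            timestep = 0.005)
  pos <- matrix(c(0, 0, 0), 1, 3)
  vel <- matrix(c(3, -2, 0), 1, 3)
  run <- ld_run(pos, vel, particle_spec(), big_box, pars, n_steps = 100,
                snapshot_every = 100, include_pairs = FALSE)
  expect_equal(as.numeric(run$final_pos),
               c(3, -2, 0) * 0.5, tolerance = 1e-12)
  expect_equal(as.numeric(run$final_vel), c(3, -2, 0), tolerance = 1e-12)
})

test_that("identical seeds give bitwise-identical trajectories", {
  rec <- system_recipe("steric_rod", scale_factor = 0.1, seed = 5)
  sys <- make_system(rec)
  prot <- simulation_protocol(equilibration_time = 10,
                              production_time = 50, n_replicas = 2,
                              snapshot_interval = 5)
  pars <- integrator_params(friction = 1, timestep = 0.01, seed = 99)
  t1 <- run_protocol(sys, prot, pars)
  t2 <- run_protocol(sys, prot, pars)
  expect_identical(t1$replicas[[1]]$x, t2$replicas[[1]]$x)
  expect_identical(t1$replicas[[2]]$z, t2$replicas[[2]]$z)
  # distinct replicas are different
  expect_false(identical(t1$replicas[[1]]$x, t1$replicas[[2]]$x))
})

test_that("microcanonical limit conserves energy and matches velocity Verlet", {
  set.seed(13)
  pos <- cbind(runif(4, -20, 20), runif(4, -20, 20), runif(4, -1, 1))
  vel <- maxwell_velocities(4, 1043, 300)
  geom <- system_geometry(box_x_lo = -30, box_x_hi = 30, box_y_lo = -30,
                          box_y_hi = 30)
  pars <- integrator_params(friction = 0, temperature = 0,
                            timestep = 0.002)
  run <- ld_run(pos, vel, particle_spec(), geom, pars, n_steps = 1e5,
                snapshot_every = 5000, include_pairs = FALSE,
                record_velocities = TRUE)
  etot <- vapply(seq_len(nrow(run$x)), function(f) {
    p <- cbind(run$x[f, ], run$y[f, ], run$z[f, ])
    pe <- total_energy(p, geometry = geom,
                       include_pairs = FALSE)$breakdown$total
    ke <- sum(1043 * (run$vx[f, ]^2 + run$vy[f, ]^2 + run$vz[f, ]^2)) /
      (2 * 418.4)
    pe + ke
  }, numeric(1))
  expect_lt(diff(range(etot)) / abs(mean(etot)), 1e-4)
})

test_that("the thermostat samples the target temperature and equipartition", {
  set.seed(21)
  n <- 150
  pos <- matrix(0, n, 3)
  vel <- maxwell_velocities(n, 1043, 300)
  pars <- integrator_params(friction = 1, temperature = 300,
                            timestep = 0.005)
  run <- ld_run(pos, vel, particle_spec(), big_box, pars, n_steps = 3e4,
                snapshot_every = 100, include_pairs = FALSE,
                record_velocities = TRUE)
  temp <- kinetic_temperature(run)
  expect_lt(abs(temp - 300), 6)
  # planar restraint: var(z) = kB T / (2 k_plane)
  burn <- run$z[-(1:50), ]
  expect_equal(mean(burn^2), 0.0019872041 * 300 / (2 * 0.6),
               tolerance = 0.05)
  # zero velocities give 0 K
  run0 <- list(times = 0:1, vx = matrix(0, 2, 3), vy = matrix(0, 2, 3),
               vz = matrix(0, 2, 3))
  expect_equal(kinetic_temperature(run0), 0)
})

test_that("free in-plane MSD gives D = kBT/(m gamma)", {
  set.seed(31)
  n <- 400
  pars <- integrator_params(friction = 1, temperature = 300,
                            timestep = 0.005)
  run <- ld_run(matrix(0, n, 3), maxwell_velocities(n, 1043, 300),
                particle_spec(), big_box, pars, n_steps = 4e4,
                snapshot_every = 100, include_pairs = FALSE)
  d <- msd_diffusion(run, window = c(20, 150), friction = 1)
  d_theory <- 0.0019872041 * 300 * 418.4 / 1043 * 1e-4
  expect_lt(abs(d / d_theory - 1), 0.08)
  # halving the friction doubles the theoretical D
  expect_equal((0.0019872041 * 300 * 418.4 / (1043 * 0.5)) /
                 (0.0019872041 * 300 * 418.4 / 1043), 2)
})

test_that("protocol equilibration confines to the corral; zero production keeps one frame", {
  rec <- system_recipe("steric_rod", scale_factor = 0.12, seed = 3)
  sys <- make_system(rec)
  prot <- simulation_protocol(equilibration_time = 200,
                              production_time = 0, n_replicas = 1,
                              snapshot_interval = 10)
  pars <- integrator_params(friction = 0.1, timestep = 0.01, seed = 4)
  tr <- run_protocol(sys, prot, pars)
  expect_equal(nrow(tr$replicas[[1]]$x), 1)
  # soft one-sided wall: essentially no particle past the boundary
  expect_lt(max(tr$replicas[[1]]$x), sys$geometry$corral_boundary_x + 0.5)
})

test_that("trajectories can be written to columnar files", {
  rec <- system_recipe("steric_rod", scale_factor = 0.1, seed = 8)
  sys <- make_system(rec)
  prot <- simulation_protocol(equilibration_time = 0, production_time = 20,
                              n_replicas = 1, snapshot_interval = 10)
  tr <- run_protocol(sys, prot, integrator_params(timestep = 0.01, seed = 1))
  dir <- tempfile()
  write_trajectories(tr, dir)
  expect_true(file.exists(file.path(dir, "replica_001.csv.gz")))
  df <- read.table(gzfile(file.path(dir, "replica_001.csv.gz")),
                   header = TRUE, sep = ",")
  expect_equal(sort(unique(df$time)), tr$times)
  expect_equal(nrow(df), length(tr$times) * ncol(tr$replicas[[1]]$x))
})
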