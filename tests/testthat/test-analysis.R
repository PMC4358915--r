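test_that("depletion counting reproduces the 6% / 2% / 0% conversions", {
  rec <- system_recipe("steric_rod")
  geom <- system_geometry(box_x_lo = rec$box_x_lo, box_x_hi = rec$box_x_hi,
                          box_y_lo = -rec$y_width / 2,
                          box_y_hi = rec$y_width / 2)
  n <- recipe_particle_count(rec)   # 438
  inside <- matrix(runif(n, -475, -1), 1, n)
  tr <- fake_trajectories(list(inside), geometry = geom)
  s <- depletion_series(tr)
  expect_equal(s$mean, 6, tolerance = 0.01)
  expect_equal(s$c0, s$mean)

  # uniform over the whole box: about 2%
  set.seed(2)
  unif <- matrix(runif(5 * n, -475, 925), 5, n)
  su <- depletion_series(fake_trajectories(list(unif), geometry = geom))
  expect_equal(mean(su$mean), 6 * 475 / 1400, tolerance = 0.15)

  # empty pool and particle-number conservation
  outside <- matrix(runif(n, 1, 900), 1, n)
  so <- depletion_series(fake_trajectories(list(outside), geometry = geom))
  expect_equal(so$mean, 0)
  pool_counts <- s$per_replica * s$corral_area / (100 * s$area_per_lipid)
  expect_equal(as.numeric(pool_counts), n)
})

test_that("stretched-exponential fits recover generating parameters", {
  # pure exponential, noiseless: <= 0.1%
  s1 <- make_decay_curve(c0 = 6, c_inf = 2, tau = 1e3, beta = 1,
                         noise_sd = 0, n_points = 300, t_max = 8e3)
  f1 <- fit_stretched_exponential(s1)
  expect_true(f1$converged && !f1$blockade)
  expect_equal(f1$tau, 1e3, tolerance = 1e-3)
  expect_equal(f1$beta, 1, tolerance = 1e-3)
  expect_equal(f1$c_inf, 2, tolerance = 1e-3)

  # stretched, noiseless: <= 0.5%
  s2 <- make_decay_curve(c0 = 6, c_inf = 2, tau = 5e3, beta = 0.6,
                         noise_sd = 0, n_points = 400, t_max = 5e4)
  f2 <- fit_stretched_exponential(s2)
  expect_equal(f2$tau, 5e3, tolerance = 5e-3)
  expect_equal(f2$beta, 0.6, tolerance = 5e-3)
  expect_equal(f2$c_inf, 2, tolerance = 5e-3)
})

test_that("noisy fits land inside bootstrap confidence intervals", {
  set.seed(77)
  s <- make_decay_curve(c0 = 6, c_inf = 2, tau = 5e3, beta = 0.6,
                        noise_sd = 0.06, n_points = 250, t_max = 5e4,
                        n_replicas = 20)
  f <- fit_stretched_exponential(s)
  boots <- replicate(60, {
    idx <- sample(s$n_replicas, replace = TRUE)
    sb <- s
    sb$mean <- rowMeans(s$per_replica[, idx, drop = FALSE])
    fb <- fit_stretched_exponential(sb)
    c(fb$tau, fb$beta, fb$c_inf)
  })
  ci <- apply(boots, 1, sd)
  expect_lt(abs(f$tau - 5e3), 3 * ci[1] + 1e-9)
  expect_lt(abs(f$beta - 0.6), 3 * ci[2] + 1e-9)
  expect_lt(abs(f$c_inf - 2), 3 * ci[3] + 1e-9)
})

test_that("mean relaxation time follows the gamma-function identities", {
  expect_equal(mean_relaxation_time(1234, 1), 1234)
  expect_equal(mean_relaxation_time(10, 0.5), 20)
  expect_equal(mean_relaxation_time(1, 2), sqrt(pi) / 2)
  expect_error(mean_relaxation_time(10, 0), "positive")
  expect_error(mean_relaxation_time(0, 1), "positive")
})

test_that("relaxation ratios: identity, blockade, and factor-of-6 retardation", {
  s_free <- make_decay_curve(tau = 1e3, beta = 0.8, t_max = 1e4,
                             n_points = 200)
  f_free <- fit_stretched_exponential(s_free)
  expect_equal(relaxation_ratio(f_free, f_free), 1)

  # a fence retarding relaxation 6-fold gives xi = 1/6
  s_slow <- make_decay_curve(tau = 6e3, beta = 0.8, t_max = 6e4,
                             n_points = 200)
  f_slow <- fit_stretched_exponential(s_slow)
  expect_equal(relaxation_ratio(f_slow, f_free), 1 / 6, tolerance = 0.01)

  # non-decaying pool: blockade flag and xi = 0
  flat <- make_decay_curve(c0 = 6, c_inf = 6, tau = 1e3, beta = 1,
                           t_max = 1e4, n_points = 100)
  f_flat <- fit_stretched_exponential(flat)
  expect_true(f_flat$blockade)
  expect_equal(relaxation_ratio(f_flat, f_free), 0)
})

test_that("PMF inversion: uniform occupancy gives W = 0 at the reference", {
  rec <- system_recipe("steric_rod", scale_factor = 0.5)
  geom <- system_geometry(box_x_lo = rec$box_x_lo, box_x_hi = rec$box_x_hi,
                          box_y_lo = -rec$y_width / 2,
                          box_y_hi = rec$y_width / 2)
  set.seed(5)
  # uniform 2% occupancy over the whole accessible region
  n <- round(2 / 100 * (rec$box_x_hi - rec$box_x_lo) * rec$y_width / 65)
  xs <- lapply(1:4, function(i)
    matrix(runif(40 * n, rec$box_x_lo, rec$box_x_hi), 40, n))
  tr <- fake_trajectories(xs, geometry = geom, times = 1:40)
  pm <- pmf_1d(tr, bin_width = 25, c_ref = 2, burn_in = 0)
  expect_lt(max(abs(pm$w)), 0.12)   # ~kT/5 statistical ripple
  expect_false(any(pm$empty))

  # a bin at concentration c_ref/e sits one kB T up the profile
  expect_equal(-0.0019872041 * 300 * log((2 / exp(1)) / 2),
               0.0019872041 * 300)
})

test_that("MSD of static particles is zero and short windows error", {
  still <- list(times = seq(0, 100, 10),
                x = matrix(3, 11, 5), y = matrix(-2, 11, 5),
                z = matrix(0, 11, 5))
  expect_equal(as.numeric(msd_diffusion(still, window = c(10, 100),
                                        friction = 1)), 0)
  expect_error(msd_diffusion(still, window = c(10, 50), friction = 0.1),
               "10/friction")
})

test_that("burial histograms count charged residues inside the hydrophobic region", {
  fil <- make_pseudo_filament(pseudo_filament_spec())
  none <- burial_histogram(fil, z_min = 10)
  expect_equal(attr(none, "total"), 0)

  # a single LYS 3 A below the boundary falls in the third 1 A bin
  one <- data.frame(x = 0, y = 0, z = -8, radius = 3.4, charge = 1,
                    resid = "LYS", resno = 1, elety = "CA")
  h <- burial_histogram(one, hydrophobic_boundary = -5)
  expect_equal(attr(h, "total"), 1)
  expect_equal(h$count[h$z_lo <= -8 & h$z_hi > -8], 1)

  # raising Z_min (less buried) never increases the total count
  totals <- vapply(c(-15, -10, -5, 0), function(zm)
    attr(burial_histogram(fil, z_min = zm), "total"), numeric(1))
  expect_true(all(diff(totals) <= 0))
  expect_error(burial_histogram(data.frame(z = 1)), "labels")
})
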