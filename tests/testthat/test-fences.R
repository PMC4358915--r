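test_that("steric rod geometry: gap placement, counts, and blocked length", {
  empty <- build_steric_rod(rod_fence_spec(fence_length = 1000,
                                           opening_length = 1000))
  expect_equal(nrow(empty), 0)

  full <- build_steric_rod(rod_fence_spec(fence_length = 1000,
                                          opening_length = 0))
  expect_equal(nrow(full), ceiling(1000 / 10.8))  # 93 contact spheres
  expect_true(all(full$charge == 0) && all(full$z == 0) &&
                all(full$x == 0))
  expect_lt(max(diff(sort(full$y))), 10.8 + 1e-9)

  half <- build_steric_rod(rod_fence_spec(fence_length = 1000,
                                          opening_length = 500))
  expect_true(all(abs(half$y) > 250 & abs(half$y) < 500))
  # blocked length + opening = fence length
  expect_equal(1000 - 500, 2 * 250)
  expect_error(rod_fence_spec(fence_length = 100, opening_length = 200),
               "exceed")
})

test_that("electrostatic rods are unbroken, elevated, charged rows", {
  spec <- rod_fence_spec(fence_length = 450, opening_length = 0,
                         sphere_charge = -0.5, height = 7)
  rod <- build_electrostatic_rod(spec)
  expect_true(all(rod$z == 7))
  expect_true(all(rod$charge == -0.5))
  expect_equal(nrow(rod), ceiling(450 / 10.8))
  expect_error(build_electrostatic_rod(
    rod_fence_spec(opening_length = 100, sphere_charge = 1)), "opening")
  expect_error(build_steric_rod(spec), "uncharged")
})

test_that("filament replication is a rigid helical transform", {
  set.seed(9)
  mono <- data.frame(x = runif(8, -5, 5), y = runif(8, 0, 20),
                     z = runif(8, 0, 10))
  one <- replicate_filament(mono, 1, rotation = 166.4, translation = 27.6)
  expect_equal(one$x, mono$x)
  expect_equal(one$y, mono$y)

  fil <- replicate_filament(mono, 13, rotation = 166.4, translation = 27.6)
  expect_equal(nrow(fil), 13 * 8)
  last <- fil[fil$subunit == 13, ]
  expect_equal(last$y - mono$y, rep(12 * 27.6, 8))
  # rigidity: internal distances preserved to 1e-10
  d0 <- dist(mono[, c("x", "y", "z")])
  for (s in c(2, 7, 13)) {
    ds <- dist(fil[fil$subunit == s, c("x", "y", "z")])
    expect_equal(as.numeric(ds), as.numeric(d0), tolerance = 1e-10)
  }
  # replication commutes with rigid translation along the axis
  mono_t <- mono
  mono_t$y <- mono$y + 11
  fil_t <- replicate_filament(mono_t, 5, rotation = 166.4,
                              translation = 27.6)
  fil_then <- replicate_filament(mono, 5, rotation = 166.4,
                                 translation = 27.6)
  fil_then$y <- fil_then$y + 11
  expect_equal(fil_t$x, fil_then$x, tolerance = 1e-12)
  expect_equal(fil_t$y, fil_then$y, tolerance = 1e-12)
  expect_equal(fil_t$z, fil_then$z, tolerance = 1e-12)
})

test_that("burial translates to the requested minimum Z and is idempotent", {
  coords <- data.frame(x = 1:4, y = 1:4, z = c(3, 5, 9, 12))
  b0 <- bury_filament(coords, 0)
  expect_equal(min(b0$z), 0)
  b9 <- bury_filament(coords, -9)
  expect_equal(b9$z, coords$z - 12)   # lowest atom at +3 -> shift -12
  expect_equal(bury_filament(b9, -9), b9)
  expect_equal(coords$x, b9$x)
})

test_that("structures load with formal charges and round-trip coordinates", {
  p1 <- write_fixture_pdb(c("LYS"))
  s1 <- load_structure(p1)
  expect_equal(sum(s1$charge), 1)

  p2 <- write_fixture_pdb(c("ASP", "ASP", "ARG"))
  s2 <- load_structure(p2)
  expect_equal(sum(s2$charge), -1)

  bad <- write_fixture_pdb(c("LYS", "XXX"))
  expect_error(load_structure(bad), "XXX")

  set.seed(12)
  xyz <- matrix(round(runif(9, -40, 40), 3), 3, 3)
  p3 <- write_fixture_pdb(c("GLY", "PHE", "GLU"), xyz = xyz)
  s3 <- load_structure(p3)
  expect_equal(cbind(s3$x, s3$y, s3$z), xyz, tolerance = 1e-3,
               ignore_attr = TRUE)
})
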