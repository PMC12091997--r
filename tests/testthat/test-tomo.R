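test_that("measure_lengths is exact on an analytic sphere and rigid-invariant", {
  m <- membrane_sphere(c(0, 0, 0), 150)
  f <- conformer_field(matrix(c(178, 0, 0), 1), m)
  ld <- measure_lengths(f)
  expect_equal(ld$lengths_A, 280)

  mc <- gen_minicell_field(n_conformers = 500, length_noise_sd = 0, seed = 2)
  ld0 <- measure_lengths(mc$field)
  expect_equal(ld0$lengths_A, rep(280, 500), tolerance = 1e-9)

  # rigid-body transform of apexes and center together leaves lengths unchanged
  shift <- c(40, -25, 60)
  f2 <- conformer_field(sweep(mc$field$apex_points, 2, shift, "+"),
                        membrane_sphere(shift, 150))
  expect_equal(measure_lengths(f2)$lengths_A, ld0$lengths_A, tolerance = 1e-9)
})

test_that("point-cloud membranes agree with the analytic sphere within sampling", {
  set.seed(6)
  n <- 20000
  z <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi); s <- sqrt(1 - z^2)
  cloud <- membrane_cloud(150 * cbind(s * cos(phi), s * sin(phi), z))
  mc <- gen_minicell_field(n_conformers = 300, seed = 3)
  d_sphere <- measure_lengths(mc$field)$lengths_A
  d_cloud <- measure_lengths(conformer_field(mc$field$apex_points, cloud))$lengths_A
  # mean spacing between 2e4 points on this sphere is ~4 nm
  spacing_A <- 10 * sqrt(4 * pi * 150^2 / n)
  expect_lt(max(abs(d_cloud - d_sphere)), 2 * spacing_A)
})

test_that("apexes inside the sphere warn and use the absolute distance", {
  m <- membrane_sphere(c(0, 0, 0), 150)
  f <- conformer_field(matrix(c(100, 0, 0), 1), m)
  expect_warning(ld <- measure_lengths(f), "inside")
  expect_equal(ld$lengths_A, 500)
})

test_that("enumerate_density arithmetic on fixed segments", {
  m <- membrane_sphere(c(0, 0, 0), 100)
  apex <- matrix(rep(c(110, 0, 0), 100), ncol = 3, byrow = TRUE)
  f <- conformer_field(apex, m, segment_labels = rep(1L, 100))
  e <- enumerate_density(f, segment_areas = 1e4, cell_area = 1e5)
  expect_equal(e$count, 1000)

  # two segments with densities d and 3d: mean 2d, sd d*sqrt(2)
  f2 <- conformer_field(rbind(apex, apex[1:30, ]), m,
                        segment_labels = c(rep(1L, 100), rep(2L, 30)))
  e2 <- enumerate_density(f2, segment_areas = c(1e4, 1e3), cell_area = 1e5)
  d <- 100 / 1e4
  expect_equal(e2$mean_density, 2 * d)
  expect_equal(e2$density_sd, d * sqrt(2), tolerance = 1e-12)
  expect_error(enumerate_density(f2, segment_areas = c(1e4, 0)), "positive")
})

test_that("enumerate_density recovers a uniformly placed truth, unbiased over repeats", {
  mc <- gen_minicell_field(seed = 11)
  e <- enumerate_density(mc$field, mc$segment_areas)
  expect_lt(abs(e$count - 11760), 3 * max(e$sd, 1))

  est <- vapply(1:100, function(s) {
    g <- gen_minicell_field(n_conformers = 2000, n_segments = 10, seed = s)
    enumerate_density(g$field, g$segment_areas)$count
  }, numeric(1))
  expect_lt(abs(mean(est) - 2000) / 2000, 0.01)
})

test_that("feasibility stacks closed conformers by integer ceiling", {
  r <- feasibility(26, 12.89, 27.8, tolerance = 2)
  expect_identical(r$stacked_closed_count, 3L)
  expect_true(r$open_consistent)
  expect_identical(feasibility(25, 12.89, 27.8)$stacked_closed_count, 2L)
  expect_identical(feasibility(12.89, 12.89, 27.8)$stacked_closed_count, 1L)
  expect_false(feasibility(26, 12.89, 35, tolerance = 2)$open_consistent)
  # property: exact integer ceiling over random inputs
  set.seed(23)
  for (i in 1:100) {
    th <- runif(1, 1, 60); cl <- runif(1, 1, 30)
    expect_identical(feasibility(th, cl, 28)$stacked_closed_count,
                     as.integer(ceiling(th / cl)))
  }
})

test_that("fsc is 1 for identical volumes and ~0 for independent noise", {
  set.seed(41)
  v <- array(rnorm(32^3), dim = rep(32, 3))
  f <- fsc(v, v, voxel_size = 2)
  expect_true(all(abs(f$curve$fsc[-1] - 1) < 1e-8))
  expect_false(f$crossed)
  expect_equal(f$resolution_A, 4)   # Nyquist for 2 A voxels

  w <- array(rnorm(32^3), dim = rep(32, 3))
  f2 <- fsc(v, w, voxel_size = 2)
  expect_true(all(abs(f2$curve$fsc[f2$curve$shell > 4]) < 0.1))
})

test_that("fsc is symmetric, scale-invariant and errors on shape mismatch", {
  hm <- gen_halfmaps(n = 32, seed = 51)
  a <- fsc(hm$vol1, hm$vol2, hm$voxel_size)
  b <- fsc(hm$vol2, hm$vol1, hm$voxel_size)
  expect_equal(a$curve$fsc, b$curve$fsc, tolerance = 1e-12)
  c_ <- fsc(hm$vol1 * 7.3, hm$vol2, hm$voxel_size)
  expect_equal(a$curve$fsc, c_$curve$fsc, tolerance = 1e-9)
  bad <- array(0, dim = c(16, 16, 16))
  expect_error(fsc(hm$vol1, bad, 2.5))
})

test_that("fsc reports a 20 A crossing for a 20 A band-limited shared signal", {
  hm <- gen_halfmaps(signal_resolution = 20, n = 64, voxel_size = 2.5, seed = 101)
  f <- fsc(hm$vol1, hm$vol2, hm$voxel_size)
  expect_true(f$crossed)
  expect_lt(abs(f$resolution_A - 20) / 20, 0.15)
})
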