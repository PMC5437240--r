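test_that("trapezoidal TI is exact on constant and linear integrands", {
  s <- tibble::tibble(lambda = c(0, 0.25, 0.6, 1), dudl_mean = rep(3.7, 4))
  expect_equal(ti_integrate(s)$dg, 3.7)
  s2 <- tibble::tibble(lambda = c(0, 0.5, 1), dudl_mean = 2 * c(0, 0.5, 1))
  expect_equal(ti_integrate(s2)$dg, 1.0)
})

test_that("TI recovers the generator's analytic integral on a 21-point grid", {
  gen <- make_ti_series(a = -4.49, b = 1.3, c = 0.8, n_lambda = 21)
  res <- ti_integrate(gen$series)
  expect_lt(abs(res$dg - gen$dg_analytic), 0.01)
})

test_that("TI propagates per-point SEMs through the quadrature weights", {
  s <- tibble::tibble(lambda = c(0, 0.5, 1), dudl_mean = c(1, 2, 3),
                      dudl_sem = c(0.1, 0.2, 0.1))
  w <- c(0.25, 0.5, 0.25)  # trapezoid weights on this grid
  expect_equal(ti_integrate(s)$dg_se, sqrt(sum((w * c(0.1, 0.2, 0.1))^2)))
})

test_that("TI input validation catches bad series", {
  expect_error(ti_integrate(tibble::tibble(lambda = 0.5, dudl_mean = 1)),
               "two lambda")
  expect_error(ti_integrate(tibble::tibble(lambda = c(0, 0, 1),
                                           dudl_mean = 1:3)), "increasing")
  expect_warning(ti_integrate(tibble::tibble(lambda = c(0.1, 0.9),
                                             dudl_mean = c(1, 1))),
                 "endpoints")
})

test_that("well depth measures the bound minimum against the plateau", {
  prof <- tibble::tibble(bin_center = seq(-2, 10, by = 0.5))
  prof$free_energy <- ifelse(abs(prof$bin_center) < 2,
                             -1.83 * (1 - (prof$bin_center / 2)^2), 0)
  expect_equal(well_depth(prof, c(-1, 1), c(5, 10)), -1.83)
  flat <- tibble::tibble(bin_center = 1:10, free_energy = 0)
  expect_equal(well_depth(flat, c(1, 3), c(8, 10)), 0)
  shifted <- dplyr::mutate(prof, free_energy = free_energy + 5)
  expect_equal(well_depth(shifted, c(-1, 1), c(5, 10)), -1.83)
  expect_error(well_depth(prof, c(100, 200), c(5, 10)), "bound_range")
})

test_that("symmetry correction defaults to -RT ln n with verbatim override", {
  expect_equal(symmetry_correction(1), 0)
  expect_equal(symmetry_correction(3, 300), -0.59616 * log(3), tolerance = 1e-6)
  expect_equal(symmetry_correction(3, 300), -0.655, tolerance = 1e-3)
  expect_equal(symmetry_correction(3, override = -0.36), -0.36)
  expect_error(symmetry_correction(0), "n_sites")
})

test_that("volume correction references the 1 M standard state", {
  expect_equal(volume_correction(1660.539, 300), 0)
  expect_equal(volume_correction(164.1, 300), 1.38, tolerance = 0.005)
  expect_equal(volume_correction(1660.539 / 2, 300), 0.59616 * log(2),
               tolerance = 1e-6)
  expect_error(volume_correction(-5), "positive")
})

test_that("the Gaussian volume estimator matches its closed form", {
  iso <- sample_bound_positions(diag(3), n = 1e5, seed = 1)
  expect_equal(bound_volume(iso$positions), (2 * pi * exp(1))^1.5,
               tolerance = 0.02)
  scaled <- dplyr::mutate(iso$positions, x = 2 * x, y = 2 * y, z = 2 * z)
  expect_equal(bound_volume(scaled) / bound_volume(iso$positions), 8,
               tolerance = 1e-6)
  aniso <- sample_bound_positions(diag(c(1, 4, 9)), n = 1e5, seed = 2)
  expect_equal(bound_volume(aniso$positions), 6 * (2 * pi * exp(1))^1.5,
               tolerance = 0.02)
})

test_that("degenerate position clouds are rejected", {
  expect_error(bound_volume(matrix(rnorm(15), 5, 3)), "10 positions")
  flat <- cbind(rnorm(50), rnorm(50), 0)
  expect_error(bound_volume(flat), "rank")
})

test_that("binding decomposition sums exactly and converts to Kd", {
  dec <- combine_binding(-1.83, -0.36, 1.38)
  expect_identical(dec$dg_total, -1.83 + -0.36 + 1.38)
  expect_equal(dec$dg_total, -0.81)
  zero <- combine_binding(0, 0, 0)
  expect_equal(zero$dg_total, 0)
  expect_equal(zero$kd, 1)
  dop <- combine_binding(-6.23, -0.36, 3.2)
  expect_equal(dop$dg_total, -3.39)  # exact arithmetic on the components
})

test_that("dG/Kd conversion is exact, monotone and self-inverse", {
  expect_equal(dg_to_kd(0), 1)
  expect_equal(dg_to_kd(-4.49, 300), 5.4e-4, tolerance = 0.01)
  expect_equal(dg_to_kd(-0.81, 300), 2.59e-1, tolerance = 0.01)
  dgs <- seq(-6, 2, by = 0.5)
  expect_true(all(diff(dg_to_kd(dgs)) > 0))
  expect_equal(kd_to_dg(dg_to_kd(dgs)), dgs, tolerance = 1e-12)
  expect_error(kd_to_dg(-1))
})
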