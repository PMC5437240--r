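test_that("a single unbiased window inverts to a flat PMF", {
  set.seed(21)
  w <- tibble::tibble(center = 0, spring_k = 0,
                      samples = list(runif(50000, -2, 2)))
  pmf <- wham_pmf(umbrella_windows(w), n_bins = 20)
  prof <- dplyr::filter(tidy(pmf), is.finite(free_energy))
  # every bin within a few sigma of the flat mean, sigma = kT/sqrt(n_i)
  dev <- abs(prof$free_energy - mean(prof$free_energy))
  expect_true(all(dev <= 4 * prof$uncertainty))
})

test_that("WHAM recovers a known harmonic PMF", {
  pm <- pmf_spec("harmonic", a = 2)
  uw <- sample_umbrella_windows(pm, centers = seq(-3, 3, by = 0.25),
                                spring_k = 10, n_per_window = 20000, seed = 3)
  pmf <- wham_pmf(uw, n_bins = 100)
  prof <- dplyr::filter(tidy(pmf), n_samples > 500)
  truth <- pm$fun(prof$bin_center)
  err <- (prof$free_energy - min(prof$free_energy)) - (truth - min(truth))
  expect_lt(max(abs(err)), 0.1)
})

test_that("WHAM shifts agree with a brute-force fixed-point oracle", {
  set.seed(31)
  centers <- seq(-0.9, 0.9, length.out = 10)
  w <- tibble::tibble(
    center = c(-0.5, 0.5), spring_k = c(3, 3),
    samples = list(rnorm(2000, -0.5, 0.4), rnorm(2000, 0.5, 0.4)))
  uw <- umbrella_windows(w)
  pmf <- wham_pmf(uw, n_bins = 10, tol = 1e-14)
  # re-bin exactly as the package does, then iterate the raw equations
  edges <- seq(min(unlist(w$samples)) - 1e-9, max(unlist(w$samples)) + 1e-9,
               length.out = 11)
  mids <- (edges[-1] + edges[-11]) / 2
  counts <- sapply(w$samples, function(s) {
    tabulate(findInterval(s, edges, rightmost.closed = TRUE), nbins = 10)
  })
  f_oracle <- brute_force_wham_shifts(counts, mids, w$spring_k, w$center,
                                      kt = rt_kcal(300))
  expect_equal(pmf$shifts, f_oracle, tolerance = 1e-10)
})

test_that("PMF is unchanged by a constant offset of the generating potential", {
  base <- pmf_spec("table", x = seq(-3, 3, by = 0.1),
                   u = 0.5 * seq(-3, 3, by = 0.1)^2)
  lifted <- pmf_spec("table", x = seq(-3, 3, by = 0.1),
                     u = 0.5 * seq(-3, 3, by = 0.1)^2 + 5)
  uw1 <- sample_umbrella_windows(base, seq(-2, 2, by = 0.5), 8, 5000, seed = 5)
  uw2 <- sample_umbrella_windows(lifted, seq(-2, 2, by = 0.5), 8, 5000, seed = 5)
  p1 <- wham_pmf(uw1, n_bins = 40)
  p2 <- wham_pmf(uw2, n_bins = 40)
  expect_equal(p1$profile$free_energy, p2$profile$free_energy, tolerance = 1e-10)
})

test_that("doubling samples per window shrinks bin uncertainty by about sqrt(2)", {
  pm <- pmf_spec("harmonic", a = 1)
  uw1 <- sample_umbrella_windows(pm, seq(-2, 2, by = 0.5), 8, 4000, seed = 6)
  uw2 <- sample_umbrella_windows(pm, seq(-2, 2, by = 0.5), 8, 8000, seed = 6)
  p1 <- suppressWarnings(wham_pmf(uw1, n_bins = 30))$profile
  p2 <- suppressWarnings(wham_pmf(uw2, n_bins = 30))$profile
  # compare the best-sampled bin (near the window centres' midpoint)
  u1 <- p1$uncertainty[which.max(p1$n_samples)]
  u2 <- p2$uncertainty[which.max(p2$n_samples)]
  expect_equal(u1 / u2, sqrt(2), tolerance = 0.1)
})

test_that("non-convergence and bad plateau ranges are reported", {
  set.seed(41)
  w <- tibble::tibble(center = c(-1, 1), spring_k = c(5, 5),
                      samples = list(rnorm(500, -1, 0.3), rnorm(500, 1, 0.3)))
  uw <- suppressWarnings(umbrella_windows(w))
  expect_error(wham_pmf(uw, n_bins = 20, max_iter = 2), "did not converge")
  expect_error(wham_pmf(uw, n_bins = 20, plateau_range = c(50, 60)),
               "plateau_range")
})

test_that("window validation flags empty windows and non-overlap", {
  expect_error(umbrella_windows(tibble::tibble(
    center = 0, spring_k = 1, samples = list(numeric()))), "at least one")
  expect_warning(umbrella_windows(tibble::tibble(
    center = c(0, 10), spring_k = c(1, 1),
    samples = list(c(0, 0.1), c(10, 10.1)))), "non-overlapping")
})

test_that("umbrella window files round-trip through the reader", {
  dir <- withr::local_tempdir()
  pm <- pmf_spec("flat")
  uw <- sample_umbrella_windows(pm, c(-1, 0, 1), 5, 200, seed = 8)
  for (j in 1:3) {
    writeLines(c(sprintf("# center %.6f", uw$windows$center[j]),
                 sprintf("# spring_k %.6f", uw$windows$spring_k[j]),
                 format(uw$windows$samples[[j]], digits = 12)),
               file.path(dir, sprintf("window_%02d.dat", j)))
  }
  uw2 <- read_umbrella_windows(dir)
  expect_equal(uw2$windows$center, uw$windows$center)
  expect_equal(unlist(uw2$windows$samples), unlist(uw$windows$samples),
               tolerance = 1e-10)
})
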