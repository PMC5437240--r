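test_that("the Hill model obeys its closed-form identities", {
  expect_equal(hill_model(0.86, kd = 0.86, bmax = 0.17, h = 2.22), 0.17 / 2)
  expect_equal(hill_model(0, kd = 1, bmax = 0.2, h = 1.5), 0)
  expect_equal(hill_model(10, kd = 1, bmax = 0.2, h = 2), 0.2 * 100 / 101)
  # strictly increasing and saturating at bmax
  cc <- seq(0, 50, by = 0.5)
  y <- hill_model(cc, 2, 0.3, 1.7)
  expect_true(all(diff(y) > 0))
  expect_lt(max(y), 0.3)
  expect_equal(hill_model(1e6, 2, 0.3, 1.7), 0.3, tolerance = 1e-6)
})

test_that("noise-free curves at the phenol and serotonin regimes refit exactly", {
  for (p in list(c(kd = 0.86, bmax = 0.17, h = 2.22),
                 c(kd = 3.34, bmax = 0.11, h = 1.63))) {
    tt <- make_titration(p["kd"], p["bmax"], p["h"],
                         log_spaced(0.05, 10, 12), noise_sd = 0)
    fit <- fit_hill(tt)$parameters
    expect_true(fit$converged)
    expect_equal(fit$kd, unname(p["kd"]), tolerance = 1e-6)
    expect_equal(fit$bmax, unname(p["bmax"]), tolerance = 1e-6)
    expect_equal(fit$h, unname(p["h"]), tolerance = 1e-6)
  }
})

test_that("noise-free recovery holds across the (kd, h) grid", {
  for (kd in c(0.1, 1, 10)) {
    for (h in c(0.5, 2, 8)) {
      tt <- make_titration(kd, 0.15, h, log_spaced(0.01, 100, 16),
                           noise_sd = 0)
      fit <- fit_hill(tt)$parameters
      expect_equal(fit$kd / kd, 1, tolerance = 1e-6)
      expect_equal(fit$h / h, 1, tolerance = 1e-6)
    }
  }
})

test_that("an all-zero curve is flagged as degenerate", {
  tt <- tibble::tibble(concentration_mM = log_spaced(0.05, 10, 12), delta_a = 0)
  fit <- fit_hill(tt)$parameters
  expect_true(!fit$converged || fit$bmax < 1e-6)
})

test_that("fits are invariant to point order and uniform duplication", {
  tt <- make_titration(0.86, 0.17, 2.22, log_spaced(0.05, 10, 12),
                       noise_sd = 0.005, seed = 7)
  base <- fit_hill(tt)$parameters
  shuffled <- tt[sample(nrow(tt)), ]
  doubled <- dplyr::bind_rows(tt, tt)
  expect_equal(fit_hill(shuffled)$parameters$kd, base$kd, tolerance = 1e-8)
  expect_equal(fit_hill(doubled)$parameters$kd, base$kd, tolerance = 1e-8)
})

test_that("mean fitted Kd tracks the generating value under noise", {
  tt <- make_titration(0.86, 0.17, 2.22, log_spaced(0.05, 10, 12),
                       noise_sd = 0.005, n_replicates = 15, seed = 3)
  fits <- fit_hill_replicates(tt)
  expect_true(all(fits$converged))
  sem <- sd(fits$kd) / sqrt(nrow(fits))
  expect_lt(abs(mean(fits$kd) - 0.86), 3 * sem)
})

test_that("replicate summaries report n-1 statistics and drop failures", {
  same <- tibble::tibble(kd = rep(0.8, 3), bmax = 0.2, h = 2, converged = TRUE)
  s <- summarize_replicates(same)
  expect_equal(s$sd, rep(0, 3))
  three <- tibble::tibble(kd = c(0.8, 0.86, 0.92), bmax = 0.2, h = 2,
                          converged = TRUE)
  s2 <- summarize_replicates(three)
  expect_equal(s2$mean[s2$parameter == "kd"], 0.86)
  expect_equal(s2$sd[s2$parameter == "kd"], 0.06, tolerance = 1e-10)
  mixed <- dplyr::bind_rows(three,
                            tibble::tibble(kd = 99, bmax = 1, h = 9,
                                           converged = FALSE))
  s3 <- summarize_replicates(mixed)
  expect_equal(unique(s3$n), 3L)
  expect_error(summarize_replicates(three[1, ]), "2 converged")
})

test_that("difference absorbance interpolates between tabulated wavelengths", {
  wl <- seq(300, 550, by = 10)
  free <- tibble::tibble(wavelength_nm = wl, absorbance = 0.1)
  bound_same <- free
  expect_equal(difference_absorbance(bound_same, free), 0)
  bound_up <- dplyr::mutate(free, absorbance = absorbance + 0.05)
  expect_equal(difference_absorbance(bound_up, free), 0.05)
  coarse_free <- tibble::tibble(wavelength_nm = c(440, 450),
                                absorbance = c(0.10, 0.20))
  coarse_bound <- tibble::tibble(wavelength_nm = c(440, 450),
                                 absorbance = c(0.30, 0.20))
  # hand linear interpolation at 444 nm
  a_free <- 0.10 + (0.20 - 0.10) * (444 - 440) / 10
  a_bound <- 0.30 + (0.20 - 0.30) * (444 - 440) / 10
  expect_equal(difference_absorbance(coarse_bound, coarse_free),
               a_bound - a_free)
  narrow <- tibble::tibble(wavelength_nm = c(500, 550), absorbance = 0.1)
  expect_error(difference_absorbance(narrow, narrow), "outside")
})

test_that("tidy and glance expose the fit in broom shape", {
  tt <- make_titration(1, 0.2, 2, log_spaced(0.05, 10, 12), noise_sd = 0)
  fit <- fit_hill(tt)
  td <- tidy(fit)
  expect_equal(td$term, c("kd", "bmax", "h"))
  expect_equal(td$estimate, c(1, 0.2, 2), tolerance = 1e-6)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$nobs, 12)
})
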