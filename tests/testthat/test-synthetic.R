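test_that("generators are bit-reproducible per seed", {
  s1 <- make_hexamer_fixture(seed = 7)
  s2 <- make_hexamer_fixture(seed = 7)
  expect_identical(s1$atoms, s2$atoms)
  t1 <- make_titration(1, 0.2, 2, log_spaced(0.1, 10, 10), n_replicates = 3,
                       seed = 5)
  t2 <- make_titration(1, 0.2, 2, log_spaced(0.1, 10, 10), n_replicates = 3,
                       seed = 5)
  expect_identical(t1, t2)
  u1 <- sample_umbrella_windows(pmf_spec("flat"), 0, 5, 100, seed = 9)
  u2 <- sample_umbrella_windows(pmf_spec("flat"), 0, 5, 100, seed = 9)
  expect_identical(u1$windows$samples, u2$windows$samples)
  ts1 <- make_ti_series(1, 2, 3, noise_sem = 0.1, seed = 2)
  ts2 <- make_ti_series(1, 2, 3, noise_sem = 0.1, seed = 2)
  expect_identical(ts1, ts2)
})

test_that("two fixture seeds differ only by sub-0.05 A jitter", {
  a <- make_hexamer_fixture(seed = 1)$atoms
  b <- make_hexamer_fixture(seed = 2)$atoms
  expect_equal(nrow(a), nrow(b))
  d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  expect_gt(max(d), 0)
  expect_lte(max(d), 0.05)
})

test_that("generator RNG use does not disturb the caller's stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(make_titration(1, 0.2, 2, log_spaced(0.1, 10, 10), seed = 4))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("the TI generator returns its analytic integral", {
  expect_equal(make_ti_series(a = -4.49)$dg_analytic, -4.49)
  expect_equal(make_ti_series(b = 2)$dg_analytic, 1.0)
  expect_equal(make_ti_series(c = 1)$dg_analytic, 2 / pi)
  expect_error(make_ti_series(n_lambda = 1), "n_lambda")
})

test_that("biased window samples follow the closed-form Gaussian widths", {
  kt <- rt_kcal(300)
  flat <- sample_umbrella_windows(pmf_spec("flat"), 0, spring_k = 10,
                                  n_per_window = 1e5, seed = 11)
  expect_equal(sd(flat$windows$samples[[1]]), sqrt(kt / 10), tolerance = 0.02)
  harm <- sample_umbrella_windows(pmf_spec("harmonic", a = 4), 0, spring_k = 10,
                                  n_per_window = 1e5, seed = 12)
  expect_equal(sd(harm$windows$samples[[1]]), sqrt(kt / (4 + 10)),
               tolerance = 0.02)
})

test_that("umbrella sampling rejects invalid requests", {
  expect_error(sample_umbrella_windows(pmf_spec("flat"), 0, 5, 0), "n_per_window")
  expect_error(sample_umbrella_windows(pmf_spec("flat"), 0, spring_k = 1e-6,
                                       n_per_window = 10, grid_pad = 0.5),
               "confine")
})

test_that("bound-position clouds carry their analytic volume", {
  iso <- sample_bound_positions(diag(3), n = 1e5, seed = 1)
  expect_equal(iso$volume_analytic, (2 * pi * exp(1))^1.5)
  expect_equal(bound_volume(iso$positions), iso$volume_analytic,
               tolerance = 0.02)
  aniso <- sample_bound_positions(diag(c(1, 4, 9)), n = 100, seed = 2)
  expect_equal(aniso$volume_analytic, 6 * iso$volume_analytic)
  expect_error(sample_bound_positions(matrix(0, 3, 3), 10), "positive definite")
  small <- sample_bound_positions(diag(3), n = 5, seed = 3)
  expect_error(bound_volume(small$positions), "10 positions")
})

test_that("noiseless titrations lie exactly on the Hill curve", {
  cc <- log_spaced(0.05, 10, 12)
  tt <- make_titration(0.86, 0.17, 2.22, cc, noise_sd = 0)
  expect_equal(tt$delta_a, hill_model(cc, 0.86, 0.17, 2.22))
  truth <- attr(tt, "true_parameters")
  expect_equal(unname(truth), c(0.86, 0.17, 2.22))
})

test_that("replicates derive independent sub-seeds from the base seed", {
  tt <- make_titration(1, 0.2, 2, log_spaced(0.1, 10, 10), noise_sd = 0.01,
                       n_replicates = 2, seed = 10)
  r1 <- dplyr::filter(tt, replicate_id == 1)
  r2 <- dplyr::filter(tt, replicate_id == 2)
  expect_false(isTRUE(all.equal(r1$delta_a, r2$delta_a)))
  # replicate 2 alone reproduces from seed + 2
  solo <- make_titration(1, 0.2, 2, log_spaced(0.1, 10, 10), noise_sd = 0.01,
                         n_replicates = 1, seed = 11)
  expect_equal(r2$delta_a, solo$delta_a)
})

test_that("infeasible ligand anchors are rejected with the offending pair", {
  lig <- tibble::tibble(name = "serotonin", site = c("I", "I"), monomer = c(4, 4))
  expect_error(make_hexamer_fixture(
    monomer_states = c("T", "T", "T", "R", "R", "R"), ligands = lig,
    zinc = character(), seed = 1), "clashes")
  bad <- tibble::tibble(name = "serotonin", site = "I", monomer = 4,
                        oh_dist = 1.0)
  expect_error(make_hexamer_fixture(
    monomer_states = c("T", "T", "T", "R", "R", "R"), ligands = bad,
    zinc = character(), seed = 1), "anchor distances")
})
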