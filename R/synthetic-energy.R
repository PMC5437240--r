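## Synthetic free-energy inputs with analytic ground truth: Boltzmann samples
## from known 1-D potentials of mean force under harmonic biases, lambda
## series with closed-form integrals, and Gaussian bound-state position
## clouds. All generators are deterministic given (spec, seed).

#' Specify a 1-D potential of mean force
#'
#' Supported forms: `"flat"` (U = 0); `"harmonic"` (U = a/2 x^2, parameter
#' `a` in kcal/mol per unit^2); `"well"` (truncated harmonic well of `depth`
#' kcal/mol and half-width `width`: U = depth ((x/width)^2 - 1) inside
#' |x| < width, 0 outside — its well depth relative to the plateau is exactly
#' -depth); `"table"` (interpolated from `x`, `u` vectors).
#'
#' @param form One of `"flat"`, `"harmonic"`, `"well"`, `"table"`.
#' @param ... Form parameters (see above).
#' @return A `pmf_spec` with elements `fun` (vectorised U(x)) and
#'   `well_depth` (analytic W0, NA for tabulated forms).
#' @export
pmf_spec <- function(form = c("flat", "harmonic", "well", "table"), ...) {
  form <- match.arg(form)
  p <- list(...)
  spec <- switch(form,
    flat = list(fun = function(x) rep(0, length(x)), well_depth = 0),
    harmonic = {
      a <- p$a %||% 1
      list(fun = function(x) 0.5 * a * x^2, well_depth = NA_real_)
    },
    well = {
      depth <- p$depth %||% 2
      width <- p$width %||% 3
      list(fun = function(x) ifelse(abs(x) < width,
                                    depth * ((x / width)^2 - 1), 0),
           well_depth = -depth)
    },
    table = {
      stopifnot(!is.null(p$x), !is.null(p$u))
      list(fun = function(x) approx(p$x, p$u, xout = x, rule = 2)$y,
           well_depth = NA_real_)
    })
  structure(c(spec, list(form = form, params = p)), class = "pmf_spec")
}

#' Sample umbrella windows from a known PMF
#'
#' Draws Boltzmann samples from density proportional to
#' exp(-(U(x) + k/2 (x - c)^2) / RT) for each window centre by inverse-CDF
#' sampling on a fine grid; deterministic per seed.
#'
#' @param pmf A `pmf_spec`.
#' @param centers Window centres (reaction-coordinate units).
#' @param spring_k Harmonic bias spring constant, kcal/mol per unit^2
#'   (recycled across windows).
#' @param n_per_window Samples per window (>= 1).
#' @param temperature Kelvin (default 300).
#' @param seed Integer seed.
#' @param grid_pad,grid_n Sampling-grid extension beyond the centres and
#'   resolution.
#' @return An `umbrella_windows` object; the generating `pmf_spec` is
#'   attached as element `pmf_spec`.
#' @export
sample_umbrella_windows <- function(pmf, centers, spring_k, n_per_window,
                                    temperature = 300, seed = 1,
                                    grid_pad = NULL, grid_n = 4001) {
  stopifnot(inherits(pmf, "pmf_spec"))
  if (n_per_window < 1) abort("n_per_window must be >= 1")
  kt <- rt_kcal(temperature)
  spring_k <- rep_len(spring_k, length(centers))
  if (any(spring_k <= 0)) abort("spring constants must be positive for sampling")
  pad <- grid_pad %||% (6 * sqrt(kt / min(spring_k)))
  grid <- seq(min(centers) - pad, max(centers) + pad, length.out = grid_n)
  u0 <- pmf$fun(grid)
  samples <- with_seed(seed, purrr::map(seq_along(centers), function(j) {
    utot <- u0 + 0.5 * spring_k[j] * (grid - centers[j])^2
    dens <- exp(-(utot - min(utot)) / kt)
    if (dens[1] > 1e-6 || dens[length(dens)] > 1e-6) {
      abort("spring too weak to confine samples within the sampling grid")
    }
    ## trapezoidal CDF: an O(dx) quadrature bias here would displace every
    ## sample relative to its bias centre and tilt the recovered PMF
    cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2))
    cdf <- cdf / cdf[length(cdf)]
    keep <- c(TRUE, diff(cdf) > 0)
    approx(cdf[keep], grid[keep], xout = runif(n_per_window), rule = 2)$y
  }))
  uw <- umbrella_windows(tibble(center = centers, spring_k = spring_k,
                                samples = samples), temperature)
  uw$pmf_spec <- pmf
  uw
}

#' Generate a thermodynamic-integration lambda series with analytic integral
#'
#' The coupling derivative is the closed form
#' dU/dlambda = a + b lambda + c sin(pi lambda), whose integral over \[0, 1\]
#' is a + b/2 + 2 c / pi; Gaussian noise of standard deviation `noise_sem`
#' is added per point and reported as the per-point SEM.
#'
#' @param a,b,c Coefficients, kcal/mol.
#' @param n_lambda Number of equally spaced lambda points (>= 2).
#' @param noise_sem Per-point Gaussian noise / SEM, kcal/mol.
#' @param seed Integer seed.
#' @return List with `series` (tibble: `lambda`, `dudl_mean`, `dudl_sem`)
#'   and `dg_analytic` (kcal/mol).
#' @export
make_ti_series <- function(a = 0, b = 0, c = 0, n_lambda = 21,
                           noise_sem = 0, seed = 1) {
  if (n_lambda < 2) abort("n_lambda must be >= 2")
  lam <- seq(0, 1, length.out = n_lambda)
  mu <- a + b * lam + c * sin(pi * lam)
  noise <- if (noise_sem > 0) {
    with_seed(seed, rnorm(n_lambda, 0, noise_sem))
  } else {
    rep(0, n_lambda)
  }
  list(series = tibble(lambda = lam, dudl_mean = mu + noise,
                       dudl_sem = rep(noise_sem, n_lambda)),
       dg_analytic = a + b / 2 + 2 * c / pi)
}

#' Sample a bound-state ligand position cloud
#'
#' Multivariate Gaussian positions with the given covariance; the analytic
#' Gaussian effective volume (2 pi e)^(3/2) |Sigma|^(1/2) is returned
#' alongside.
#'
#' @param covariance 3 x 3 positive-definite covariance, Angstrom^2.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param center Mean position (default origin).
#' @return List with `positions` (tibble x, y, z) and `volume_analytic`
#'   (cubic Angstroms).
#' @export
sample_bound_positions <- function(covariance, n, seed = 1, center = c(0, 0, 0)) {
  covariance <- as.matrix(covariance)
  stopifnot(all(dim(covariance) == c(3, 3)))
  ok <- tryCatch({chol(covariance); TRUE}, error = function(e) FALSE)
  if (!ok) abort("covariance must be positive definite")
  xyz <- with_seed(seed, MASS::mvrnorm(n, mu = center, Sigma = covariance))
  xyz <- matrix(xyz, ncol = 3)
  list(positions = tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
       volume_analytic = (2 * pi * exp(1))^1.5 * sqrt(det(covariance)))
}
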