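## One-site Hill-slope analysis of chromophore-reported titration curves.
##
## The difference absorbance at 444 nm of the R-state-specific chromophore
## follows dA(c) = Bmax c^h / (Kd^h + c^h): Kd in mM, Bmax in absorbance
## units, h the phenomenological Hill coefficient.

HILL_LOWER <- c(kd = 1e-6, bmax = 0, h = 1e-6)
HILL_UPPER <- c(kd = 100, bmax = 1, h = 20)

#' One-site Hill-slope binding model
#'
#' dA = bmax * c^h / (kd^h + c^h).
#'
#' @param c Ligand concentration, mM (>= 0); vectorised.
#' @param kd Half-saturation constant, mM (> 0).
#' @param bmax Saturation signal, AU (>= 0).
#' @param h Hill coefficient (> 0).
#' @return Predicted difference absorbance, AU.
#' @export
hill_model <- function(c, kd, bmax, h) {
  stopifnot(kd > 0, h > 0, all(c >= 0))
  ch <- c^h
  bmax * ch / (kd^h + ch)
}

#' Fit the Hill model to a titration series
#'
#' Bounded Levenberg-Marquardt least squares (via minpack.lm) of the one-site
#' Hill-slope model. Auto-initialisation: kd at the concentration nearest
#' half-maximal observed signal, bmax at the maximum observed signal, h = 1.
#' Standard errors come from the curvature of the residual surface at the
#' optimum.
#'
#' @param series Data frame with columns `concentration_mM` and `delta_a`
#'   (one replicate).
#' @param init Optional named list/vector with starting `kd`, `bmax`, `h`.
#' @return A `hill_fit` object; use [tidy()]/[glance()] or `$parameters`.
#' @export
fit_hill <- function(series, init = NULL) {
  series <- as_tibble(series)
  stopifnot(all(c("concentration_mM", "delta_a") %in% names(series)))
  if (length(unique(series$concentration_mM)) < 5) {
    abort("at least 5 distinct concentrations are required")
  }
  if (nrow(series) < 4) abort("fewer data points than parameters")
  conc <- series$concentration_mM
  da <- series$delta_a
  if (is.null(init)) {
    bmax0 <- max(da)
    half <- bmax0 / 2
    kd0 <- conc[which.min(abs(da - half))]
    if (kd0 <= 0) kd0 <- stats::median(conc[conc > 0])
    init <- c(kd = unname(kd0), bmax = unname(max(bmax0, 1e-4)), h = 1)
  }
  init <- pmin(pmax(unlist(init)[c("kd", "bmax", "h")], HILL_LOWER), HILL_UPPER)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      delta_a ~ bmax * concentration_mM^h / (kd^h + concentration_mM^h),
      data = series, start = as.list(init),
      lower = HILL_LOWER, upper = HILL_UPPER,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit)) {
    pars <- tibble(kd = NA_real_, bmax = NA_real_, h = NA_real_,
                   se_kd = NA_real_, se_bmax = NA_real_, se_h = NA_real_,
                   rss = NA_real_, converged = FALSE)
    return(structure(list(parameters = pars, data = series, fit = NULL),
                     class = "hill_fit"))
  }
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 3), names(est)))
  conv <- isTRUE(fit$convInfo$isConv)
  ## a fit pinned at the bmax = 0 boundary is a degenerate (flat) curve
  if (est[["bmax"]] < 1e-8) conv <- FALSE
  pars <- tibble(kd = est[["kd"]], bmax = est[["bmax"]], h = est[["h"]],
                 se_kd = unname(se["kd"]), se_bmax = unname(se["bmax"]),
                 se_h = unname(se["h"]), rss = deviance(fit), converged = conv)
  structure(list(parameters = pars, data = series, fit = fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  p <- x$parameters
  cat(sprintf("<hill_fit> Kd = %.4g mM, Bmax = %.4g AU, h = %.4g (%s)\n",
              p$kd, p$bmax, p$h,
              if (isTRUE(p$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Tidy a Hill fit
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`, `std.error`.
#' @method tidy hill_fit
#' @export
tidy.hill_fit <- function(x, ...) {
  p <- x$parameters
  tibble(term = c("kd", "bmax", "h"),
         estimate = c(p$kd, p$bmax, p$h),
         std.error = c(p$se_kd, p$se_bmax, p$se_h))
}

#' One-row fit summary
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return Tibble: `rss`, `nobs`, `converged`.
#' @method glance hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(rss = x$parameters$rss, nobs = nrow(x$data),
         converged = x$parameters$converged)
}

#' Summarise replicate Hill fits
#'
#' Pools per-curve fits into per-parameter sample means and standard
#' deviations (n - 1 denominator); unconverged fits are excluded and `n`
#' reflects the exclusion.
#'
#' @param fits A list of `hill_fit` objects, or a data frame with columns
#'   `kd`, `bmax`, `h`, `converged`.
#' @return Tibble: `parameter`, `mean`, `sd`, `n`.
#' @export
summarize_replicates <- function(fits) {
  if (is.list(fits) && !is.data.frame(fits)) {
    fits <- purrr::map_dfr(fits, function(f) {
      if (inherits(f, "hill_fit")) f$parameters else as_tibble(f)
    })
  }
  fits <- as_tibble(fits)
  if (!"converged" %in% names(fits)) fits$converged <- TRUE
  ok <- filter(fits, .data$converged)
  if (nrow(ok) < 2) abort("at least 2 converged fits are required")
  ok %>%
    select("kd", "bmax", "h") %>%
    tidyr::pivot_longer(dplyr::everything(), names_to = "parameter") %>%
    group_by(.data$parameter) %>%
    summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
              n = dplyr::n(), .groups = "drop") %>%
    arrange(match(.data$parameter, c("kd", "bmax", "h")))
}

#' Difference absorbance at a reference wavelength
#'
#' dA = A_bound(lambda) - A_free(lambda) with linear interpolation between
#' tabulated wavelengths.
#'
#' @param bound_spectrum,free_spectrum Data frames with columns
#'   `wavelength_nm`, `absorbance`.
#' @param lambda_max Reference wavelength in nm (default 444).
#' @return Difference absorbance, AU.
#' @export
difference_absorbance <- function(bound_spectrum, free_spectrum, lambda_max = 444) {
  eval_spec <- function(sp) {
    sp <- as_tibble(sp)
    stopifnot(all(c("wavelength_nm", "absorbance") %in% names(sp)))
    if (lambda_max < min(sp$wavelength_nm) || lambda_max > max(sp$wavelength_nm)) {
      abort(sprintf("wavelength %g nm outside the tabulated range", lambda_max))
    }
    approx(sp$wavelength_nm, sp$absorbance, xout = lambda_max)$y
  }
  eval_spec(bound_spectrum) - eval_spec(free_spectrum)
}
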