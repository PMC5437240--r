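## Binding free energies: thermodynamic integration, well depths, symmetry and
## standard-state volume corrections, and conversion between free energy and
## dissociation constant. Energies are kcal/mol, temperatures Kelvin,
## volumes cubic Angstroms, concentrations mol/L.

#' Thermodynamic integration of a lambda series
#'
#' Trapezoidal quadrature of the mean coupling derivative <dU/dlambda> over
#' lambda in \[0, 1\], with the standard error propagated through the
#' quadrature weights.
#'
#' @param series Data frame with columns `lambda`, `dudl_mean` and optionally
#'   `dudl_sem` (kcal/mol).
#' @return Tibble with one row: `dg` and `dg_se` (kcal/mol), `n_lambda`,
#'   `extrapolated` (TRUE when the endpoints 0 and 1 are absent).
#' @export
ti_integrate <- function(series) {
  series <- as_tibble(series)
  if (!all(c("lambda", "dudl_mean") %in% names(series))) {
    abort("series needs columns `lambda` and `dudl_mean`")
  }
  if (nrow(series) < 2) abort("at least two lambda points are required")
  series <- arrange(series, .data$lambda)
  lam <- series$lambda
  if (any(diff(lam) <= 0)) abort("lambda values must be strictly increasing")
  if (any(lam < 0 | lam > 1)) abort("lambda values must lie in [0, 1]")
  extrapolated <- !(abs(lam[1]) < 1e-12 && abs(lam[length(lam)] - 1) < 1e-12)
  if (extrapolated) warn("lambda endpoints 0/1 absent; integral covers the sampled range only")
  h <- diff(lam)
  w <- c(h / 2, 0) + c(0, h / 2)  # trapezoid weights
  dg <- sum(w * series$dudl_mean)
  sem <- if ("dudl_sem" %in% names(series)) series$dudl_sem else rep(0, nrow(series))
  dg_se <- sqrt(sum((w * sem)^2))
  tibble(dg = dg, dg_se = dg_se, n_lambda = nrow(series), extrapolated = extrapolated)
}

#' PMF well depth relative to the unbound plateau
#'
#' W0 = min free energy over the bound range minus the mean free energy over
#' the plateau range; invariant under an additive constant on the profile.
#'
#' @param pmf A `pmf_profile` (from [wham_pmf()]) or data frame with columns
#'   `bin_center` and `free_energy`.
#' @param bound_range,plateau_range Length-2 numeric ranges on the reaction
#'   coordinate.
#' @return W0 in kcal/mol.
#' @export
well_depth <- function(pmf, bound_range, plateau_range) {
  prof <- if (inherits(pmf, "pmf_profile")) pmf$profile else as_tibble(pmf)
  prof <- filter(prof, is.finite(.data$free_energy))
  in_bound <- prof$bin_center >= bound_range[1] & prof$bin_center <= bound_range[2]
  in_plateau <- prof$bin_center >= plateau_range[1] & prof$bin_center <= plateau_range[2]
  if (!any(in_bound)) abort("bound_range does not intersect the PMF bins")
  if (!any(in_plateau)) abort("plateau_range does not intersect the PMF bins")
  min(prof$free_energy[in_bound]) - mean(prof$free_energy[in_plateau])
}

#' Symmetry correction for equivalent binding sites
#'
#' Default -RT ln(n_sites); a verbatim override is accepted to reproduce
#' externally derived values.
#'
#' @param n_sites Number of symmetry-equivalent sites (>= 1).
#' @param temperature Kelvin (default 300).
#' @param override Optional value in kcal/mol passed through unchanged.
#' @return Correction in kcal/mol.
#' @export
symmetry_correction <- function(n_sites, temperature = 300, override = NULL) {
  if (!is.null(override)) return(override)
  if (n_sites < 1) abort("n_sites must be >= 1")
  -rt_kcal(temperature) * log(n_sites)
}

#' Volume-entropy correction to the 1 M standard state
#'
#' dG_vol = -RT ln(v_bound / V0) with V0 = 1660.539 cubic Angstroms, the
#' volume per molecule at 1 M.
#'
#' @param v_bound Effective bound-state volume in cubic Angstroms (> 0).
#' @param temperature Kelvin (default 300).
#' @return Correction in kcal/mol.
#' @export
volume_correction <- function(v_bound, temperature = 300) {
  if (v_bound <= 0) abort("v_bound must be positive")
  -rt_kcal(temperature) * log(v_bound / V0_A3)
}

#' Effective bound-state volume from ligand positions
#'
#' Gaussian effective volume v = (2 pi e)^(3/2) |Sigma|^(1/2) from the 3x3
#' positional covariance of bound-state ligand centres.
#'
#' @param positions n x 3 matrix or data frame (x, y, z) of positions in
#'   Angstroms, n >= 10.
#' @return Volume in cubic Angstroms.
#' @export
bound_volume <- function(positions) {
  xyz <- coords_matrix(positions)
  if (nrow(xyz) < 10) abort("at least 10 positions are required")
  sig <- stats::cov(xyz)
  ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 1e-10)) abort("positional covariance is rank-deficient")
  (2 * pi * exp(1))^1.5 * sqrt(det(sig))
}

#' Combine a PMF well depth with symmetry and volume corrections
#'
#' dG_b = W0 + dG_symm + dG_vol (exact arithmetic); K_d = exp(dG_b / RT).
#' Component standard errors, if given, combine in quadrature, and the K_d
#' uncertainty follows by the first-order delta method.
#'
#' @param w0 PMF well depth, kcal/mol.
#' @param dg_symm,dg_vol Corrections, kcal/mol.
#' @param temperature Kelvin (default 300).
#' @param w0_se,dg_vol_se Optional standard errors, kcal/mol.
#' @return A `binding_decomposition`: tibble row with `w0`, `dg_symm`,
#'   `dg_vol`, `dg_total`, `dg_se`, `kd` (mol/L), `kd_se`, `temperature`.
#' @export
combine_binding <- function(w0, dg_symm, dg_vol, temperature = 300,
                            w0_se = 0, dg_vol_se = 0) {
  stopifnot(is.finite(w0), is.finite(dg_symm), is.finite(dg_vol))
  dg_total <- w0 + dg_symm + dg_vol
  dg_se <- sqrt(w0_se^2 + dg_vol_se^2)
  kd <- dg_to_kd(dg_total, temperature)
  kd_se <- kd * dg_se / rt_kcal(temperature)
  out <- tibble(w0 = w0, dg_symm = dg_symm, dg_vol = dg_vol,
                dg_total = dg_total, dg_se = dg_se, kd = kd, kd_se = kd_se,
                temperature = temperature)
  class(out) <- c("binding_decomposition", class(out))
  out
}

#' Convert binding free energy to dissociation constant
#'
#' K_d = exp(dG / RT) with R = 1.98720e-3 kcal/(mol K); RT = 0.59616 kcal/mol
#' at 300 K.
#'
#' @param dg Standard binding free energy, kcal/mol.
#' @param temperature Kelvin (default 300).
#' @return K_d in mol/L.
#' @export
dg_to_kd <- function(dg, temperature = 300) {
  exp(dg / rt_kcal(temperature))
}

#' Convert dissociation constant to binding free energy
#'
#' Inverse of [dg_to_kd()]: dG = RT ln(K_d).
#'
#' @param kd Dissociation constant, mol/L (> 0).
#' @param temperature Kelvin (default 300).
#' @return dG in kcal/mol.
#' @export
kd_to_dg <- function(kd, temperature = 300) {
  stopifnot(all(kd > 0))
  rt_kcal(temperature) * log(kd)
}
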