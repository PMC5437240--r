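## Synthetic titration curves from the Hill model with additive Gaussian
## noise on the difference absorbance. Replicate i draws from sub-seed
## seed + i (stable across versions).

#' Generate noisy Hill-model titration replicates
#'
#' dA = hill_model(c; kd, bmax, h) + N(0, noise_sd) per point; replicate `i`
#' uses sub-seed `seed + i`, so individual replicates are reproducible in
#' isolation.
#'
#' @param kd Generating half-saturation constant, mM.
#' @param bmax Generating saturation signal, AU.
#' @param h Generating Hill coefficient.
#' @param concentrations Ligand concentrations, mM (>= 5 distinct values).
#' @param noise_sd Gaussian noise standard deviation, AU (default 0.005,
#'   about 3% of a phenol-like Bmax).
#' @param n_replicates Number of replicate curves.
#' @param seed Integer base seed.
#' @param ligand_name Label stored with the series.
#' @return Tibble: `concentration_mM`, `delta_a`, `replicate_id`,
#'   `ligand_name`; generating parameters in attribute `"true_parameters"`.
#' @export
make_titration <- function(kd, bmax, h, concentrations, noise_sd = 0.005,
                           n_replicates = 1, seed = 1,
                           ligand_name = "ligand") {
  stopifnot(kd > 0, bmax >= 0, h > 0, all(concentrations >= 0))
  out <- purrr::map_dfr(seq_len(n_replicates), function(i) {
    mu <- hill_model(concentrations, kd, bmax, h)
    eps <- if (noise_sd > 0) {
      with_seed(seed + i, rnorm(length(concentrations), 0, noise_sd))
    } else {
      rep(0, length(concentrations))
    }
    tibble(concentration_mM = concentrations, delta_a = mu + eps,
           replicate_id = i, ligand_name = ligand_name)
  })
  attr(out, "true_parameters") <- c(kd = kd, bmax = bmax, h = h)
  out
}

#' Log-spaced concentration series
#'
#' @param from,to Range endpoints, mM (> 0).
#' @param n Number of points.
#' @return Numeric vector of length `n`, log-spaced from `from` to `to`.
#' @export
log_spaced <- function(from, to, n = 12) {
  stopifnot(from > 0, to > from)
  exp(seq(log(from), log(to), length.out = n))
}

#' Fit every replicate of a titration table
#'
#' Applies [fit_hill()] per `replicate_id` and row-binds the parameter
#' tables.
#'
#' @param titration Tibble from [make_titration()] (or with the same
#'   columns).
#' @param init Optional starting values passed to [fit_hill()].
#' @return Tibble of per-replicate parameter rows (`replicate_id` first).
#' @export
fit_hill_replicates <- function(titration, init = NULL) {
  titration %>%
    group_by(.data$replicate_id) %>%
    dplyr::group_modify(function(d, key) fit_hill(d, init = init)$parameters) %>%
    ungroup()
}
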