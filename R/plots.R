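## ggplot2 methods for the package's result objects.

#' Plot a potential of mean force
#'
#' Free energy against the reaction coordinate with a +-1 sigma counting
#' ribbon where uncertainties are available.
#'
#' @param object A `pmf_profile` from [wham_pmf()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pmf_profile
#' @export
autoplot.pmf_profile <- function(object, ...) {
  prof <- filter(object$profile, is.finite(.data$free_energy))
  p <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$bin_center,
                                          y = .data$free_energy))
  if (any(is.finite(prof$uncertainty))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$free_energy - .data$uncertainty,
                   ymax = .data$free_energy + .data$uncertainty),
      alpha = 0.2)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "reaction coordinate (Å)",
                  y = "free energy (kcal/mol)")
}

#' Plot a Hill fit
#'
#' Data points and the fitted one-site Hill-slope curve on a log
#' concentration axis.
#'
#' @param object A `hill_fit` from [fit_hill()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hill_fit
#' @export
autoplot.hill_fit <- function(object, ...) {
  d <- object$data
  p <- object$parameters
  rng <- range(d$concentration_mM[d$concentration_mM > 0])
  curve <- tibble(concentration_mM = log_spaced(rng[1], rng[2], 200))
  curve$delta_a <- hill_model(curve$concentration_mM, p$kd, p$bmax, p$h)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$concentration_mM,
                                  y = .data$delta_a)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ligand concentration (mM)",
                  y = expression(Delta * A[444] * " (AU)"))
}

#' Plot a titration table
#'
#' One panel of replicate curves, points coloured by replicate.
#'
#' @param titration Tibble from [make_titration()].
#' @return A ggplot.
#' @export
plot_titration <- function(titration) {
  ggplot2::ggplot(titration,
                  ggplot2::aes(x = .data$concentration_mM, y = .data$delta_a,
                               colour = factor(.data$replicate_id))) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ligand concentration (mM)",
                  y = expression(Delta * A[444] * " (AU)"),
                  colour = "replicate")
}
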