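## Weighted histogram analysis method (WHAM) for umbrella-sampling windows.
##
## Windows are harmonic biases U_b(x) = k/2 (x - c)^2 on a 1-D reaction
## coordinate. The self-consistent equations
##   P(x_i) = n_i / sum_j N_j exp((f_j - b_ij)/kT)
##   exp(-f_j/kT) = sum_i P(x_i) exp(-b_ij/kT)
## are iterated until the window shifts f_j stop changing, then the PMF is
## F(x_i) = -kT ln P(x_i), referenced so the unbound plateau averages zero.

#' Umbrella window container
#'
#' Bundles umbrella windows (`center`, `spring_k`, `samples`) with the
#' sampling temperature and validates them: positive spring constants,
#' non-empty samples, and overlap of adjacent windows' sampled ranges
#' (a warning when ranges do not overlap).
#'
#' @param windows Tibble/data frame with columns `center`, `spring_k`
#'   (kcal/mol per unit^2) and a `samples` list-column of numeric vectors.
#' @param temperature Kelvin (default 300).
#' @return An `umbrella_windows` object.
#' @export
umbrella_windows <- function(windows, temperature = 300) {
  w <- as_tibble(windows)
  stopifnot(all(c("center", "spring_k", "samples") %in% names(w)))
  if (any(w$spring_k < 0)) abort("spring constants must be >= 0")
  n <- purrr::map_int(w$samples, length)
  if (any(n == 0)) abort("every window must contain at least one sample")
  w <- arrange(w, .data$center)
  if (nrow(w) > 1) {
    lo <- purrr::map_dbl(w$samples, min)
    hi <- purrr::map_dbl(w$samples, max)
    if (any(hi[-nrow(w)] < lo[-1])) {
      warn("adjacent umbrella windows have non-overlapping sample ranges")
    }
  }
  structure(list(windows = w, temperature = temperature),
            class = "umbrella_windows")
}

#' @export
print.umbrella_windows <- function(x, ...) {
  cat(sprintf("<umbrella_windows> %d windows, %d samples, T = %g K\n",
              nrow(x$windows), sum(purrr::map_int(x$windows$samples, length)),
              x$temperature))
  invisible(x)
}

#' Potential of mean force by WHAM
#'
#' Solves the WHAM equations self-consistently for the given umbrella
#' windows. Bins span the sampled coordinate range; empty bins interior to it
#' are flagged with a warning and carry NA free energy. The per-bin
#' uncertainty is the Poisson counting estimate kT/sqrt(n_i).
#'
#' @param windows An `umbrella_windows` object (or data frame acceptable to
#'   [umbrella_windows()]).
#' @param n_bins Number of histogram bins (default 100).
#' @param tol Convergence tolerance on the relative change of the window
#'   shifts (default 1e-8).
#' @param max_iter Iteration cap (default 1e5); non-convergence is an error
#'   reporting the last residual.
#' @param plateau_range Optional length-2 range over which the PMF is
#'   referenced to zero mean; when NULL the minimum is set to zero.
#' @param temperature Kelvin; defaults to the windows' temperature.
#' @return A `pmf_profile`: list with `profile` (tibble: `bin_center`,
#'   `free_energy`, `uncertainty`, `n_samples`), `shifts`, `n_iter`,
#'   `temperature`.
#' @export
wham_pmf <- function(windows, n_bins = 100, tol = 1e-8, max_iter = 1e5,
                     plateau_range = NULL, temperature = NULL) {
  if (!inherits(windows, "umbrella_windows")) windows <- umbrella_windows(windows)
  temperature <- temperature %||% windows$temperature
  kt <- rt_kcal(temperature)
  w <- windows$windows
  all_x <- unlist(w$samples)
  rng <- range(all_x)
  edges <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- matrix(0, n_bins, nrow(w))
  for (j in seq_len(nrow(w))) {
    counts[, j] <- tabulate(findInterval(w$samples[[j]], edges,
                                         rightmost.closed = TRUE), nbins = n_bins)
  }
  n_i <- rowSums(counts)
  N_j <- colSums(counts)
  bias <- outer(centers, seq_len(nrow(w)),
                function(x, j) 0.5 * w$spring_k[j] * (x - w$center[j])^2)
  f <- rep(0, nrow(w))
  expb <- exp(-bias / kt)  # n_bins x n_windows
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- expb %*% (N_j * exp(f / kt))
    p <- n_i / pmax(denom, .Machine$double.xmin)
    f_new <- -kt * log(pmax(as.numeric(t(expb) %*% p), .Machine$double.xmin))
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f)) / max(kt, max(abs(f_new)))
    f <- f_new
    if (resid < tol) break
    if (iter >= max_iter) {
      abort(sprintf("WHAM did not converge in %d iterations (last residual %.3g)",
                    iter, resid))
    }
  }
  occupied <- n_i > 0
  if (any(!occupied & centers > min(centers[occupied]) &
          centers < max(centers[occupied]))) {
    warn("empty bins interior to the sampled range; PMF has gaps")
  }
  fe <- rep(NA_real_, n_bins)
  fe[occupied] <- -kt * log(p[occupied])
  unc <- rep(NA_real_, n_bins)
  unc[occupied] <- kt / sqrt(n_i[occupied])
  if (!is.null(plateau_range)) {
    in_pl <- occupied & centers >= plateau_range[1] & centers <= plateau_range[2]
    if (!any(in_pl)) abort("plateau_range does not intersect the sampled bins")
    fe <- fe - mean(fe[in_pl])
  } else {
    fe <- fe - min(fe, na.rm = TRUE)
  }
  structure(list(profile = tibble(bin_center = centers, free_energy = fe,
                                  uncertainty = unc, n_samples = n_i),
                 shifts = f, n_iter = iter, temperature = temperature),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("<pmf_profile> %d bins, %d WHAM iterations, T = %g K\n",
              nrow(x$profile), x$n_iter, x$temperature))
  invisible(x)
}

#' @rdname wham_pmf
#' @param x A `pmf_profile`.
#' @param ... Unused.
#' @method tidy pmf_profile
#' @export
tidy.pmf_profile <- function(x, ...) x$profile

#' Read a lambda series from a TSV/CSV file
#'
#' Expects a header with columns `lambda`, `dudl_mean` and optionally
#' `dudl_sem`.
#'
#' @param path File path; the separator is sniffed from the header line.
#' @return Tibble suitable for [ti_integrate()].
#' @export
read_lambda_series <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  as_tibble(utils::read.table(path, header = TRUE, sep = sep,
                              comment.char = "#"))
}

#' Read umbrella windows from a directory of sample files
#'
#' Each file holds one window: comment lines `# center <value>` and
#' `# spring_k <value>`, then one coordinate sample per line.
#'
#' @param dir Directory of window files.
#' @param temperature Kelvin (default 300).
#' @return An `umbrella_windows` object.
#' @export
read_umbrella_windows <- function(dir, temperature = 300) {
  files <- sort(list.files(dir, full.names = TRUE))
  if (!length(files)) abort(paste0("no window files in ", dir))
  w <- purrr::map_dfr(files, function(f) {
    lines <- readLines(f)
    hdr <- grep("^#", lines, value = TRUE)
    get <- function(key) {
      m <- grep(paste0("^#\\s*", key), hdr, value = TRUE)
      if (!length(m)) abort(paste0("window file ", f, " lacks '# ", key, "'"))
      as.numeric(sub(paste0("^#\\s*", key, "\\s+"), "", m[1]))
    }
    tibble(center = get("center"), spring_k = get("spring_k"),
           samples = list(as.numeric(grep("^#", lines, value = TRUE, invert = TRUE))))
  })
  umbrella_windows(w, temperature)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
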