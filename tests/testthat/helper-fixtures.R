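# Shared fixtures and independent oracles, all generated in code.

# Canonical serotonin-loaded T3R3 hexamer (paper-style composition: 3 site I
# + 3 site III ligands, two tetrahedral zinc sites).
t3r3_serotonin_fixture <- function(seed = 1, jitter_amp = 0.012) {
  make_hexamer_fixture(
    monomer_states = c("T", "T", "T", "R", "R", "R"),
    ligands = tibble::tibble(
      name = "serotonin",
      site = c("I", "I", "I", "III", "III", "III"),
      monomer = c(4, 5, 6, 1, 2, 3)),
    zinc = c("tetrahedral", "tetrahedral"),
    seed = seed, jitter_amp = jitter_amp)
}

# Minimal atom-table constructor for hand-built geometric cases.
atoms_tbl <- function(atom_name, element, resid, chain, resno, xyz,
                      record = "ATOM") {
  tibble::tibble(
    model = 1L, record = record, atom_id = seq_along(atom_name),
    atom_name = atom_name, element = element, resid = resid, chain = chain,
    resno = as.integer(resno), x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, altloc = "")
}

# Brute-force rigid-fit RMSD oracle: numeric minimisation over Euler angles
# and translation, independent of the SVD route.
brute_force_rmsd <- function(a, b) {
  rot_from_angles <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    rz %*% ry %*% rx
  }
  obj <- function(par) {
    moved <- b %*% t(rot_from_angles(par[1:3]))
    moved <- sweep(moved, 2, -par[4:6])
    sqrt(mean(rowSums((moved - a)^2)))
  }
  best <- Inf
  for (start in list(rep(0, 6), c(0.5, -0.3, 0.8, 0, 0, 0),
                     c(2, 1, -1, 1, -1, 1))) {
    fit <- stats::optim(start, obj, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

# Direct WHAM fixed-point oracle on pre-binned counts: naive iteration of the
# self-consistent equations written independently of the package routine.
brute_force_wham_shifts <- function(counts, centers, spring_k, window_centers,
                                    kt, n_iter = 20000) {
  n_bins <- nrow(counts)
  n_w <- ncol(counts)
  n_i <- rowSums(counts)
  N_j <- colSums(counts)
  f <- rep(0, n_w)
  for (it in seq_len(n_iter)) {
    p <- numeric(n_bins)
    for (i in seq_len(n_bins)) {
      den <- 0
      for (j in seq_len(n_w)) {
        b <- 0.5 * spring_k[j] * (centers[i] - window_centers[j])^2
        den <- den + N_j[j] * exp((f[j] - b) / kt)
      }
      p[i] <- n_i[i] / den
    }
    f_new <- numeric(n_w)
    for (j in seq_len(n_w)) {
      s <- 0
      for (i in seq_len(n_bins)) {
        b <- 0.5 * spring_k[j] * (centers[i] - window_centers[j])^2
        s <- s + p[i] * exp(-b / kt)
      }
      f_new[j] <- -kt * log(s)
    }
    f_new <- f_new - f_new[1]
    if (max(abs(f_new - f)) < 1e-15) {
      f <- f_new
      break
    }
    f <- f_new
  }
  f
}
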