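## Synthetic hexamer fixtures: geometric test articles, not physical models.
##
## Backbones are built by sequential torsion geometry (helix phi = -57,
## psi = -47; extended phi = -120, psi = +120; type II' turn torsions at
## B7-B8 for T monomers). Six monomers are placed 3-fold symmetrically in two
## trimers; zinc shells, site I/III ligands and the specific side-chain atoms
## the classifiers need (His Ne2, Cys SG, fingerprint side chains) are placed
## directly at their anchor geometries.

## standard backbone geometry (Angstroms / degrees)
BB_N_CA <- 1.458
BB_CA_C <- 1.525
BB_C_N <- 1.329
BB_C_O <- 1.231
ANG_N_CA_C <- 111.2
ANG_CA_C_N <- 116.2
ANG_C_N_CA <- 121.7
ANG_CA_C_O <- 120.8

INSULIN_A_SEQ <- c("GLY", "ILE", "VAL", "GLU", "GLN", "CYS", "CYS", "THR",
                   "SER", "ILE", "CYS", "SER", "LEU", "TYR", "GLN", "LEU",
                   "GLU", "ASN", "TYR", "CYS", "ASN")
INSULIN_B_SEQ <- c("PHE", "VAL", "ASN", "GLN", "HIS", "LEU", "CYS", "GLY",
                   "SER", "HIS", "LEU", "VAL", "GLU", "ALA", "LEU", "TYR",
                   "LEU", "VAL", "CYS", "GLY", "GLU", "ARG", "GLY", "PHE",
                   "PHE", "TYR", "THR", "PRO", "LYS", "THR")

## Idealised planar serotonin heavy-atom template (indole + 5-OH +
## aminoethyl); pyrrole ring is N1-C2-C3-C3A-C7A.
SEROTONIN_TEMPLATE <- tibble::tibble(
  atom_name = c("N1", "C2", "C3", "C3A", "C4", "C5", "C6", "C7", "C7A",
                "O5", "CB", "CC", "NZ"),
  element = c("N", "C", "C", "C", "C", "C", "C", "C", "C", "O", "C", "C", "N"),
  x = c(-0.291, -1.683, -2.253, -1.212, -1.212, 0.000, 1.212, 1.212, 0.000,
        0.000, -3.720, -5.020, -6.320),
  y = c(2.769, 2.915, 1.636, 0.700, -0.700, -1.400, -0.700, 0.700, 1.400,
        -2.760, 1.324, 1.724, 1.324),
  z = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0.600, 1.200)
)

PHENOL_TEMPLATE <- tibble::tibble(
  atom_name = c("C1", "C2", "C3", "C4", "C5", "C6", "O1"),
  element = c(rep("C", 6), "O"),
  x = c(0.000, 1.212, 1.212, 0.000, -1.212, -1.212, 0.000),
  y = c(1.400, 0.700, -0.700, -1.400, -0.700, 0.700, 2.760),
  z = rep(0, 7)
)

## torsion recipe per conformational state for the 30-residue B chain
state_recipe <- function(state) {
  phi <- rep(-120, 30)
  psi <- rep(120, 30)
  hel <- switch(state,
    R = 1:19,
    Rf = 3:19,
    T = 9:19,
    abort(paste0("unknown monomer state '", state, "'")))
  phi[hel] <- -57
  psi[hel] <- -47
  if (state == "T") {  # type II' beta-turn at B7-B8
    phi[7] <- 60; psi[7] <- -120
    phi[8] <- -80; psi[8] <- 0
  }
  list(phi = phi, psi = psi)
}

## Backbone (N, CA, C, O per residue) from phi/psi torsions, omega = 180.
build_chain_backbone <- function(phi, psi) {
  n <- length(phi)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(BB_N_CA, 0, 0)
  a <- deg2rad(ANG_N_CA_C)
  C[1, ] <- CA[1, ] + BB_CA_C * c(-cos(a), sin(a), 0)
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], BB_C_N,
                         ANG_CA_C_N, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], BB_N_CA,
                          ANG_C_N_CA, 180)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], BB_CA_C,
                         ANG_N_CA_C, phi[i])
  }
  for (i in 1:n) O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], BB_C_O,
                                      ANG_CA_C_O, psi[i] + 180)
  purrr::map_dfr(1:n, function(i) {
    tibble(resno = i, atom_name = c("N", "CA", "C", "O"),
           element = c("N", "C", "C", "O"),
           x = c(N[i, 1], CA[i, 1], C[i, 1], O[i, 1]),
           y = c(N[i, 2], CA[i, 2], C[i, 2], O[i, 2]),
           z = c(N[i, 3], CA[i, 3], C[i, 3], O[i, 3]))
  })
}

## Rodrigues rotation taking unit direction a onto unit direction b.
rotation_between <- function(a, b) {
  a <- vec_unit(a); b <- vec_unit(b)
  v <- vec_cross(a, b)
  cth <- sum(a * b)
  if (vec_len(v) < 1e-12) {
    if (cth > 0) return(diag(3))
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- vec_unit(vec_cross(a, p))
    return(2 * outer(axis, axis) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * (1 / (1 + cth))
}

## One insulin monomer (A + B chain backbones + Cys SG pair) in a local frame.
build_monomer <- function(state) {
  rec_b <- state_recipe(state)
  b <- build_chain_backbone(rec_b$phi, rec_b$psi) %>%
    mutate(chain_role = "B", resid = INSULIN_B_SEQ[.data$resno])
  phi_a <- rep(-120, 21); psi_a <- rep(120, 21)
  phi_a[2:19] <- -57; psi_a[2:19] <- -47
  a <- build_chain_backbone(phi_a, psi_a) %>%
    mutate(chain_role = "A", resid = INSULIN_A_SEQ[.data$resno])

  bxyz <- as.matrix(b[, c("x", "y", "z")])
  cen_b <- colMeans(bxyz)
  pa1 <- svd(sweep(bxyz, 2, cen_b))$v[, 1]
  end_dir <- bxyz[which(b$resno == 19 & b$atom_name == "CA")[1], ] - cen_b
  u <- end_dir - sum(end_dir * pa1) * pa1   # lateral outward direction at B19
  u <- if (vec_len(u) < 1e-6) vec_unit(vec_cross(pa1, c(0, 0, 1))) else vec_unit(u)
  b19_ca <- bxyz[which(b$resno == 19 & b$atom_name == "CA")[1], ]
  b19_sg <- b19_ca + 1.82 * u

  axyz <- as.matrix(a[, c("x", "y", "z")])
  cen_a <- colMeans(axyz)
  a20_ca <- axyz[which(a$resno == 20 & a$atom_name == "CA")[1], ]
  body_dir <- vec_unit(cen_a - a20_ca)
  rot <- rotation_between(body_dir, u)
  a20_sg_local <- a20_ca - 1.82 * body_dir
  target_sg <- b19_sg + 2.05 * u
  shift <- target_sg - as.numeric(rot %*% a20_sg_local)
  axyz_new <- transform_coords(axyz, rot, shift)
  a$x <- axyz_new[, 1]; a$y <- axyz_new[, 2]; a$z <- axyz_new[, 3]
  a20_sg <- as.numeric(rot %*% a20_sg_local) + shift

  extras <- tibble(
    chain_role = c("B", "A"), resno = c(19L, 20L),
    resid = c("CYS", "CYS"), atom_name = c("SG", "SG"), element = c("S", "S"),
    x = c(b19_sg[1], a20_sg[1]), y = c(b19_sg[2], a20_sg[2]),
    z = c(b19_sg[3], a20_sg[3]))
  bind_rows(a, b, extras) %>%
    select("chain_role", "resno", "resid", "atom_name", "element", "x", "y", "z")
}

ligand_template <- function(name) {
  switch(name,
    serotonin = dplyr::mutate(SEROTONIN_TEMPLATE, resid = "SRO"),
    phenol = dplyr::mutate(PHENOL_TEMPLATE, resid = "IPH"),
    abort(paste0("no ligand template for '", name, "'")))
}

## Orthonormal frame with first axis u.
frame_about <- function(u) {
  u <- vec_unit(u)
  p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- vec_unit(vec_cross(u, p))
  e3 <- vec_cross(u, e2)
  list(u = u, e2 = e2, e3 = e3)
}

#' Build a synthetic insulin hexamer fixture
#'
#' Constructs an idealised insulin hexamer as a geometric test article: six
#' torsion-built monomers (any mix of T/Rf/R), 3-fold arranged in two
#' trimers, optional axial zinc sites with tetrahedral (3 His Ne2 + axial
#' Cl) or octahedral (3 His Ne2 + 3 waters) shells, and serotonin/phenol
#' ligands placed at site I or site III anchor geometry (site I: ligand OH
#' oxygen at `oh_dist` from the Cys A6 carbonyl O, His B5 Ne2 at `pi_dist`
#' from the pyrrole centroid; site III: ligand between Tyr A14 / Leu A13
#' with its OH near Glu A17). Deterministic for a given seed; a small seeded
#' coordinate jitter (uniform within `jitter_amp`) distinguishes seeds.
#'
#' @param monomer_states Character vector of six states in `{"T","Rf","R"}`
#'   (monomers 1-3 form the top trimer, 4-6 the bottom).
#' @param ligands Optional tibble with columns `name` ("serotonin" or
#'   "phenol"), `site` ("I" or "III"), `monomer` (1-6), and optionally
#'   `oh_dist`, `pi_dist` (anchor distances, 2-4 Angstroms).
#' @param zinc Character vector (length 0-2) of zinc geometries,
#'   `"tetrahedral"` or `"octahedral"`; entry 1 is the top-trimer site.
#' @param seed Integer seed controlling the jitter.
#' @param jitter_amp Half-width of the uniform coordinate jitter in
#'   Angstroms (default 0.012; use 0 for exact anchor distances).
#' @param path Optional path; when given the fixture is also written as PDB.
#' @return A `hex_structure`.
#' @export
make_hexamer_fixture <- function(monomer_states = c("T", "T", "T", "R", "R", "R"),
                                 ligands = NULL,
                                 zinc = c("tetrahedral", "tetrahedral"),
                                 seed = 1, jitter_amp = 0.012, path = NULL) {
  if (length(monomer_states) != 6) abort("exactly six monomer states are required")
  if (!all(monomer_states %in% c("T", "Rf", "R"))) {
    abort("monomer states must be in {T, Rf, R}")
  }
  if (length(zinc) > 2) abort("at most two zinc sites are supported")
  radius <- 30; z_off <- 12; zn_z <- 24

  mono_atoms <- purrr::map_dfr(1:6, function(m) {
    loc <- build_monomer(monomer_states[m])
    xyz <- as.matrix(loc[, c("x", "y", "z")])
    xyz <- sweep(xyz, 2, colMeans(xyz))
    az <- if (m <= 3) 120 * (m - 1) else 60 + 120 * (m - 4)
    zz <- if (m <= 3) z_off else -z_off
    rot <- rotation_about_z(az)
    pos <- as.numeric(rot %*% c(radius, 0, 0)) + c(0, 0, zz)
    xyz <- transform_coords(xyz, rot, pos)
    loc %>% mutate(
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      chain = ifelse(.data$chain_role == "A", LETTERS[2 * m - 1], LETTERS[2 * m]),
      monomer = m, record = "ATOM") %>%
      select(-"chain_role")
  })

  het_rows <- list()
  ## zinc shells on the 3-fold axis
  if (length(zinc)) {
    for (k in seq_along(zinc)) {
      top <- k == 1
      zn_pos <- c(0, 0, if (top) zn_z else -zn_z)
      axis_dir <- if (top) c(0, 0, 1) else c(0, 0, -1)
      trimer <- if (top) 1:3 else 4:6
      geom <- zinc[k]
      if (geom == "tetrahedral") {
        r3 <- 1 / sqrt(3)
        verts <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * r3
        rot <- rotation_between(c(1, 1, 1) * r3, axis_dir)
        verts <- verts %*% t(rot)
        cl <- zn_pos + 2.25 * verts[1, ]
        his <- sweep(2.05 * verts[2:4, ], 2, zn_pos, "+")
        het_rows[[length(het_rows) + 1]] <- tibble(
          record = "HETATM", atom_name = "CL", element = "Cl", resid = "CL",
          chain = "Z", resno = NA_integer_, x = cl[1], y = cl[2], z = cl[3])
      } else if (geom == "octahedral") {
        rot <- rotation_between(vec_unit(c(1, 1, 1)), axis_dir)
        hd <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) %*% t(rot)
        wd <- -hd
        his <- sweep(2.10 * hd, 2, zn_pos, "+")
        wat <- sweep(2.15 * wd, 2, zn_pos, "+")
        het_rows[[length(het_rows) + 1]] <- tibble(
          record = "HETATM", atom_name = "O", element = "O", resid = "HOH",
          chain = "Z", resno = NA_integer_,
          x = wat[, 1], y = wat[, 2], z = wat[, 3])
      } else {
        abort(paste0("unknown zinc geometry '", geom, "'"))
      }
      het_rows[[length(het_rows) + 1]] <- tibble(
        record = "HETATM", atom_name = "ZN", element = "Zn", resid = "ZN",
        chain = "Z", resno = NA_integer_,
        x = zn_pos[1], y = zn_pos[2], z = zn_pos[3])
      ## His B10 Ne2 of the trimer's monomers form the protein face
      his_rows <- purrr::map_dfr(1:3, function(i) {
        m <- trimer[i]
        tibble(record = "ATOM", atom_name = "NE2", element = "N",
               resid = "HIS", chain = LETTERS[2 * m], resno = 10L,
               monomer = m, x = his[i, 1], y = his[i, 2], z = his[i, 3])
      })
      mono_atoms <- bind_rows(mono_atoms, his_rows)
    }
  }

  ## ligands + fingerprint decoration side-chain atoms
  lig_rows <- list()
  if (!is.null(ligands) && nrow(ligands)) {
    ligands <- as_tibble(ligands)
    if (!"oh_dist" %in% names(ligands)) ligands$oh_dist <- NA_real_
    if (!"pi_dist" %in% names(ligands)) ligands$pi_dist <- NA_real_
    prot_cen <- colMeans(as.matrix(mono_atoms[, c("x", "y", "z")]))
    for (i in seq_len(nrow(ligands))) {
      site <- ligands$site[i]
      m <- ligands$monomer[i]
      oh_dist <- ligands$oh_dist[i]
      if (is.na(oh_dist)) oh_dist <- if (site == "I") 2.42 else 3.20
      pi_dist <- ligands$pi_dist[i]
      if (is.na(pi_dist)) pi_dist <- 3.50
      if (oh_dist < 2 || oh_dist > 4 || pi_dist < 2 || pi_dist > 4) {
        abort("anchor distances must lie within [2, 4] Angstroms")
      }
      a_chain <- LETTERS[2 * m - 1]
      b_chain <- LETTERS[2 * m]
      anchor_resno <- if (site == "I") 6L else 14L
      anchor <- mono_atoms %>%
        filter(.data$chain == a_chain, .data$resno == anchor_resno,
               .data$atom_name == "O")
      carb <- mono_atoms %>%
        filter(.data$chain == a_chain, .data$resno == anchor_resno,
               .data$atom_name == "C")
      p0 <- c(anchor$x[1], anchor$y[1], anchor$z[1])
      ## approach radially away from the host A-chain helix axis so the
      ## ligand body clears the chain
      host_a <- filter(mono_atoms, .data$chain == a_chain, .data$record == "ATOM")
      axyz <- as.matrix(host_a[, c("x", "y", "z")])
      cen_a <- colMeans(axyz)
      ax <- svd(sweep(axyz, 2, cen_a))$v[, 1]
      radial <- (p0 - cen_a) - sum((p0 - cen_a) * ax) * ax
      if (vec_len(radial) < 1e-6) radial <- vec_unit(p0 - prot_cen)
      fr <- frame_about(radial)
      rot <- cbind(fr$e2, fr$u, fr$e3)  # template x->e2, y->u (outward), z->e3
      tpl <- ligand_template(ligands$name[i])
      oh_name <- if (ligands$name[i] == "serotonin") "O5" else "O1"
      oh_local <- as.numeric(tpl[tpl$atom_name == oh_name, c("x", "y", "z")])
      txyz <- as.matrix(tpl[, c("x", "y", "z")])
      target_oh <- p0 + oh_dist * fr$u
      gxyz <- transform_coords(sweep(txyz, 2, oh_local), rot, target_oh)
      lig_chain <- "X"
      lig_resno <- 100L + i
      lig_rows[[length(lig_rows) + 1]] <- tibble(
        record = "HETATM", atom_name = tpl$atom_name, element = tpl$element,
        resid = tpl$resid[1], chain = lig_chain, resno = lig_resno,
        x = gxyz[, 1], y = gxyz[, 2], z = gxyz[, 3])
      gpos <- function(nm) as.numeric(gxyz[tpl$atom_name == nm, ])
      deco <- function(ch, rn, resid, nm, el, pos, m) {
        tibble(record = "ATOM", atom_name = nm, element = el, resid = resid,
               chain = ch, resno = rn, monomer = m,
               x = pos[1], y = pos[2], z = pos[3])
      }
      if (ligands$name[i] == "serotonin" && site == "I") {
        pyr <- colMeans(gxyz[tpl$atom_name %in% c("N1", "C2", "C3", "C3A", "C7A"), ])
        mono_atoms <- bind_rows(mono_atoms,
          deco(b_chain, 5L, "HIS", "NE2", "N", pyr + pi_dist * fr$e3, m),
          deco(a_chain, 9L, "SER", "OG", "O", gpos("O5") + 3.39 * fr$e3, m),
          deco(a_chain, 11L, "CYS", "SG", "S", gpos("C7") - 3.40 * fr$e3, m),
          deco(b_chain, 17L, "LEU", "CD1", "C", gpos("C4") - 3.45 * fr$e3, m),
          deco(b_chain, 21L, "GLU", "OE1", "O", gpos("NZ") + 2.75 * fr$e3, m))
      } else if (site == "I") {  # phenol: same pocket, no pyrrole anchor
        mono_atoms <- bind_rows(mono_atoms,
          deco(a_chain, 9L, "SER", "OG", "O", gpos(oh_name) + 3.39 * fr$e3, m),
          deco(a_chain, 11L, "CYS", "SG", "S", gpos("C3") - 3.40 * fr$e3, m),
          deco(b_chain, 5L, "HIS", "NE2", "N", gpos("C1") + 3.50 * fr$e3, m),
          deco(b_chain, 17L, "LEU", "CD1", "C", gpos("C5") - 3.45 * fr$e3, m),
          deco(b_chain, 21L, "GLU", "OE1", "O", gpos("C4") + 3.30 * fr$e3, m))
      } else if (site == "III") {
        nz <- if (ligands$name[i] == "serotonin") "NZ" else "C4"
        ring <- if (ligands$name[i] == "serotonin") "C4" else "C2"
        mono_atoms <- bind_rows(mono_atoms,
          deco(a_chain, 17L, "GLU", "OE1", "O", gpos(oh_name) + 2.96 * fr$e3, m),
          deco(b_chain, 22L, "ARG", "NH1", "N", gpos(nz) + 2.70 * fr$e3, m),
          deco(a_chain, 13L, "LEU", "CD1", "C", gpos(ring) - 3.50 * fr$e3, m))
      } else {
        abort(paste0("unsupported ligand site '", site, "'"))
      }
    }
  }

  atoms <- bind_rows(c(list(mono_atoms), lig_rows, het_rows))
  ## hetero residue numbering on chain Z
  hz <- which(atoms$chain == "Z")
  if (length(hz)) atoms$resno[hz] <- 500L + seq_along(hz)

  ## feasibility: ligand atoms must not clash with anything outside their
  ## own residue
  lig_idx <- which(atoms$record == "HETATM" & !atoms$resid %in% NON_LIGAND_HET)
  if (length(lig_idx)) {
    for (ii in lig_idx) {
      same <- atoms$chain == atoms$chain[ii] & atoms$resno == atoms$resno[ii] &
        atoms$record == "HETATM"
      ox <- as.matrix(atoms[!same, c("x", "y", "z")])
      d <- sqrt(colSums((t(ox) - c(atoms$x[ii], atoms$y[ii], atoms$z[ii]))^2))
      if (any(d < 1.8)) {
        bad <- which.min(d)
        abort(sprintf(
          "infeasible anchor set: ligand atom %s %s%d clashes with %s %s%d %s (%.2f A)",
          atoms$atom_name[ii], atoms$chain[ii], atoms$resno[ii],
          atoms$resid[!same][bad], atoms$chain[!same][bad],
          atoms$resno[!same][bad], atoms$atom_name[!same][bad], min(d)))
      }
    }
  }

  atoms <- with_seed(seed, {
    n <- nrow(atoms)
    atoms %>% mutate(
      x = .data$x + runif(n, -jitter_amp, jitter_amp),
      y = .data$y + runif(n, -jitter_amp, jitter_amp),
      z = .data$z + runif(n, -jitter_amp, jitter_amp))
  })
  atoms <- atoms %>%
    mutate(model = 1L, occupancy = 1, altloc = "",
           x = round(.data$x, 3), y = round(.data$y, 3), z = round(.data$z, 3)) %>%
    arrange(.data$chain, .data$resno,
            match(.data$atom_name, c("N", "CA", "C", "O"))) %>%
    mutate(atom_id = dplyr::row_number()) %>%
    select("model", "record", "atom_id", "atom_name", "element", "resid",
           "chain", "resno", "x", "y", "z", "occupancy", "altloc")
  st <- new_structure(atoms, 1L, "PDB")
  if (!is.null(path)) write_structure(st, path)
  st
}

#' Build a single-monomer fixture
#'
#' One torsion-built insulin monomer (chains A and B) in the given
#' conformational state; convenient for state-classifier tests and examples.
#'
#' @param state `"T"`, `"Rf"` or `"R"`.
#' @return A `hex_structure` with two chains.
#' @export
make_monomer_fixture <- function(state = "T") {
  loc <- build_monomer(state)
  atoms <- loc %>%
    mutate(model = 1L, record = "ATOM", occupancy = 1, altloc = "",
           chain = ifelse(.data$chain_role == "A", "A", "B")) %>%
    arrange(.data$chain, .data$resno,
            match(.data$atom_name, c("N", "CA", "C", "O"))) %>%
    mutate(atom_id = dplyr::row_number()) %>%
    select("model", "record", "atom_id", "atom_name", "element", "resid",
           "chain", "resno", "x", "y", "z", "occupancy", "altloc")
  new_structure(atoms, 1L, "PDB")
}
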