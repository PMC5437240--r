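## Insulin monomer identification and T/Rf/R conformational-state assignment.
##
## Canonical numbering: the 21-residue chain is the A chain (A1..A21), the
## 30-residue chain is the B chain (B1..B30). The conformational state is read
## off the B-chain N terminus: helix from B1 (R), helix from B3/B4 with frayed
## B1-B2 (Rf), extended B1-B6 with a B7-B10 turn into the invariant B9-B19
## helix (T).

PHI_HELIX_RANGE <- c(-100, -30)
PSI_HELIX_RANGE <- c(-80, -5)
MIN_HELIX_RUN <- 4L
SS_CUTOFF <- 3.0  # Cys A20 - Cys B19 sulfur pairing cutoff, Angstroms

## Map protein chains to insulin chain types by length (21 -> A, 30 -> B).
chain_types <- function(atoms) {
  atoms %>%
    filter(.data$record == "ATOM") %>%
    distinct(.data$chain, .data$resno) %>%
    dplyr::count(.data$chain, name = "n_res") %>%
    mutate(chain_type = dplyr::case_when(
      .data$n_res == 21 ~ "A",
      .data$n_res == 30 ~ "B",
      TRUE ~ NA_character_
    ))
}

#' Identify insulin monomers by disulfide pairing
#'
#' Pairs each A chain (21 residues) with the B chain (30 residues) whose
#' Cys A20 - Cys B19 sulfur-sulfur distance is smallest and within 3.0
#' Angstroms. Unpaired chains are reported with a warning and omitted.
#'
#' @param structure A `hex_structure` or atom tibble (model 1 is used).
#' @return Tibble with one row per monomer: `monomer_id`, `a_chain`,
#'   `b_chain`, `ss_distance` (Angstroms), sorted by A-chain id.
#' @export
identify_monomers <- function(structure) {
  at <- as_atoms(structure, model = 1L)
  ct <- chain_types(at)
  a_chains <- ct$chain[which(ct$chain_type == "A")]
  b_chains <- ct$chain[which(ct$chain_type == "B")]
  empty <- tibble(monomer_id = integer(), a_chain = character(),
                  b_chain = character(), ss_distance = numeric())
  if (!length(a_chains) || !length(b_chains)) {
    warn("no pairable A(21-residue)/B(30-residue) chains found")
    return(empty)
  }
  sg <- function(ch, rn) {
    row <- filter(at, .data$chain == ch, .data$resno == rn,
                  .data$atom_name == "SG")
    if (!nrow(row)) return(NULL)
    c(row$x[1], row$y[1], row$z[1])
  }
  a_sg <- purrr::map(a_chains, sg, rn = 20L)
  b_sg <- purrr::map(b_chains, sg, rn = 19L)
  keep_a <- !purrr::map_lgl(a_sg, is.null)
  keep_b <- !purrr::map_lgl(b_sg, is.null)
  if (!all(keep_a) || !all(keep_b)) {
    warn("chains lacking Cys A20/B19 SG atoms cannot be paired and were dropped")
  }
  a_chains <- a_chains[keep_a]; a_sg <- a_sg[keep_a]
  b_chains <- b_chains[keep_b]; b_sg <- b_sg[keep_b]
  if (!length(a_chains) || !length(b_chains)) return(empty)
  dmat <- matrix(Inf, length(a_chains), length(b_chains))
  for (i in seq_along(a_chains)) {
    for (j in seq_along(b_chains)) dmat[i, j] <- vec_len(a_sg[[i]] - b_sg[[j]])
  }
  pairs <- list()
  repeat {
    if (!any(is.finite(dmat)) || min(dmat) > SS_CUTOFF) break
    idx <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
    pairs[[length(pairs) + 1]] <- tibble(
      a_chain = a_chains[idx[1]], b_chain = b_chains[idx[2]],
      ss_distance = dmat[idx[1], idx[2]])
    dmat[idx[1], ] <- Inf
    dmat[, idx[2]] <- Inf
  }
  if (!length(pairs)) {
    warn("no A/B chain pair within the 3.0 A disulfide cutoff")
    return(empty)
  }
  out <- bind_rows(pairs) %>% arrange(.data$a_chain)
  n_unpaired <- (length(a_chains) - nrow(out)) + (length(b_chains) - nrow(out))
  if (n_unpaired > 0) {
    warn(sprintf("%d chain(s) left unpaired under the 3.0 A S-S cutoff", n_unpaired))
  }
  mutate(out, monomer_id = dplyr::row_number()) %>%
    select("monomer_id", "a_chain", "b_chain", "ss_distance")
}

#' Backbone phi/psi dihedrals
#'
#' Computes per-residue phi and psi (degrees, in (-180, 180]) for each protein
#' chain. Phi is undefined for a chain's first residue and psi for its last;
#' residues missing any of N, CA, C propagate NA to the affected dihedrals.
#'
#' @param structure A `hex_structure` or atom tibble.
#' @param chain Optional chain id to restrict to.
#' @return Tibble: `chain`, `resno`, `phi`, `psi`.
#' @export
backbone_dihedrals <- function(structure, chain = NULL) {
  at <- as_atoms(structure, model = 1L) %>% filter(.data$record == "ATOM")
  if (!is.null(chain)) at <- filter(at, .data$chain == !!chain)
  purrr::map_dfr(split(at, at$chain), chain_dihedrals)
}

chain_dihedrals <- function(at) {
  resnos <- sort(unique(at$resno))
  get_atom <- function(rn, nm) {
    row <- at[at$resno == rn & at$atom_name == nm, , drop = FALSE]
    if (!nrow(row)) return(NULL)
    c(row$x[1], row$y[1], row$z[1])
  }
  n <- length(resnos)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    Ni <- get_atom(resnos[i], "N")
    CAi <- get_atom(resnos[i], "CA")
    Ci <- get_atom(resnos[i], "C")
    if (i > 1 && resnos[i] - resnos[i - 1] == 1) {
      Cprev <- get_atom(resnos[i - 1], "C")
      if (!is.null(Cprev) && !is.null(Ni) && !is.null(CAi) && !is.null(Ci)) {
        phi[i] <- torsion_angle(Cprev, Ni, CAi, Ci)
      }
    }
    if (i < n && resnos[i + 1] - resnos[i] == 1) {
      Nnext <- get_atom(resnos[i + 1], "N")
      if (!is.null(Ni) && !is.null(CAi) && !is.null(Ci) && !is.null(Nnext)) {
        psi[i] <- torsion_angle(Ni, CAi, Ci, Nnext)
      }
    }
  }
  tibble(chain = at$chain[1], resno = resnos, phi = phi, psi = psi)
}

in_range <- function(x, rng) !is.na(x) & x >= rng[1] & x <= rng[2]

## Per-residue helicity from the alpha-basin dihedral windows. A chain-start
## residue with undefined phi counts as helical on psi alone (a helix running
## from residue 1 has no phi there to test).
residue_helicity <- function(dih) {
  phi_ok <- in_range(dih$phi, PHI_HELIX_RANGE)
  psi_ok <- in_range(dih$psi, PSI_HELIX_RANGE)
  first <- seq_len(nrow(dih)) == 1
  psi_ok & (phi_ok | (is.na(dih$phi) & first))
}

#' Classify one monomer's conformational state
#'
#' Finds the longest continuous helical run (>= 4 residues, dihedral windows
#' phi in \[-100, -30\], psi in \[-80, -5\]) ending at or beyond B17 and labels
#' the monomer by the run's first residue: R (helix from B1-B2), Rf (B3-B4),
#' T (B7 or later with B1-B6 non-helical), otherwise undetermined.
#'
#' @param structure A `hex_structure` or atom tibble.
#' @param b_chain Chain id of the monomer's B chain.
#' @return Tibble with one row: `b_chain`, `state`, `helix_start`.
#' @export
classify_monomer_state <- function(structure, b_chain) {
  at <- as_atoms(structure, model = 1L)
  bb <- filter(at, .data$record == "ATOM", .data$chain == b_chain)
  undet <- tibble(b_chain = b_chain, state = "undetermined", helix_start = NA_integer_)
  if (!nrow(bb)) return(undet)
  canon <- sort(unique(bb$resno))
  have_bb <- purrr::map_lgl(1:19, function(rn) {
    rows <- bb[bb$resno == rn, ]
    all(c("N", "CA", "C") %in% rows$atom_name)
  })
  if (length(canon) < 19 || !all(have_bb)) return(undet)
  dih <- chain_dihedrals(bb)
  hel <- residue_helicity(dih)
  runs <- rle(hel)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ok <- runs$values & runs$lengths >= MIN_HELIX_RUN & ends >= 17
  if (!any(ok)) return(undet)
  pick <- which(ok)[which.max(runs$lengths[ok])]
  helix_start <- dih$resno[starts[pick]]
  state <- if (helix_start <= 2) {
    "R"
  } else if (helix_start %in% c(3, 4)) {
    "Rf"
  } else if (helix_start >= 7 && !any(hel[dih$resno <= 6])) {
    "T"
  } else {
    "undetermined"
  }
  tibble(b_chain = b_chain, state = state, helix_start = as.integer(helix_start))
}

#' Hexamer-level state from six monomer labels
#'
#' @param states Character vector of exactly six labels in
#'   `{"T", "Rf", "R", "undetermined"}`.
#' @return One of `"T6"`, `"T3Rf3"`, `"T3R3"`, `"R6"`, `"mixed"`,
#'   `"undetermined"`.
#' @export
classify_hexamer <- function(states) {
  if (length(states) != 6) abort("exactly six monomer states are required")
  if (any(states == "undetermined")) return("undetermined")
  tab <- table(factor(states, levels = c("T", "Rf", "R")))
  if (tab[["T"]] == 6) return("T6")
  if (tab[["R"]] == 6) return("R6")
  if (tab[["T"]] == 3 && tab[["R"]] == 3) return("T3R3")
  if (tab[["T"]] == 3 && tab[["Rf"]] == 3) return("T3Rf3")
  "mixed"
}

#' Full conformational-state assignment of a hexamer structure
#'
#' Convenience wrapper: identifies monomers, classifies each, and (when six
#' monomers are present) assigns the hexamer-level state.
#'
#' @param structure A `hex_structure` or atom tibble.
#' @return List with `monomers` (tibble: monomer id, chains, state,
#'   helix_start) and `hexamer_state`.
#' @export
classify_states <- function(structure) {
  mons <- identify_monomers(structure)
  if (!nrow(mons)) {
    return(list(monomers = mons, hexamer_state = "undetermined"))
  }
  states <- purrr::map_dfr(mons$b_chain, function(bc) {
    classify_monomer_state(structure, bc)
  })
  monomers <- left_join(mons, states, by = "b_chain")
  hex_state <- if (nrow(monomers) == 6) classify_hexamer(monomers$state) else "undetermined"
  list(monomers = monomers, hexamer_state = hex_state)
}
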