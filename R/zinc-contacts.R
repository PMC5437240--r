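## Zinc coordination geometry, hydrogen bonds and pi contacts.

ZN_CUTOFF <- 2.8       # Zn ligand-shell cutoff, Angstroms
HB_CUTOFF <- 3.6       # heavy-atom donor-acceptor cutoff, Angstroms
PI_CUTOFF <- 3.8       # N/O to ring-centroid cutoff, Angstroms
TET_ANGLE <- 109.47
COORD_ELEMENTS <- c("N", "O", "S", "Cl", "Br", "F", "I")

#' Classify zinc coordination sites
#'
#' For every Zn atom, collects coordinating N/O/S/halide atoms within
#' `cutoff`, and labels the site geometry: coordination number 4 with mean
#' inter-ligand angle within 15 degrees of 109.47 is tetrahedral; coordination
#' 5-6 with angles populating 90/180 degrees is octahedral; anything else is
#' "other". A non-His ligand sitting opposite the His face (on the local
#' 3-fold axis) is reported as the axial species.
#'
#' @param structure A `hex_structure` or atom tibble.
#' @param cutoff Ligand-shell cutoff in Angstroms (default 2.8).
#' @return Tibble, one row per Zn: position, `coordination_number`,
#'   `geometry`, `axial_species`, and a `ligands` list-column of coordinating
#'   atoms with distances.
#' @export
classify_zinc_site <- function(structure, cutoff = ZN_CUTOFF) {
  at <- as_atoms(structure, model = 1L)
  zn <- filter(at, .data$element == "Zn")
  if (!nrow(zn)) return(tibble(
    zn_chain = character(), zn_resno = integer(), x = numeric(), y = numeric(),
    z = numeric(), coordination_number = integer(), geometry = character(),
    axial_species = character(), ligands = list()))
  cand <- filter(at, .data$element %in% COORD_ELEMENTS)
  purrr::map_dfr(seq_len(nrow(zn)), function(i) {
    p <- c(zn$x[i], zn$y[i], zn$z[i])
    d <- sqrt((cand$x - p[1])^2 + (cand$y - p[2])^2 + (cand$z - p[3])^2)
    lig <- cand[d <= cutoff, ]
    lig$distance <- d[d <= cutoff]
    cn <- nrow(lig)
    geometry <- "other"
    axial <- NA_character_
    if (cn >= 2) {
      vecs <- sweep(as.matrix(lig[, c("x", "y", "z")]), 2, p)
      vecs <- vecs / sqrt(rowSums(vecs^2))
      pairs <- utils::combn(cn, 2)
      angles <- apply(pairs, 2, function(pr) {
        rad2deg(acos(max(-1, min(1, sum(vecs[pr[1], ] * vecs[pr[2], ])))))
      })
      if (cn == 4 && abs(mean(angles) - TET_ANGLE) <= 15) {
        geometry <- "tetrahedral"
      } else if (cn %in% 5:6 &&
                 mean(pmin(abs(angles - 90), abs(angles - 180))) <= 15) {
        geometry <- "octahedral"
      }
      his <- lig$resid == "HIS"
      if (any(his) && any(!his)) {
        axis_dir <- -colSums(vecs[his, , drop = FALSE])
        if (vec_len(axis_dir) > 1e-8) {
          axis_dir <- vec_unit(axis_dir)
          cosang <- as.numeric(vecs[!his, , drop = FALSE] %*% axis_dir)
          if (max(cosang) > 0.8) {
            axial <- lig$resid[!his][which.max(cosang)]
          }
        }
      }
    }
    tibble(zn_chain = zn$chain[i], zn_resno = zn$resno[i],
           x = p[1], y = p[2], z = p[3],
           coordination_number = cn, geometry = geometry,
           axial_species = axial, ligands = list(as_tibble(lig)))
  })
}

## Bond graph inferred from heavy-atom distances (1.75 A; 2.3 A when both
## atoms are sulfur, to cover disulfides). Used only to exclude bonded and
## 1-3 pairs from hydrogen-bond candidates and for ring perception.
bond_graph <- function(at) {
  xyz <- as.matrix(at[, c("x", "y", "z")])
  n <- nrow(at)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (n < 2) return(g)
  dm <- as.matrix(stats::dist(xyz))
  cut <- matrix(1.75, n, n)
  is_s <- at$element == "S"
  cut[is_s, is_s] <- 2.3
  adj <- dm > 0.4 & dm <= cut
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  edges <- which(adj, arr.ind = TRUE)
  if (nrow(edges)) g <- igraph::add_edges(g, as.vector(t(edges)))
  g
}

## All chordless 5- and 6-membered rings within one residue's bond graph,
## returned as a list of atom-index vectors (indices into `at`).
residue_rings <- function(at) {
  out <- list()
  keys <- paste(at$model, at$chain, at$resno, at$resid)
  for (key in unique(keys)) {
    idx <- which(keys == key)
    sub <- at[idx, ]
    n <- nrow(sub)
    if (n < 5) next
    xyz <- as.matrix(sub[, c("x", "y", "z")])
    dm <- as.matrix(stats::dist(xyz))
    adj <- dm > 0.4 & dm <= 1.75
    nbrs <- lapply(seq_len(n), function(i) which(adj[i, ]))
    seen <- character()
    dfs <- function(path) {
      v <- path[length(path)]
      for (w in nbrs[[v]]) {
        if (w == path[1] && length(path) >= 5) {
          key2 <- paste(sort(path), collapse = "-")
          if (!key2 %in% seen) {
            seen <<- c(seen, key2)
            out[[length(out) + 1]] <<- idx[path]
          }
        } else if (!(w %in% path) && length(path) < 6 && w > path[1]) {
          dfs(c(path, w))
        }
      }
    }
    for (v in seq_len(n)) dfs(v)
  }
  ## drop rings that contain a chord (keep only minimal rings)
  out[purrr::map_lgl(out, function(ring) {
    sub <- at[ring, ]
    dm <- as.matrix(stats::dist(as.matrix(sub[, c("x", "y", "z")])))
    n_bonds <- sum(dm > 0.4 & dm <= 1.75) / 2
    n_bonds == length(ring)
  })]
}

#' Detect hydrogen bonds and pi contacts
#'
#' Hydrogen bonds are reported for N/O donor-acceptor heavy-atom pairs within
#' `hb_cutoff`, excluding covalently bonded and 1-3 pairs (bond connectivity
#' inferred from distances). Pi contacts are N/O atoms within `pi_cutoff` of
#' the centroid of a 5- or 6-membered ring of another residue. Only distances
#' are screened; no angular term is applied.
#'
#' @param structure A `hex_structure` or atom tibble.
#' @param hb_cutoff Heavy-atom donor-acceptor cutoff (default 3.6 Angstroms).
#' @param pi_cutoff N/O to ring-centroid cutoff (default 3.8 Angstroms).
#' @return Tibble: `type` ("HB" or "pi_contact"), donor/partner atom
#'   descriptors, `distance` (Angstroms).
#' @export
detect_contacts <- function(structure, hb_cutoff = HB_CUTOFF, pi_cutoff = PI_CUTOFF) {
  at <- as_atoms(structure, model = 1L)
  at <- filter(at, .data$element != "H")
  no <- which(at$element %in% c("N", "O"))
  empty <- tibble(type = character(), chain_a = character(), resno_a = integer(),
                  resid_a = character(), atom_a = character(),
                  chain_b = character(), resno_b = integer(),
                  resid_b = character(), atom_b = character(),
                  distance = numeric())
  if (length(no) < 1) return(empty)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  g <- bond_graph(at)
  res <- list()
  if (length(no) >= 2) {
    dm <- as.matrix(stats::dist(xyz[no, , drop = FALSE]))
    cand <- which(dm > 0 & dm <= hb_cutoff, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand)) {
      ia <- no[cand[, 1]]
      ib <- no[cand[, 2]]
      gd <- igraph::distances(g, v = unique(ia), to = unique(ib))
      topo <- gd[cbind(match(ia, unique(ia)), match(ib, unique(ib)))]
      keep <- topo > 2  # exclude bonded (1-2) and 1-3 pairs
      ia <- ia[keep]; ib <- ib[keep]
      if (length(ia)) {
        res$hb <- tibble(
          type = "HB",
          chain_a = at$chain[ia], resno_a = at$resno[ia],
          resid_a = at$resid[ia], atom_a = at$atom_name[ia],
          chain_b = at$chain[ib], resno_b = at$resno[ib],
          resid_b = at$resid[ib], atom_b = at$atom_name[ib],
          distance = dm[cand][keep])
      }
    }
  }
  rings <- residue_rings(at)
  if (length(rings)) {
    pi_rows <- purrr::map_dfr(rings, function(ring) {
      centroid <- colMeans(xyz[ring, , drop = FALSE])
      d <- sqrt(colSums((t(xyz[no, , drop = FALSE]) - centroid)^2))
      same_res <- at$chain[no] == at$chain[ring[1]] &
        at$resno[no] == at$resno[ring[1]] &
        at$resid[no] == at$resid[ring[1]]
      hit <- which(d <= pi_cutoff & !same_res)
      if (!length(hit)) return(NULL)
      i <- no[hit]
      tibble(type = "pi_contact",
             chain_a = at$chain[i], resno_a = at$resno[i],
             resid_a = at$resid[i], atom_a = at$atom_name[i],
             chain_b = at$chain[ring[1]], resno_b = at$resno[ring[1]],
             resid_b = at$resid[ring[1]],
             atom_b = paste0("ring", length(ring)),
             distance = d[hit])
    })
    res$pi <- pi_rows
  }
  out <- bind_rows(res)
  if (!nrow(out)) return(empty)
  arrange(out, .data$type, .data$distance)
}
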