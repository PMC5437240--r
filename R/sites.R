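## Ligand binding-site assignment by contact fingerprints.
##
## Site I is the internal phenolic pocket of the R-state hexamer (Cys A6 /
## Ser A9 / Cys A11 carbonyl-amide anchors plus His B5, Leu B17, Glu B21),
## site II the B9/B12/B16/B17 pocket between neighbouring monomers, and site
## III the surface pocket between 3-fold-related dimers (Tyr A14, Glu A17,
## Arg B22, Leu A13). Fingerprints are matched on canonical insulin residue
## ids regardless of which monomer contributes the residue.

CONTACT_CUTOFF <- 4.0    # heavy-atom ligand-residue contact cutoff, Angstroms
FINGERPRINT_MIN <- 0.5   # minimum match fraction to assign a site

SITE_FINGERPRINTS <- list(
  I = c("A6", "A9", "A11", "B5", "B17", "B21"),
  II = c("B9", "B12", "B16", "B17"),
  III = c("A14", "A17", "B22", "A13")
)

LIGAND_NAME_MAP <- c(
  IPH = "phenol", PHN = "phenol",
  SRO = "serotonin", SRT = "serotonin",
  LDP = "dopamine", DAH = "dopamine",
  ARG = "arginine"
)

NON_LIGAND_HET <- c("HOH", "WAT", "DOD", "ZN", "CL", "NA", "K", "MG", "CA",
                    "BR", "SO4", "PO4", "ACT", "GOL")

#' Assign hetero ligands to binding sites I/II/III
#'
#' Computes, for every recognised hetero ligand, the protein residues within
#' `contact_cutoff` (minimum heavy-atom distance) and matches the contact set
#' against the site I/II/III fingerprints. The site with the highest match
#' fraction wins, provided at least half the fingerprint residues are in
#' contact; ties and sub-threshold matches are left unassigned.
#'
#' @param structure A `hex_structure` or atom tibble.
#' @param contact_cutoff Heavy-atom cutoff in Angstroms (default 4.0).
#' @return Tibble, one row per ligand: `ligand_name`, `resid`, `chain`,
#'   `resno`, `site` ("I", "II", "III" or "unassigned"), `match_fraction`,
#'   and a `contacts` list-column (canonical residue id, minimum distance).
#' @export
assign_ligand_sites <- function(structure, contact_cutoff = CONTACT_CUTOFF) {
  at <- as_atoms(structure, model = 1L)
  at <- filter(at, .data$element != "H")
  lig <- filter(at, .data$record == "HETATM", !.data$resid %in% NON_LIGAND_HET)
  empty <- tibble(ligand_name = character(), resid = character(),
                  chain = character(), resno = integer(), site = character(),
                  match_fraction = numeric(), contacts = list())
  if (!nrow(lig)) return(empty)
  prot <- filter(at, .data$record == "ATOM")
  ct <- chain_types(prot)
  prot <- left_join(prot, select(ct, "chain", "chain_type"), by = "chain") %>%
    filter(!is.na(.data$chain_type)) %>%
    mutate(canonical_id = paste0(.data$chain_type, .data$resno))
  if (!nrow(prot)) return(empty)
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  lig_keys <- distinct(lig, .data$chain, .data$resno, .data$resid)
  purrr::map_dfr(seq_len(nrow(lig_keys)), function(i) {
    la <- filter(lig, .data$chain == lig_keys$chain[i],
                 .data$resno == lig_keys$resno[i],
                 .data$resid == lig_keys$resid[i])
    lxyz <- as.matrix(la[, c("x", "y", "z")])
    dmin <- apply(lxyz, 1, function(p) sqrt(colSums((t(pxyz) - p)^2)))
    per_atom_min <- apply(dmin, 1, min)  # per protein atom, min over ligand atoms
    contacts <- prot %>%
      mutate(min_dist = per_atom_min) %>%
      group_by(.data$canonical_id) %>%
      summarise(min_distance = min(.data$min_dist), .groups = "drop") %>%
      filter(.data$min_distance <= contact_cutoff) %>%
      arrange(.data$min_distance)
    fracs <- purrr::map_dbl(SITE_FINGERPRINTS, function(fp) {
      mean(fp %in% contacts$canonical_id)
    })
    best <- max(fracs)
    site <- "unassigned"
    if (best >= FINGERPRINT_MIN && sum(fracs == best) == 1) {
      site <- names(SITE_FINGERPRINTS)[which.max(fracs)]
    }
    nm <- unname(LIGAND_NAME_MAP[lig_keys$resid[i]])
    tibble(ligand_name = ifelse(is.na(nm), "other", nm),
           resid = lig_keys$resid[i], chain = lig_keys$chain[i],
           resno = lig_keys$resno[i], site = site,
           match_fraction = best, contacts = list(contacts))
  })
}
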