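Package: hexbind
Title: Conformational States and Ligand Binding Thermodynamics of Insulin Hexamers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ligand binding to zinc-coordinated insulin
    hexamers. Classifies monomer and hexamer conformational states (T, Rf, R;
    T6, T3Rf3, T3R3, R6) from backbone dihedrals, characterises zinc
    coordination geometry, detects hydrogen bonds and pi contacts, and assigns
    phenolic ligands to binding sites I/II/III by contact fingerprints.
    Estimates binding free energies from thermodynamic-integration lambda
    series and umbrella-sampling windows (WHAM), applies symmetry and
    standard-state volume-entropy corrections, and converts free energies to
    dissociation constants. Fits chromophore-reported titration curves with the
    one-site Hill-slope model. A synthetic-data module generates ideal hexamer
    fixtures, umbrella windows from known potentials of mean force, lambda
    series with analytic integrals, and noisy titration curves so the whole
    pipeline is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
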