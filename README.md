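# hexbind

Insulin is stored in pancreatic β-cell granules as a Zn²⁺-coordinated
hexamer whose six monomers interconvert between three conformations of the
B-chain N terminus: **T** (B1–B6 extended, octahedral Zn²⁺), **Rf** (helix
from B3, "frayed" B1–B2) and **R** (helix from B1, tetrahedral Zn²⁺ with an
axial anion). Phenolic ligands — phenol itself, and the neurotransmitters
serotonin and dopamine that co-accumulate in the granules — bind the hexamer
at an internal pocket (site I) and a surface pocket between 3-fold-related
dimers (site III), shifting the T/R equilibrium and stabilising particular
oligomeric states such as T₃R₃.

`hexbind` is an R package for the computational side of this system, aimed
at structural bioinformaticians and simulators who need to:

1. **Classify structures** — parse PDB/mmCIF coordinates, identify
   insulin monomers by the Cys A20–Cys B19 disulfide, assign per-monomer
   T/Rf/R states from backbone dihedrals, label the hexamer (T₆, T₃Rf₃,
   T₃R₃, R₆), characterise Zn²⁺ coordination geometry
   (octahedral/tetrahedral), detect hydrogen bonds and N/O–π ring contacts,
   and assign ligands to sites I/II/III by contact fingerprints. Kabsch
   superposition gives backbone or ligand r.m.s.d. between structures.
2. **Estimate binding free energies** — thermodynamic integration of
   λ-series (trapezoidal ⟨∂U/∂λ⟩ quadrature with error propagation), WHAM
   unbiasing of umbrella-sampling windows into a potential of mean force,
   and the decomposition

   ΔG_b° = W₀ + ΔG_symm + ΔG_vol,  K_d = exp(ΔG_b°/RT)

   where W₀ is the PMF well depth relative to the unbound plateau,
   ΔG_symm = −RT ln n accounts for n symmetry-equivalent sites (a verbatim
   override is accepted), and ΔG_vol = −RT ln(v_bound/V₀) references the
   Gaussian effective bound volume v = (2πe)^{3/2}|Σ|^{1/2} to the 1 M
   standard state (V₀ = 1660.539 Å³ per molecule).
3. **Fit titration curves** — one-site Hill-slope regression
   ΔA = B_max·c^h/(K_d^h + c^h) of chromophore-reported difference
   absorbance at 444 nm, with bounded Levenberg–Marquardt optimisation,
   per-curve standard errors and replicate summaries.
4. **Generate synthetic data** — every input above can be produced by a
   seeded generator with analytic ground truth: torsion-built hexamer
   fixtures with placed ligands and Zn²⁺ shells, Boltzmann samples from
   known 1-D PMFs under harmonic biases, λ-series with closed-form
   integrals, Gaussian bound-state clouds, and noisy Hill curves. The whole
   pipeline is therefore testable offline.

All user-facing functions take data frames and return tibbles; fitted
objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Build a serotonin-loaded T₃R₃ hexamer fixture (3 site I + 3 site III
ligands, two tetrahedral Zn²⁺ sites) and run the classification stack:

```r
library(hexbind)
library(dplyr)

st <- make_hexamer_fixture(
  monomer_states = c("T", "T", "T", "R", "R", "R"),
  ligands = tibble::tibble(name = "serotonin",
                           site = c("I", "I", "I", "III", "III", "III"),
                           monomer = c(4, 5, 6, 1, 2, 3)),
  zinc = c("tetrahedral", "tetrahedral"), seed = 1)

classify_states(st)$monomers
#>   monomer_id a_chain b_chain ss_distance state helix_start
#> 1          1 A       B              2.07 T               9
#> ...
#> 6          6 K       L              2.05 R               1
classify_states(st)$hexamer_state
#> [1] "T3R3"

count(assign_ligand_sites(st), site)
#>   site      n
#> 1 I         3
#> 2 III       3

select(classify_zinc_site(st), coordination_number, geometry, axial_species)
#>   coordination_number geometry     axial_species
#> 1                   4 tetrahedral  CL
#> 2                   4 tetrahedral  CL
```

The six monomers classify to their generating states (helix from B1 for R,
B9–B19 helix with extended B1–B6 for T), the hexamer is T₃R₃ with six
serotonins split 3:3 over sites I and III, and both axial Zn²⁺ ions are
tetrahedral with a chloride axial ligand — the composition expected for a
serotonin-stabilised hexamer.

Free-energy bookkeeping and the ΔG↔K_d conversion:

```r
combine_binding(w0 = -1.83, dg_symm = -0.36, dg_vol = 1.38, temperature = 300)
#>      w0 dg_symm dg_vol dg_total    kd
#> 1 -1.83   -0.36   1.38    -0.81 0.257
```

A −0.81 kcal/mol site III binding free energy corresponds to K_d ≈ 0.26 M
at 300 K (RT = 0.59616 kcal/mol).

Hill analysis of a synthetic phenol-like titration:

```r
tt <- make_titration(kd = 0.86, bmax = 0.17, h = 2.22,
                     concentrations = log_spaced(0.05, 10, 12),
                     noise_sd = 0.005, seed = 1)
fit_hill(tt)
#> <hill_fit> Kd = 0.8585 mM, Bmax = 0.1731 AU, h = 2.268 (converged)
```

A single noisy curve refits to within a few percent of the generating
parameters; `fit_hill_replicates()` + `summarize_replicates()` pool many
curves into mean ± SD tables.

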