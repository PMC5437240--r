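---
title: "Methods: conformational states, binding free energies and Hill analysis of insulin hexamers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational states, binding free energies and Hill analysis of insulin hexamers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexbind)
library(dplyr)
```

`hexbind` covers three layers of an insulin-hexamer/ligand study: geometric
classification of structures, binding free-energy estimation, and Hill
analysis of titration curves, plus a synthetic-data layer that makes every
stage testable against analytic ground truth. This vignette records the
models, the tunable parameters, and the design choices that were genuinely
open.

## Conformational-state classification

Insulin is a 51-residue two-chain hormone (A1–A21, B1–B30); within the
hexamer each monomer's B-chain N terminus adopts one of three
conformations. The classifier works entirely from backbone dihedrals:

* a residue is *helical* iff φ ∈ [−100°, −30°] and ψ ∈ [−80°, −5°], the
  standard α-basin; a helical *run* needs ≥ 4 consecutive helical
  residues. A chain-start residue with undefined φ counts on ψ alone,
  since a helix running from B1 has no φ there to test.
* the monomer label comes from the first residue (`helix_start`) of the
  longest helical run ending at or beyond B17: helix from B1–B2 → **R**,
  from B3–B4 → **Rf** (frayed B1–B2), from B7 or later with a fully
  non-helical B1–B6 → **T**. Runs starting at B5–B6 are flagged
  `undetermined` rather than silently binned — that region is not covered
  by any of the three canonical forms.
* six monomer labels combine to the hexamer label: T₆, T₃Rf₃, T₃R₃, R₆;
  any other composition is `mixed`, and any undetermined monomer makes the
  hexamer undetermined. `mixed` is reported rather than suppressed because
  real depositions can in principle contain non-canonical compositions;
  interpreting them is left to the user.

The dihedral windows are a design decision: the state definitions in the
literature are verbal (helix from B1/B3/B9), so any implementation must
pick a numeric helicity criterion. The α-basin bounds used here are wide
enough to tolerate a few degrees of distortion yet exclude the extended
basin (φ ≈ −120°, ψ ≈ +120°) and the type II′ turn torsions at B7–B8 of
the T state.

Monomers are identified by pairing the 21-residue chain's Cys A20 Sγ with
the nearest 30-residue chain's Cys B19 Sγ within 3.0 Å (greedy nearest-pair
matching); chains are mapped to canonical A/B numbering by chain length.
Mixed or renumbered depositions must be renumbered by the caller first.

## Zinc sites, contacts and ligand-site assignment

* **Zn coordination**: ligand atoms are N/O/S/halide atoms within 2.8 Å of
  the Zn (default `zinc_cutoff`). Coordination number 4 with mean
  inter-ligand angle within 15° of 109.47° → tetrahedral; 5–6 ligands with
  angles populating 90°/180° (mean deviation ≤ 15°) → octahedral;
  otherwise `other`. The thresholds are ours: geometry names appear in the
  literature without numeric criteria. A non-His ligand anti-aligned with
  the mean His direction (cosine > 0.8) is reported as the axial species —
  the tetrahedral R-state signature (3 His B10 + axial Cl⁻), with no axial
  species for the octahedral T-state shell (3 His + 3 water).
* **Hydrogen bonds** are distance-only: N/O heavy-atom pairs within 3.6 Å,
  excluding covalently bonded and 1–3 pairs on a distance-inferred bond
  graph. No angular term is applied because the reference measurements for
  this system are reported as distances; the 3.6 Å default covers the
  weakest reported contacts (≈ 3.4 Å) with margin.
* **π contacts** are N/O atoms within 3.8 Å of the centroid of a 5- or
  6-membered ring of another residue (rings perceived per residue from the
  bond graph) — capturing the His B5 Nε2–pyrrole interaction that pins the
  serotonin indole in site I.
* **Site assignment** matches each hetero ligand's contact residues
  (minimum heavy-atom distance ≤ 4.0 Å) against fingerprints on canonical
  residue ids: site I {A6, A9, A11, B5, B17, B21}, site II {B9, B12, B16,
  B17}, site III {A14, A17, B22, A13}. The best-matching site wins if at
  least half its fingerprint is in contact; ties are left unassigned. The
  50% threshold tolerates missing side-chain atoms in real depositions.
  Fingerprints deliberately ignore *which* monomer contributes a residue:
  sites II/III span monomers, and the canonical id is the stable part of
  the signature.

## Free energies

Units are kcal/mol, Kelvin, Å, mol/L, with R = 1.98720×10⁻³ kcal/(mol K)
(RT = 0.59616 at the default T = 300 K — this constant reproduces all the
ΔG↔K_d pairs used in the tests to ≤ 1%).

* **Thermodynamic integration**: ΔG = ∫₀¹ ⟨∂U/∂λ⟩ dλ by trapezoidal
  quadrature on the caller's λ grid (exact for piecewise-linear
  integrands); the per-λ SEM propagates through the quadrature weights in
  quadrature. Missing λ = 0/1 endpoints are flagged, not silently
  extrapolated.
* **WHAM**: harmonic-bias umbrella windows are histogrammed on a common
  grid (default 100 bins over the sampled range) and the self-consistent
  window shifts are iterated to a relative tolerance of 10⁻⁸ (cap 10⁵
  iterations; non-convergence is an error carrying the last residual).
  The PMF is referenced so a user-chosen unbound plateau range averages
  zero — profiles for surface-site binding decay to a flat region, which
  fixes the additive constant; without a plateau range the minimum is set
  to zero. Per-bin uncertainty is the Poisson counting estimate kT/√n.
  Empty bins interior to the sampled range are flagged as gaps.
* **Decomposition**: ΔG_b° = W₀ + ΔG_symm + ΔG_vol, exact arithmetic, with
  W₀ = min(PMF over the bound range) − mean(PMF over the plateau range).
  ΔG_symm defaults to −RT ln n for n equivalent sites but accepts a
  verbatim override, because externally derived symmetry terms (e.g. from
  a simulation protocol's own analysis) need not equal the ideal value.
  ΔG_vol = −RT ln(v_bound/V₀) with V₀ = 1660.539 Å³; the bound volume may
  be supplied directly or estimated from bound-state ligand positions by
  the Gaussian effective volume v = (2πe)^{3/2}|Σ|^{1/2}. That estimator
  is exact for a Gaussian occupancy cloud and is the simplest volume
  measure consistent with a positional covariance; for strongly
  non-Gaussian clouds it is biased, which is a known limitation.
  K_d = exp(ΔG_b°/RT); component uncertainties combine in quadrature and
  map to K_d by the first-order delta method.

## Hill analysis

The chromophore assay reports the R-state population through the
difference absorbance at 444 nm. Fits use the one-site Hill-slope form
ΔA = B_max·c^h/(K_d^h + c^h) — the standard "specific binding with Hill
slope" parameterisation — under bounded Levenberg–Marquardt (bounds
K_d ∈ (0, 100] mM, B_max ∈ [0, 1] AU, h ∈ (0, 20], preventing divergence
on flat curves). Auto-initialisation takes B_max from the maximum observed
signal, K_d from the concentration nearest half-max, h = 1. Standard
errors come from the curvature of the residual surface at the optimum.
Concentrations are treated as dispensed (no ligand-depletion correction),
fits are per replicate curve, and replicate summaries report mean ± SD
(n−1): the replicate-then-summarise reading matches how such assays
report "values from at least three independently determined curves".
A fit pinned at the B_max = 0 boundary is flagged unconverged — an
all-zero curve has no identifiable K_d.

## The synthetic-data layer

Every generator returns (or embeds) its analytic ground truth, and each
downstream stage has a test consuming exactly that pairing.

* **Hexamer fixtures** are geometric test articles, not physical models:
  backbones are built by sequential torsion geometry (helix −57/−47,
  extended −120/+120, type II′ turn at B7–B8 for T monomers; standard bond
  lengths/angles), six monomers are placed 3-fold symmetrically in two
  trimers (radius 30 Å, trimer offset ±12 Å — chosen so neighbouring
  monomers and ligand pockets cannot interfere), and only the side-chain
  atoms the classifiers actually read are placed: Cys Sγ pairs at 2.05 Å,
  His B10 Nε2 at the Zn shell vertices, and the site I/III fingerprint
  atoms at their anchor distances (serotonin OH 2.42 Å from the Cys A6
  carbonyl O, His B5 Nε2 3.50 Å from the pyrrole centroid, Glu A17
  carboxylate 2.96 Å from the site III ligand OH). Anchor distances must
  lie in [2, 4] Å and any ligand-protein approach below 1.8 Å aborts the
  build listing the offending pair. A seeded uniform jitter of ±0.012 Å
  distinguishes seeds while keeping any two builds within 0.05 Å per atom.
  What the fixtures do *not* emulate: real side-chain rotamers, packing,
  solvent, or crystallographic disorder — so passing classification tests
  demonstrates correctness of the geometric criteria, not robustness to
  every pathology of deposited structures.
* **Umbrella windows** draw Boltzmann samples from
  exp(−(U(x) + k/2 (x−c)²)/RT) by inverse-CDF sampling on a 4001-point
  grid. The CDF uses trapezoidal accumulation: a left-Riemann CDF would
  displace every sample by O(grid step) relative to its bias centre, which
  WHAM would convert into a systematic tilt of the recovered PMF — this
  was measurable and is why the quadrature matters. A window whose biased
  density does not vanish at the grid edges errors out ("spring too
  weak").
* **λ-series** use ∂U/∂λ = a + bλ + c sin(πλ) with analytic integral
  a + b/2 + 2c/π and optional Gaussian noise equal to the reported SEM.
* **Titration curves** add Gaussian noise (default sd 0.005 AU, ≈ 3% of a
  phenol-like B_max) to exact Hill values; replicate i uses sub-seed
  seed + i, documented and stable.

## Problem sizes and numerical choices

The test and acceptance runs use: 50 titration replicates per regime at 12
log-spaced concentrations; 20 000–50 000 samples per umbrella window over
25–49 windows (0.25-unit spacing, k = 10 kcal/mol/unit²) with 100–120 WHAM
bins; 10⁵-point clouds for volume checks; 21-point λ grids. These sizes
put the stochastic benchmarks comfortably inside their tolerances (WHAM
PMF error ≲ 0.03 kcal/mol against the 0.1 kcal/mol benchmark; chain-level
K_d error ≈ 1–2% against the 10% benchmark) while keeping the full suite
under a minute. WHAM comparisons are restricted to adequately sampled bins
(≥ 500 samples): outermost bins hold a handful of points and carry only
counting noise, not information about the potential.

Tie-breaks and degenerate inputs are deterministic throughout: altloc
duplicates keep the highest occupancy (ties → 'A'); fingerprint ties leave
a ligand unassigned; an undercoordinated Zn is `other`; chains that cannot
be disulfide-paired are reported and omitted.

## Known limitations

* The classifier requires canonical chain lengths (21/30) for A/B mapping;
  fragments and renumbered entries need caller-side canonicalisation.
* Hydrogen-bond detection is distance-only by design; an angular screen
  would need hydrogen positions or inferred donor geometry.
* WHAM is 1-D and harmonic-bias only; there is no MBAR estimator and no
  support for multidimensional reaction coordinates.
* The Gaussian bound-volume estimator assumes a unimodal, roughly Gaussian
  bound state; multimodal site occupancy should supply `v_bound` directly.
* The Hill model is phenomenological: h summarises cooperativity without
  modelling the underlying allosteric mechanism, and no competitive
  two-ligand binding model is provided (background ligands enter only as
  labels).
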