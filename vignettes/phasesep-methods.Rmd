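---
title: "Methods: exposure-based C_sat prediction and condensate assay fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposure-based C_sat prediction and condensate assay fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasesep)
```

# Scope and model

`phasesep` quantifies liquid-liquid phase separation (LLPS) of proteins and
peptides from two directions:

1. **Structure side.** From a PDB structure (or a disordered-state
   ensemble), compute per-residue solvent-accessible surface area (SASA),
   normalize it into an *effective exposure* in [0, 1], sum exposures over
   four residue classes, and feed those sums into a linear model of the
   log10 apparent saturation concentration (`C_sat`):

   log10(C_sat) = A·N_polar + B·N_hydrophobic + C·N_charge + D·N_aromatic + E

   The package ships a published coefficient set
   (`published_csat_model()`: −0.041, +0.016, −0.005, +0.026, intercept
   +2.24) and an OLS fitter (`fit_csat_model()`) for deriving a new set
   from observations.

2. **Assay side.** Fit the standard condensate assays: Boltzmann sigmoid
   light-scattering kinetics (`fit_boltzmann()`), single exponential FRAP
   recovery (`fit_frap()`), sequential dissolution titrations decomposed
   into interaction-type percentages (`dissolution_percentages()`),
   apparent crowder partition coefficients (`partition_coefficient()`),
   phase-regime C_sat extraction (`csat_from_grid()`), and Beer-Lambert
   dilute-phase concentrations (`dilute_phase_concentration()`).

Everything is data-frame first: functions take tibbles, return tibbles or
small fit objects with `tidy()`/`glance()`/`augment()`/`autoplot()`
methods, and chain with the pipe.

# Structure input

`read_structure()` parses fixed-column PDB (the only supported structure
format; mmCIF is out of scope). Policy decisions, all applied at parse
time:

- **Hydrogens are dropped.** Crystal structures mostly lack them; mixing
  hydrogenated and non-hydrogenated inputs would bias exposure values.
- **Waters (HOH) are dropped; other heteroatoms are kept** but flagged
  `is_hetero` and excluded from SASA by default (`include_hetero = TRUE`
  restores them). How chromophores and ligands should occlude the protein
  surface is genuinely open; excluding them treats the polypeptide surface
  on its own terms and is the reproducible default.
- **Alternate locations** resolve to the highest-occupancy conformer,
  first on ties.
- **Residue numbering is verbatim** (insertion codes appended), no
  renumbering; a residue is keyed by (chain, index string).

Multi-model files become one tibble with a `model` column; under
`model = "all"` the models must share an identical residue list
(`validate_ensemble()` reports the first mismatch).

# SASA and effective exposure

`shrake_rupley()` implements the classical test-point construction: each
atom gets a deterministic lattice of `n_points` points on its
solvent-expanded sphere (van der Waals radius + probe), and a point is
exposed iff it lies strictly outside every other atom's expanded sphere.
Area = exposed fraction × sphere area, so per-residue area is *exactly*
the sum of member-atom areas.

Numerical choices:

- **Probe radius 1.4 Å, 960 points** by default. Both are configurable and
  recorded in the result object; point counts from 92 up are accepted.
- **Point set**: a generalized golden-angle spiral — deterministic, so
  results are reproducible without a seed.
- **Lattice orientation** (`frame`): no finite-point lattice can be both
  exactly monotone under atom addition and exactly invariant under
  rotation. The default `"principal"` mode anchors the lattice to the
  structure's principal axes (eigenvectors of the coordinate covariance,
  signs fixed by the third moment along each axis, right-handed
  completion), which makes areas *exactly* invariant under rigid motion of
  the input. The `"fixed"` mode uses a globally oriented lattice, under
  which adding an atom can never increase another atom's area (exact
  occlusion monotonicity). The two modes agree to within the lattice
  resolution (≲2% per atom at 960 points, ≲0.5% on totals).
- **van der Waals radii**: C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80
  Å; unlisted elements fall back to 1.80 Å with a warning.
- **Boundary rule**: a test point exactly on a neighbouring sphere counts
  as exposed; exactly coincident equal spheres therefore both report full
  area (degenerate, documented, tolerance 1e-9 on the squared distance).

An independent **Monte-Carlo oracle** (`monte_carlo_sasa()`) estimates the
same areas by uniform random sampling on each sphere, with a standard
error; the test suite requires 2% agreement on random clusters.

**Effective exposure** divides each residue's SASA by that residue type's
maximum allowed SASA (`max_sasa_table()`, the Tien et al. 2013
"theoretical" Gly-X-Gly values) and clamps into [0, 1] — terminal residues
can exceed the tripeptide-context maximum, and the exposure quantity is
defined on [0, 1]. For ensembles, per-residue SASA is the unweighted mean
over models *before* normalization (`ensemble_average_exposures()`).

# The C_sat model

Residues partition into aromatic {W, F, Y, H}, polar {P, T, S, N, Q},
charged {R, K, E, D} and hydrophobic {A, C, G, I, L, M, V} — exhaustive
and disjoint, asserted at package load. `exposure_features()` sums
effective exposures per class; residues with unknown codes are skipped and
counted.

`fit_csat_model()` is unweighted OLS with intercept on log10
concentration (energies are proportional to log concentration, and the
published model is written in log10). It refuses fewer than 6 observations
and rank-deficient designs. The packaged published model's concentration
unit is taken as **µM**: the published intercept 2.24 corresponds to
about 174 µM, which sits inside the ~1–600 µM range protein C_sat values
span; the unit is recorded in the model object and propagated, but the
original publication does not state it, so treat absolute predictions with
that caveat. The packaged coefficients are used as published, not
re-derived (re-deriving them needs the original structure set and
experimental C_sat values, which are not shipped).

# Assay fits

**Kinetics.** `fit_boltzmann()` fits
`y = y0 + (ymax − y0) / (1 + exp(−k (t − t_half)))` by Levenberg-Marquardt
least squares (`minpack.lm`, cost tolerance 1e-10). Starting values: `y0`
min, `ymax` max, `t_half` the interpolated half-crossing, `k = 4/(t90 −
t10)`; bounds `y0, ymax ∈ [−0.2, 1.5]`, `k > 0`; up to 5 deterministically
jittered restarts. A monotone-decreasing trace fits with `k < 0` plus a
warning. `normalize_trace()` handles baseline subtraction (first point or
pointwise blank) and scaling to max 1, and is idempotent.

**FRAP.** `preprocess_frap()` applies the double normalization
`(bleach − background) / (reference − background) / prebleach`; the
reference-ratio step cancels passive photofading exactly when fading is
multiplicative and shared between ROIs. The recipe is recorded in an
attribute and `prebleach` is configurable (raw recordings do not fix
whether rescaling is to the pre-bleach or post-bleach level, so both are
expressible). `fit_frap()` fits `I(t) = A (1 − exp(−t/τ)) + C`; `A` is the
mobile fraction, and the recovery half-time is the exact identity
`t_half = τ ln 2`, never an independently fitted number. Non-recovering
traces (no positive τ, or non-positive amplitude) are an error rather than
a fit.

**Dissolution titration.** Condensates are titrated sequentially with NaCl
(electrostatic), 1,6-hexanediol (hydrophobic) and urea (H-bonding). The
drop attributed to each additive runs from the value at that stage's start
(the previous stage's end, or the initial value — the sequential-titration
reading) to the value at its end; a rising stage clamps to zero
contribution, because an interaction class cannot contribute negatively,
and the rest renormalize. Stage order is accepted as recorded (order was
shown not to change the outcome) and the percentages always sum to 100
when anything dissolved at all.

**Partitioning and grids.** `partition_coefficient()` is
mean(inside)/mean(outside) ROI intensity — with the packaged
beta-lactoglobulin FITC-PEG intensities (7.63 / 404.34) it gives 0.0189,
which the original report rounds to "0.01 = ~0"; the package reports the
unrounded ratio. `csat_from_grid()` reads the smallest LLPS concentration
in a phase-regime column, treats precipitate as non-LLPS, and warns on
non-contiguous LLPS regimes. `dilute_phase_concentration()` is
`c = dilution × A/(εl)` in µM, with the four chromophore extinction
coefficients packaged (`extinction_coefficients()`).

# Synthetic data

Every input class has a seeded generator whose ground truth is attached as
`attr(x, "truth")`, so round-trip tests read the truth from the object:

- `make_test_structure()`: a single carbon (analytic sphere area), a
  carbon pair at chosen distance, or an extended peptide with fixed
  ideal-bond-length backbone geometry (N, CA, C, O, CB; ~3.8 Å CA-CA
  rise). The geometry is adequate for exercising SASA and sequence
  plumbing and makes no physical-realism claim. Jittered copies provide
  ensemble models.
- `simulate_boltzmann_trace()` / `simulate_frap_trace()`: exact forward
  models plus i.i.d. Gaussian noise; the FRAP generator emits all three
  ROIs with optional multiplicative photofading, default grids 0–600 s
  (step 5) and 0–60 s (step 0.2) matching the assays' natural scales.
- `simulate_titration()`: linear within-stage ramps with the protocol's
  concentration steps (NaCl 50–150 mM, hexanediol 2–15% w/v, urea
  0.5–2 M), fractions of the initial signal as truth.
- `simulate_feature_table()`: features uniform in [0, 20] exposure units
  by default (the scale a mid-sized globular protein's category sums
  occupy), log10 C_sat from the linear model plus Gaussian noise.
- `make_phase_grid()`: state matrix implied by a C_sat per crowder level,
  optional precipitate band.

The noise model is i.i.d. Gaussian everywhere — real traces have
correlated drift, shot noise and outliers, so passing recovery tests
demonstrate correctness of the estimators under the stated model, not
robustness to instrument pathology. Problem sizes in the test suite (20
seeded clusters of ≤10 atoms for the SASA oracle, 200 regression
replicates at n = 20, 20–50 assay replicates, 1000 random titrations) were
chosen to make sampling error small relative to the tested tolerances
while keeping the default run quick.

# Known limitations

- PDB fixed-column input only; no mmCIF, no symmetry expansion, no
  download clients.
- The exposure predictor is structure-based by construction; sequence-only
  prediction is out of scope.
- FRAP fitting is the single-exponential phenomenological model, not
  diffusion-based (Soumpasis/Axelrod) recovery.
- The published-coefficient model is only as transferable as its training
  set; predictions for proteins far outside that set (very large, heavily
  modified, or strongly charged systems) extrapolate.
- Image analysis (condensate segmentation, ROI extraction) is upstream of
  this package: partitioning and FRAP functions consume extracted
  intensities.

# A worked pipeline

```{r pipeline}
pep <- make_test_structure("extended_peptide", sequence = "GAVRWSTDKQ")
exposures <- shrake_rupley(pep) |>
  residue_exposures(extract_sequence(pep))
exposures

features <- exposure_features(exposures, source_id = "demo-peptide")
features

predict_csat(published_csat_model(), features)
```

```{r assays}
fit_boltzmann(simulate_boltzmann_trace(noise_sd = 0.02, seed = 11))

simulate_frap_trace(A = 0.8, tau = 5, C = 0.1, noise_sd = 0.03, seed = 3) |>
  preprocess_frap() |>
  fit_frap()

simulate_titration(c(0.7, 0.2, 0.05), noise_sd = 0.01, seed = 5) |>
  dissolution_percentages()
```
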