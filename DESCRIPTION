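Package: phasesep
Title: Quantitative Analysis of Protein and Peptide Liquid-Liquid Phase
    Separation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying liquid-liquid phase separation (LLPS) of
    proteins and peptides. Computes per-residue solvent-accessible surface
    area (Shrake-Rupley) and effective solvent exposure from PDB structures
    and disordered-state ensembles, builds the four-category exposure
    features (polar, hydrophobic, charged, aromatic) that drive a linear
    log10 saturation-concentration (C_sat) predictor, and fits the standard
    condensate assays: Boltzmann sigmoid light-scattering kinetics, single
    exponential FRAP recovery, sequential dissolution titrations decomposed
    into interaction-type percentages, crowder partition coefficients,
    phase-regime C_sat extraction, and Beer-Lambert dilute-phase
    concentrations. Includes seeded synthetic-data generators with embedded
    ground truth for every input class so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
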