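# phasesep

Quantitative analysis of protein and peptide liquid-liquid phase
separation (LLPS), for structural biologists and condensate biophysicists
who need to go from a structure or an assay trace to a number.

Growing evidence treats condensate formation as a generic property of
proteins: given a crowded milieu, folded and disordered chains alike demix
once their concentration passes an apparent saturation concentration
(C_sat), with the driving interactions — electrostatic, hydrophobic,
H-bonding — encoded in the solvent-exposed surface. `phasesep` implements
the quantitative machinery around that view:

- **Structure → C_sat.** Per-residue solvent-accessible surface area by
  the Shrake–Rupley test-point construction, normalized by each residue
  type's maximum allowed SASA into an *effective exposure* in [0, 1],
  summed over residue classes (aromatic WFYH, polar PTSNQ, charged RKED,
  hydrophobic ACGILMV) and fed into the linear predictor

  ```
  log10(C_sat) = A·N_polar + B·N_hydrophobic + C·N_charge + D·N_aromatic + E
  ```

  with either a freshly fitted coefficient set (`fit_csat_model()`, OLS)
  or the packaged published one (`published_csat_model()`: −0.041, +0.016,
  −0.005, +0.026, +2.24; concentrations in µM). Disordered proteins are
  handled as multi-model ensembles with SASA averaged over models.

- **Condensate assays.** Boltzmann sigmoid fits of light-scattering
  assembly kinetics with half-time t₁/₂; single exponential FRAP recovery
  `I(t) = A(1 − e^(−t/τ)) + C` with mobile fraction `A` and
  `t₁/₂ = τ ln 2`; sequential NaCl / 1,6-hexanediol / urea dissolution
  titrations decomposed into electrostatic / hydrophobic / H-bonding
  percentages; apparent partition coefficients from ROI intensities;
  C_sat read off phase-regime grids; Beer–Lambert dilute-phase
  concentrations.

- **Synthetic data.** Seeded generators for every input class (toy
  structures with analytically known SASA, sigmoid and FRAP traces,
  titrations, feature tables, phase grids), each carrying its ground
  truth, so the entire pipeline is testable offline.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` / `augment()` on fit objects, `autoplot()` / `plot_*()` for
figures.

## Worked example

From a peptide structure to a predicted saturation concentration:

```r
library(phasesep)

pep <- make_test_structure("extended_peptide", sequence = "GAVRWSTDKQ")
exposures <- shrake_rupley(pep) |>
  residue_exposures(extract_sequence(pep))
features <- exposure_features(exposures, source_id = "demo-peptide")
features
#> # A tibble: 1 × 6
#>   source_id    n_polar n_hydrophobic n_charge n_aromatic n_skipped
#>   <chr>          <dbl>         <dbl>    <dbl>      <dbl>     <int>
#> 1 demo-peptide    1.88          2.38     1.29      0.349         0

predict_csat(published_csat_model(), features)
#> [1] 159.7877
```

The four feature sums are total effective exposure per residue class —
this fully exposed 10-mer contributes ~1.9 polar, ~2.4 hydrophobic, ~1.3
charged and ~0.3 aromatic exposure units — and the model maps them to a
predicted C_sat of ≈160 µM.

Assay fits work the same way, here on simulated data with known truth:

```r
fit_boltzmann(simulate_boltzmann_trace(noise_sd = 0.02, seed = 11))
#> <boltzmann_fit> y0 = -0.006666, ymax = 1.001, k = 0.05033 /s, t_half = 200.1 s (rss 0.0416)

simulate_titration(c(0.7, 0.2, 0.05), noise_sd = 0.01, seed = 5) |>
  dissolution_percentages()
#> # A tibble: 1 × 4
#>   pct_electrostatic pct_hydrophobic pct_hbond residual_fraction
#>               <dbl>           <dbl>     <dbl>             <dbl>
#> 1              74.8            20.3      4.91            0.0471
```

The kinetics fit recovers the generating half-time (200 s) from a noisy
trace; the titration decomposition attributes ~75% of condensate
stability to electrostatics, matching the simulated 0.7/0.2/0.05
dissolution fractions.

The packaged glycine-homopeptide series shows the length dependence of
peptide LLPS:

```r
linear_fit(gly_series())
#> # A tibble: 1 × 7
#>   slope intercept      r r_squared     n x_transform y_transform
#>   <dbl>     <dbl>  <dbl>     <dbl> <int> <chr>       <chr>
#> 1 -7.11      71.2 -0.977     0.954     6 identity    identity
```

C_sat falls by ~7 mM per added glycine over lengths 5–10 (R² ≈ 0.95): a
longer chain needs a lower concentration to phase separate.

See `vignettes/phasesep-methods.Rmd` for the full model description,
numerical choices and limitations.

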