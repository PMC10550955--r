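# Packaged reference constants used across the pipeline.

#' Three-letter to one-letter amino acid code table
#' @noRd
.aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

#' Residue interaction-class partition
#'
#' The four-way partition of the 20 standard amino acids used to build the
#' exposure features of the saturation-concentration model: aromatic
#' (W, F, Y, H), polar (P, T, S, N, Q), charged (R, K, E, D) and hydrophobic
#' (A, C, G, I, L, M, V). Every standard one-letter code belongs to exactly
#' one class.
#'
#' @return A tibble with columns `code` (one-letter amino acid code) and
#'   `class` (one of `"aromatic"`, `"polar"`, `"charged"`, `"hydrophobic"`).
#' @examples
#' residue_classes()
#' @export
residue_classes <- function() {
  tibble::tibble(
    code = c(
      "W", "F", "Y", "H",
      "P", "T", "S", "N", "Q",
      "R", "K", "E", "D",
      "A", "C", "G", "I", "L", "M", "V"
    ),
    class = rep(
      c("aromatic", "polar", "charged", "hydrophobic"),
      times = c(4, 5, 4, 7)
    )
  )
}

#' Maximum allowed solvent-accessible surface area per residue
#'
#' Theoretical maximum accessible surface area (ASA) of each amino acid X in
#' a Gly-X-Gly tripeptide context, in square Angstroms, from the Tien et al.
#' (2013) "theoretical" column. Dividing an observed per-residue SASA by
#' this value gives the effective (relative) solvent exposure in \[0, 1\].
#'
#' @return A tibble with columns `code` and `max_sasa` (Angstrom squared).
#' @references Tien MZ, Meyer AG, Sydykova DK, Spielman SJ, Wilke CO (2013)
#'   Maximum allowed solvent accessibilities of residues in proteins.
#'   PLoS ONE 8:e80635.
#' @examples
#' max_sasa_table()
#' @export
max_sasa_table <- function() {
  tibble::tibble(
    code = c(
      "A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
    ),
    max_sasa = c(
      129, 274, 195, 193, 167, 223, 225, 104, 224, 197,
      201, 236, 224, 240, 159, 155, 172, 285, 263, 174
    )
  )
}

#' Van der Waals radii used by the SASA calculation
#'
#' Element-to-radius lookup (Angstroms): C 1.70, N 1.55, O 1.52, S 1.80,
#' H 1.20, P 1.80. Unlisted elements fall back to 1.80 with a warning at
#' the point of use.
#'
#' @return A named numeric vector of radii in Angstroms.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
}

.vdw_fallback <- 1.80

#' In-study glycine homopeptide saturation concentrations
#'
#' Apparent saturation concentrations (mM) of (Gly)n homopeptides of length
#' n = 5..10 in 10% (w/v) PEG-8000, 20 mM sodium phosphate buffer pH 7.4,
#' as determined by phase-regime microscopy: 40, 25, 20, 12, 8 and 2 mM.
#' Used for the peptide-length versus C_sat correlation.
#'
#' @return A tibble with columns `length` (residues) and `csat_mM`.
#' @examples
#' gly_series() |> linear_fit()
#' @export
gly_series <- function() {
  tibble::tibble(
    length = 5:10,
    csat_mM = c(40, 25, 20, 12, 8, 2)
  )
}

#' Chromophore molar extinction coefficients
#'
#' Extinction coefficients used to convert dilute-phase absorbance into
#' concentration for the chromophore-bearing proteins: hemoglobin (Hb,
#' A406), myoglobin (Mb, A408), cytochrome c (Cyt c, A410) and catalase
#' (CATA, A405).
#'
#' @return A tibble with columns `protein`, `wavelength_nm` and
#'   `epsilon_M_cm` (per molar per cm).
#' @export
extinction_coefficients <- function() {
  tibble::tibble(
    protein = c("Hb", "Mb", "Cyt c", "CATA"),
    wavelength_nm = c(406, 408, 410, 405),
    epsilon_M_cm = c(270548, 129000, 101600, 324000)
  )
}

#' Reference crowder-partitioning intensities for beta-lactoglobulin
#'
#' Mean FITC-PEG fluorescence intensities measured inside (7.63 a.u.) and
#' outside (404.34 a.u.) beta-lactoglobulin condensates, averaged over >50
#' condensates. Their ratio is the apparent PEG partition coefficient.
#'
#' @return A tibble with columns `location` and `mean_intensity`.
#' @examples
#' blac_peg_intensities() |> partition_coefficient()
#' @export
blac_peg_intensities <- function() {
  tibble::tibble(
    location = c("inside", "outside"),
    mean_intensity = c(7.63, 404.34)
  )
}
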