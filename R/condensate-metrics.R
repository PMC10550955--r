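# Condensate statistics: dissolution-titration interaction decomposition,
# apparent crowder partition coefficient, phase-regime C_sat extraction and
# Beer-Lambert dilute-phase concentration.

.additive_map <- c(
  NaCl = "electrostatic",
  hexanediol = "hydrophobic",
  urea = "hbond"
)

#' Decompose a dissolution titration into interaction-type percentages
#'
#' A preformed condensate is titrated sequentially with NaCl (disrupts
#' electrostatic interactions), 1,6-hexanediol (hydrophobic) and urea
#' (H-bonding); the scattering drop attributable to each additive stage,
#' as a share of the total drop, estimates the relative contribution of
#' that interaction type to condensate stability. Drops are measured from
#' the value at each stage's start (the previous stage's end, or the
#' initial value) to the value at its end; a stage where scattering rises
#' contributes zero and the remaining stages are renormalized. Stages may
#' appear in any recorded order.
#'
#' @param series Data frame with columns `additive` (values `"NaCl"`,
#'   `"hexanediol"`, `"urea"` in titration order), `step` (step within the
#'   stage) and `scattering` (normalized so the pre-titration value is
#'   `initial_value`). [simulate_titration()] produces this shape.
#' @param initial_value Scattering before any additive (default 1).
#' @return One-row tibble with `pct_electrostatic`, `pct_hydrophobic`,
#'   `pct_hbond` (percentages summing to 100) and `residual_fraction` (the
#'   final scattering value).
#' @examples
#' simulate_titration(c(0.7, 0.1, 0.1), noise_sd = 0) |>
#'   dissolution_percentages()
#' @export
dissolution_percentages <- function(series, initial_value = 1) {
  stopifnot(all(c("additive", "scattering") %in% names(series)))
  if (!is.null(attr(series, "initial_value"))) {
    initial_value <- attr(series, "initial_value")
  }
  stopifnot(initial_value > 0, all(series$scattering >= 0))
  additives <- unique(series$additive)
  if (!setequal(additives, names(.additive_map))) {
    rlang::abort(paste0(
      "Need all three additive stages (",
      paste(names(.additive_map), collapse = ", "), "); got: ",
      paste(additives, collapse = ", ")
    ))
  }
  stage_end <- series |>
    dplyr::mutate(additive = factor(.data$additive, levels = additives)) |>
    dplyr::group_by(.data$additive) |>
    dplyr::summarise(
      end = dplyr::last(.data$scattering), .groups = "drop"
    )
  start <- c(initial_value, stage_end$end[-nrow(stage_end)])
  drops <- pmax(0, start - stage_end$end)
  total <- sum(drops)
  if (total <= 0) rlang::abort("No dissolution signal: total drop is zero")
  pct <- stats::setNames(
    100 * drops / total,
    .additive_map[as.character(stage_end$additive)]
  )
  tibble::tibble(
    pct_electrostatic = unname(pct["electrostatic"]),
    pct_hydrophobic = unname(pct["hydrophobic"]),
    pct_hbond = unname(pct["hbond"]),
    residual_fraction = stage_end$end[nrow(stage_end)] / initial_value
  )
}

#' Apparent partition coefficient from ROI intensities
#'
#' Ratio of mean fluorescence intensity inside condensates to outside —
#' since fluorescence is proportional to concentration, this is the
#' apparent partition coefficient of the labelled species (e.g. FITC-PEG)
#' into the dense phase.
#'
#' @param measurements Data frame with columns `location` (`"inside"` /
#'   `"outside"`) and `mean_intensity` (a.u.), one row per ROI.
#' @return The dimensionless ratio `mean(inside) / mean(outside)`.
#' @examples
#' blac_peg_intensities() |> partition_coefficient()
#' @export
partition_coefficient <- function(measurements) {
  stopifnot(all(c("location", "mean_intensity") %in% names(measurements)))
  inside <- measurements$mean_intensity[measurements$location == "inside"]
  outside <- measurements$mean_intensity[measurements$location == "outside"]
  if (length(inside) == 0 || length(outside) == 0) {
    rlang::abort("Need at least one inside and one outside ROI")
  }
  if (mean(outside) == 0) rlang::abort("Mean outside intensity is zero")
  mean(inside) / mean(outside)
}

#' Apparent C_sat from a phase-regime grid
#'
#' The apparent saturation concentration at a given crowder level is the
#' smallest protein concentration whose grid state is LLPS at that level.
#' Precipitate cells are treated as non-LLPS and never returned. If the
#' LLPS cells are non-contiguous (a soluble cell sits above the returned
#' concentration but below another LLPS cell) a warning is raised.
#'
#' @param grid Long-format data frame with columns `protein_conc`,
#'   `crowder_pct` and `state` (`"soluble"`, `"LLPS"`, `"precipitate"`).
#' @param crowder_level The crowder column (% w/v) to read.
#' @return The C_sat, in the units of `protein_conc`.
#' @examples
#' make_phase_grid(
#'   csat_by_crowder = c("10" = 2),
#'   protein_grid = c(0.5, 1, 2, 4), crowder_grid = 10
#' ) |> csat_from_grid(crowder_level = 10)
#' @export
csat_from_grid <- function(grid, crowder_level) {
  stopifnot(all(c("protein_conc", "crowder_pct", "state") %in% names(grid)))
  bad <- setdiff(unique(grid$state), c("soluble", "LLPS", "precipitate"))
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown state(s): ", paste(bad, collapse = ", ")))
  }
  col <- grid |>
    dplyr::filter(.data$crowder_pct == crowder_level) |>
    dplyr::arrange(.data$protein_conc)
  if (nrow(col) == 0) {
    rlang::abort(paste0("Crowder level ", crowder_level, " is not in the grid"))
  }
  llps <- which(col$state == "LLPS")
  if (length(llps) == 0) {
    rlang::abort(paste0("No C_sat at crowder level ", crowder_level,
                        ": no LLPS observed"))
  }
  if (any(col$state[seq(min(llps), max(llps))] == "soluble")) {
    rlang::warn("Non-contiguous LLPS regime: soluble point above C_sat")
  }
  col$protein_conc[min(llps)]
}

#' Dilute-phase concentration by Beer-Lambert
#'
#' Converts the absorbance of the (diluted) dilute phase into a protein
#' concentration via `c = A / (epsilon l)`, multiplied by the dilution
#' factor and expressed in micromolar.
#'
#' @param absorbance Absorbance at the measurement wavelength (>= 0).
#' @param epsilon Molar extinction coefficient (per molar per cm); see
#'   [extinction_coefficients()] for the packaged chromophore values.
#' @param path Cuvette path length in cm (default 1).
#' @param dilution_factor Fold dilution applied before measuring
#'   (default 1).
#' @return Concentration in micromolar.
#' @examples
#' dilute_phase_concentration(1.016, epsilon = 101600) # Cyt c at A410
#' @export
dilute_phase_concentration <- function(absorbance, epsilon, path = 1,
                                       dilution_factor = 1) {
  if (epsilon <= 0 || path <= 0) {
    rlang::abort("Extinction coefficient and path length must be positive")
  }
  stopifnot(all(absorbance >= 0), dilution_factor > 0)
  dilution_factor * absorbance / (epsilon * path) * 1e6
}
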