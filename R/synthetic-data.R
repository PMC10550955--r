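# Seeded generators for every input class the pipeline consumes, each with
# its ground truth attached as attr(x, "truth") so round-trip tests read the
# truth from the object, never from test-code constants.

#' Generate a toy atomic structure
#'
#' Deterministic test structures with analytically checkable SASA:
#' `"single_atom"` (one carbon), `"pair"` (two carbons `distance` apart on
#' the x axis) and `"extended_peptide"` (a peptide laid out in an extended
#' conformation with fixed ideal-bond-length backbone geometry; N, CA, C, O
#' plus CB for non-glycine residues). The seed only matters when
#' `jitter_sd > 0` or `n_models > 1`, where Gaussian coordinate jitter
#' produces distinct (ensemble) models.
#'
#' @param spec `"single_atom"`, `"pair"` or `"extended_peptide"`.
#' @param distance Pair separation in Angstroms (default 100, unoccluded).
#' @param sequence One-letter sequence for `"extended_peptide"`.
#' @param n_models Number of models (jittered copies) to emit.
#' @param jitter_sd Gaussian coordinate jitter in Angstroms (default 0;
#'   models beyond the first always receive jitter of at least 0.05 A so
#'   they differ).
#' @param seed Integer seed for the jitter.
#' @return A `pdb_atoms` tibble (see [read_structure()]) with the generator
#'   parameters in `attr(, "truth")`. Write to disk with [write_pdb()].
#' @examples
#' make_test_structure("extended_peptide", sequence = "GGGGG")
#' @export
make_test_structure <- function(spec = c("single_atom", "pair",
                                         "extended_peptide"),
                                distance = 100, sequence = NULL,
                                n_models = 1, jitter_sd = 0, seed = 1) {
  spec <- match.arg(spec)
  base <- switch(spec,
    single_atom = tibble::tibble(
      name = "C1", element = "C", x = 0, y = 0, z = 0,
      residue_name = "UNK", residue_index = "1", chain_id = "A"
    ),
    pair = tibble::tibble(
      name = c("C1", "C2"), element = "C",
      x = c(0, distance), y = 0, z = 0,
      residue_name = "UNK", residue_index = c("1", "2"), chain_id = "A"
    ),
    extended_peptide = {
      if (is.null(sequence) || nchar(sequence) == 0) {
        rlang::abort("extended_peptide requires a sequence")
      }
      codes <- strsplit(sequence, "")[[1]]
      three <- names(.aa_three_to_one)[match(codes, .aa_three_to_one)]
      if (anyNA(three)) {
        rlang::abort(paste0(
          "Unknown residue code(s): ",
          paste(unique(codes[is.na(three)]), collapse = ", ")
        ))
      }
      purrr::map_dfr(seq_along(codes), function(i) {
        # extended-chain backbone, ~3.8 A CA-CA rise, ideal bond lengths
        b <- (i - 1) * 3.8
        flip <- if (i %% 2 == 0) -1 else 1
        at <- tibble::tibble(
          name = c("N", "CA", "C", "O"),
          element = c("N", "C", "C", "O"),
          x = b + c(0, 1.2, 2.4, 2.6),
          y = flip * c(0.4, -0.5, 0.4, 1.6),
          z = 0
        )
        if (codes[i] != "G") {
          at <- dplyr::bind_rows(at, tibble::tibble(
            name = "CB", element = "C",
            x = b + 1.2, y = flip * -1.0, z = 1.3
          ))
        }
        at$residue_name <- three[i]
        at$residue_index <- as.character(i)
        at$chain_id <- "A"
        at
      })
    }
  )
  atoms <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_models), function(m) {
      a <- base
      sd_m <- if (m == 1) jitter_sd else max(jitter_sd, 0.05)
      if (sd_m > 0) {
        a$x <- a$x + stats::rnorm(nrow(a), 0, sd_m)
        a$y <- a$y + stats::rnorm(nrow(a), 0, sd_m)
        a$z <- a$z + stats::rnorm(nrow(a), 0, sd_m)
      }
      a$model <- m
      a
    })
  })
  atoms <- atoms |>
    dplyr::mutate(
      serial = dplyr::row_number(), is_hetero = FALSE, occupancy = 1
    ) |>
    dplyr::select(
      "model", "serial", "name", "element", "x", "y", "z",
      "residue_name", "residue_index", "chain_id", "is_hetero", "occupancy"
    )
  out <- new_pdb_atoms(atoms, source_id = paste0("synthetic:", spec))
  attr(out, "truth") <- list(
    kind = "structure", spec = spec, distance = distance,
    sequence = sequence, n_models = n_models,
    jitter_sd = jitter_sd, seed = seed
  )
  out
}

#' Simulate a Boltzmann sigmoid light-scattering trace
#'
#' Exact sigmoid values `y0 + (ymax - y0) / (1 + exp(-k (t - t_half)))`
#' plus i.i.d. Gaussian noise.
#'
#' @param y0,ymax Baseline and plateau intensities (normalized units).
#' @param k Rate constant in 1/s (non-zero).
#' @param t_half Assembly half-time in seconds.
#' @param t_grid Time grid in seconds.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return Tibble with `time` and `intensity`; generator parameters in
#'   `attr(, "truth")`.
#' @examples
#' simulate_boltzmann_trace(k = 0.05, t_half = 200, noise_sd = 0.02, seed = 11)
#' @export
simulate_boltzmann_trace <- function(y0 = 0, ymax = 1, k = 0.05,
                                     t_half = 200,
                                     t_grid = seq(0, 600, by = 5),
                                     noise_sd = 0, seed = 1) {
  stopifnot(k != 0, noise_sd >= 0)
  if (length(t_grid) == 0) rlang::abort("Empty time grid")
  y <- y0 + (ymax - y0) / (1 + exp(-k * (t_grid - t_half)))
  y <- withr::with_seed(seed, y + stats::rnorm(length(y), 0, noise_sd))
  out <- tibble::tibble(time = t_grid, intensity = y)
  attr(out, "truth") <- list(
    kind = "boltzmann_trace", y0 = y0, ymax = ymax, k = k, t_half = t_half,
    noise_sd = noise_sd, seed = seed
  )
  out
}

#' Simulate a raw three-ROI FRAP recording
#'
#' The bleach ROI follows the single exponential recovery
#' `A (1 - exp(-t / tau)) + C`, the reference ROI is constant 1 and the
#' background ROI constant 0. Optional multiplicative photofading
#' (`fading_per_frame`, fraction lost per frame) is applied to the bleach
#' and reference ROIs; i.i.d. Gaussian noise is added to all three.
#'
#' @param A Mobile fraction (recovery amplitude, normalized units).
#' @param tau Recovery time constant in seconds (> 0).
#' @param C Post-bleach offset.
#' @param t_grid Time grid in seconds (0 = first post-bleach frame).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param fading_per_frame Fraction of intensity lost per frame (>= 0).
#' @param seed Integer seed.
#' @return Tibble with `time`, `bleach`, `background`, `reference`;
#'   generator parameters in `attr(, "truth")`.
#' @examples
#' simulate_frap_trace(A = 0.8, tau = 5, C = 0.1, noise_sd = 0.03, seed = 3)
#' @export
simulate_frap_trace <- function(A = 0.8, tau = 5, C = 0.1,
                                t_grid = seq(0, 60, by = 0.2),
                                noise_sd = 0, fading_per_frame = 0,
                                seed = 1) {
  stopifnot(tau > 0, noise_sd >= 0)
  if (fading_per_frame < 0) rlang::abort("Negative fading is not allowed")
  if (length(t_grid) == 0) rlang::abort("Empty time grid")
  n <- length(t_grid)
  fade <- (1 - fading_per_frame)^(seq_len(n) - 1)
  signal <- A * (1 - exp(-t_grid / tau)) + C
  out <- withr::with_seed(seed, tibble::tibble(
    time = t_grid,
    bleach = signal * fade + stats::rnorm(n, 0, noise_sd),
    background = stats::rnorm(n, 0, noise_sd),
    reference = fade + stats::rnorm(n, 0, noise_sd)
  ))
  attr(out, "truth") <- list(
    kind = "frap_trace", A = A, tau = tau, C = C, noise_sd = noise_sd,
    fading_per_frame = fading_per_frame, seed = seed
  )
  out
}

#' Simulate a sequential dissolution titration
#'
#' Scattering starts at 1 and declines within each additive stage by its
#' assigned fraction of the initial signal (a smooth linear ramp across the
#' stage's steps), leaving a residual of `1 - sum(true_fractions)`.
#' Additive concentration steps mirror the standard protocol: NaCl
#' 50-150 mM, 1,6-hexanediol 2-15% w/v, urea 0.5-2 M.
#'
#' @param true_fractions Length-3 vector of scattering fractions dissolved
#'   by (NaCl, hexanediol, urea); non-negative, summing to at most 1.
#' @param steps_per_stage Concentration steps per additive stage.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @param order Stage order (a permutation of `"NaCl"`, `"hexanediol"`,
#'   `"urea"`).
#' @return Tibble with `stage`, `additive`, `step`, `concentration`,
#'   `units`, `scattering`; `attr(, "truth")` holds the generating
#'   fractions and `attr(, "initial_value")` is 1.
#' @examples
#' simulate_titration(c(0.5, 0.3, 0.1), noise_sd = 0.01, seed = 5)
#' @export
simulate_titration <- function(true_fractions, steps_per_stage = 3,
                               noise_sd = 0, seed = 1,
                               order = c("NaCl", "hexanediol", "urea")) {
  stopifnot(
    length(true_fractions) == 3, all(true_fractions >= 0),
    noise_sd >= 0, setequal(order, c("NaCl", "hexanediol", "urea"))
  )
  if (sum(true_fractions) > 1) {
    rlang::abort("Dissolved fractions cannot sum to more than 1")
  }
  conc <- list(
    NaCl = list(v = c(50, 150), u = "mM"),
    hexanediol = list(v = c(2, 15), u = "% w/v"),
    urea = list(v = c(0.5, 2), u = "M")
  )
  fr <- stats::setNames(true_fractions, c("NaCl", "hexanediol", "urea"))
  level <- 1
  rows <- purrr::map_dfr(seq_along(order), function(s) {
    add <- order[s]
    drop_per_step <- fr[[add]] / steps_per_stage
    vals <- level - cumsum(rep(drop_per_step, steps_per_stage))
    level <<- vals[steps_per_stage]
    tibble::tibble(
      stage = s, additive = add, step = seq_len(steps_per_stage),
      concentration = seq(conc[[add]]$v[1], conc[[add]]$v[2],
                          length.out = steps_per_stage),
      units = conc[[add]]$u,
      scattering = vals
    )
  })
  rows$scattering <- withr::with_seed(
    seed,
    pmax(0, rows$scattering + stats::rnorm(nrow(rows), 0, noise_sd))
  )
  attr(rows, "initial_value") <- 1
  attr(rows, "truth") <- list(
    kind = "titration", true_fractions = fr, order = order,
    steps_per_stage = steps_per_stage, noise_sd = noise_sd, seed = seed
  )
  rows
}

#' Simulate exposure-feature observations from a known C_sat model
#'
#' Draws the four category exposure sums uniformly in their stated ranges
#' and generates `log10(csat)` from the linear model plus Gaussian noise;
#' `csat = 10^value`.
#'
#' @param n Number of observations (>= 6, the fitter's minimum).
#' @param coefs Named list of generating coefficients (`n_polar`,
#'   `n_hydrophobic`, `n_charge`, `n_aromatic`, `intercept`); defaults to
#'   the published model's coefficients.
#' @param feature_ranges Named list of `c(min, max)` ranges for the four
#'   features (all non-negative; default 0-20 exposure units each).
#' @param noise_sd Gaussian noise on `log10(csat)` (>= 0).
#' @param seed Integer seed.
#' @return Tibble with `source_id`, the four feature columns and `csat`
#'   (concentration, uM scale); generating parameters in `attr(, "truth")`.
#' @examples
#' simulate_feature_table(n = 100, noise_sd = 0.1, seed = 2)
#' @export
simulate_feature_table <- function(n,
                                   coefs = published_csat_model()$coefficients,
                                   feature_ranges = NULL,
                                   noise_sd = 0, seed = 1) {
  if (n < 6) rlang::abort("Need n >= 6 (the fitter's minimum)")
  stopifnot(noise_sd >= 0)
  if (is.null(feature_ranges)) {
    feature_ranges <- stats::setNames(
      rep(list(c(0, 20)), 4), .feature_cols
    )
  }
  stopifnot(setequal(names(feature_ranges), .feature_cols))
  if (any(vapply(feature_ranges, function(r) {
    r[1] < 0 || r[2] <= r[1]
  }, logical(1)))) {
    rlang::abort("Feature ranges must be non-negative with max > min")
  }
  out <- withr::with_seed(seed, {
    feats <- purrr::map_dfc(feature_ranges[.feature_cols], function(r) {
      stats::runif(n, r[1], r[2])
    })
    log_csat <- coefs$n_polar * feats$n_polar +
      coefs$n_hydrophobic * feats$n_hydrophobic +
      coefs$n_charge * feats$n_charge +
      coefs$n_aromatic * feats$n_aromatic +
      coefs$intercept +
      stats::rnorm(n, 0, noise_sd)
    dplyr::bind_cols(
      tibble::tibble(source_id = sprintf("sim%03d", seq_len(n))),
      feats,
      tibble::tibble(csat = 10^log_csat)
    )
  })
  attr(out, "truth") <- list(
    kind = "feature_table", coefs = coefs, feature_ranges = feature_ranges,
    noise_sd = noise_sd, seed = seed
  )
  out
}

#' Build a phase-regime grid from known saturation concentrations
#'
#' Each cell is LLPS iff the protein concentration is at or above the
#' C_sat assigned to that crowder level, else soluble; concentrations at or
#' above `precipitate_above` (if given) are marked precipitate instead.
#'
#' @param csat_by_crowder Named numeric vector mapping crowder level
#'   (% w/v, as names) to C_sat in the protein-concentration units.
#' @param protein_grid Ascending protein concentrations.
#' @param crowder_grid Crowder levels (% w/v); defaults to the names of
#'   `csat_by_crowder`.
#' @param precipitate_above Optional concentration threshold for the
#'   precipitate band.
#' @return Long-format tibble with `protein_conc`, `crowder_pct`, `state`;
#'   the generating map in `attr(, "truth")`.
#' @examples
#' make_phase_grid(c("10" = 2), protein_grid = c(0.5, 1, 2, 4))
#' @export
make_phase_grid <- function(csat_by_crowder, protein_grid,
                            crowder_grid = as.numeric(names(csat_by_crowder)),
                            precipitate_above = NULL) {
  if (length(protein_grid) == 0 || length(crowder_grid) == 0) {
    rlang::abort("Empty grid")
  }
  stopifnot(!is.unsorted(protein_grid), length(csat_by_crowder) ==
              length(crowder_grid))
  grid <- tidyr::expand_grid(
    crowder_pct = crowder_grid,
    protein_conc = protein_grid
  ) |>
    dplyr::mutate(
      csat = csat_by_crowder[match(.data$crowder_pct, crowder_grid)],
      state = dplyr::case_when(
        !is.null(precipitate_above) &
          .data$protein_conc >= (precipitate_above %||% Inf) ~ "precipitate",
        .data$protein_conc >= .data$csat ~ "LLPS",
        TRUE ~ "soluble"
      )
    ) |>
    dplyr::select("protein_conc", "crowder_pct", "state")
  attr(grid, "truth") <- list(
    kind = "phase_grid", csat_by_crowder = csat_by_crowder,
    precipitate_above = precipitate_above
  )
  grid
}
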