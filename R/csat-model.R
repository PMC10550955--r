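# Effective-exposure features and the linear log10(C_sat) model.

#' Classify residues into interaction categories
#'
#' Maps one-letter codes to the four-way partition used by the C_sat model
#' (see [residue_classes()]). Vectorized; non-standard codes (including
#' `"X"`) are an error, so callers must drop unknown residues first.
#'
#' @param code Character vector of one-letter amino acid codes.
#' @return Character vector of categories (`"aromatic"`, `"polar"`,
#'   `"charged"`, `"hydrophobic"`).
#' @examples
#' classify_residue(c("H", "G", "D"))
#' @export
classify_residue <- function(code) {
  classes <- residue_classes()
  out <- classes$class[match(code, classes$code)]
  if (anyNA(out)) {
    rlang::abort(paste0(
      "Non-standard residue code(s): ",
      paste(unique(code[is.na(out)]), collapse = ", ")
    ))
  }
  out
}

#' Category exposure sums (model features)
#'
#' Sums per-residue effective exposure within each interaction category,
#' giving the four regressors of the C_sat model: `n_polar`,
#' `n_hydrophobic`, `n_charge`, `n_aromatic`. Residues with missing
#' exposure (unknown code) are skipped and counted in `n_skipped`.
#'
#' @param exposures Tibble from [residue_exposures()] or
#'   [ensemble_average_exposures()] (needs columns `code` and
#'   `effective_exposure`).
#' @param source_id Optional identifier carried into the output.
#' @return A one-row tibble with columns `source_id`, `n_polar`,
#'   `n_hydrophobic`, `n_charge`, `n_aromatic`, `n_skipped`.
#' @examples
#' tibble::tibble(code = c("W", "G"), effective_exposure = c(1, 0.5)) |>
#'   exposure_features()
#' @export
exposure_features <- function(exposures, source_id = NA_character_) {
  if (nrow(exposures) == 0) rlang::abort("No residues to summarise")
  ok <- !is.na(exposures$effective_exposure) & exposures$code != "X"
  kept <- exposures[ok, ]
  if (nrow(kept) == 0) rlang::abort("All residues have missing exposure")
  stopifnot(all(kept$effective_exposure >= 0 & kept$effective_exposure <= 1))
  sums <- kept |>
    dplyr::mutate(class = classify_residue(.data$code)) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n = sum(.data$effective_exposure), .groups = "drop")
  get <- function(cl) {
    v <- sums$n[sums$class == cl]
    if (length(v) == 0) 0 else v
  }
  tibble::tibble(
    source_id = source_id,
    n_polar = get("polar"),
    n_hydrophobic = get("hydrophobic"),
    n_charge = get("charged"),
    n_aromatic = get("aromatic"),
    n_skipped = sum(!ok)
  )
}

.feature_cols <- c("n_polar", "n_hydrophobic", "n_charge", "n_aromatic")

new_csat_model <- function(coefs, csat_units = "uM", fit = NULL) {
  stopifnot(
    all(c(.feature_cols, "intercept") %in% names(coefs)),
    all(is.finite(unlist(coefs)))
  )
  structure(
    list(
      coefficients = coefs[c(.feature_cols, "intercept")],
      csat_units = csat_units,
      fit = fit
    ),
    class = "csat_model"
  )
}

#' Fit the linear log10(C_sat) model
#'
#' Ordinary least squares of log10 saturation concentration on the four
#' category exposure sums plus an intercept — unweighted, unregularized.
#'
#' @param observations A data frame with columns `n_polar`,
#'   `n_hydrophobic`, `n_charge`, `n_aromatic` and `csat` (positive
#'   concentrations in `csat_units`); one row per protein.
#' @param csat_units Unit label recorded in the model (default `"uM"`).
#' @return A `csat_model` object. Inspect with [tidy()][generics::tidy] /
#'   [glance()][generics::glance]; the underlying `lm` fit is kept in
#'   `$fit`.
#' @examples
#' obs <- simulate_feature_table(n = 30, noise_sd = 0.05, seed = 1)
#' fit_csat_model(obs)
#' @export
fit_csat_model <- function(observations, csat_units = "uM") {
  stopifnot(all(c(.feature_cols, "csat") %in% names(observations)))
  if (nrow(observations) <= 5) {
    rlang::abort("Need at least 6 observations to fit 5 parameters")
  }
  if (any(observations$csat <= 0)) {
    rlang::abort("All csat values must be positive")
  }
  dat <- dplyr::mutate(observations, .log_csat = log10(.data$csat))
  fit <- stats::lm(
    .log_csat ~ n_polar + n_hydrophobic + n_charge + n_aromatic,
    data = dat
  )
  if (any(is.na(stats::coef(fit)))) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    rlang::abort(paste0(
      "Rank-deficient design: collinear feature(s) ",
      paste(dropped, collapse = ", ")
    ))
  }
  co <- stats::coef(fit)
  new_csat_model(
    as.list(stats::setNames(
      co[c(.feature_cols, "(Intercept)")],
      c(.feature_cols, "intercept")
    )),
    csat_units = csat_units,
    fit = fit
  )
}

#' The packaged published C_sat regression model
#'
#' The published coefficient set of the structure-based saturation
#' concentration predictor:
#' log10(C_sat) = -0.041 n_polar + 0.016 n_hydrophobic - 0.005 n_charge +
#' 0.026 n_aromatic + 2.24. Concentrations are interpreted in micromolar
#' (the published model reports protein C_sat in the ~1-600 uM range; the
#' intercept 2.24 corresponds to about 174 uM).
#'
#' @return A `csat_model` object with the published coefficients.
#' @examples
#' published_csat_model() |> predict_log10_csat(zero_features())
#' @export
published_csat_model <- function() {
  new_csat_model(
    list(
      n_polar = -0.041, n_hydrophobic = 0.016,
      n_charge = -0.005, n_aromatic = 0.026,
      intercept = 2.24
    ),
    csat_units = "uM"
  )
}

#' An all-zero feature row
#' @return One-row feature tibble with all four exposure sums equal to 0.
#' @export
zero_features <- function() {
  tibble::tibble(
    source_id = NA_character_, n_polar = 0, n_hydrophobic = 0,
    n_charge = 0, n_aromatic = 0, n_skipped = 0L
  )
}

#' Predict log10 saturation concentration
#'
#' Evaluates the linear predictor of a `csat_model` on feature rows.
#'
#' @param model A `csat_model` ([fit_csat_model()] or
#'   [published_csat_model()]).
#' @param features Data frame with the four feature columns (one or more
#'   rows, e.g. from [exposure_features()]).
#' @return Numeric vector of log10 concentrations (units
#'   `model$csat_units`).
#' @examples
#' predict_log10_csat(published_csat_model(), zero_features())
#' @export
predict_log10_csat <- function(model, features) {
  stopifnot(inherits(model, "csat_model"))
  stopifnot(all(.feature_cols %in% names(features)))
  co <- model$coefficients
  with(features,
    co$n_polar * n_polar + co$n_hydrophobic * n_hydrophobic +
      co$n_charge * n_charge + co$n_aromatic * n_aromatic + co$intercept
  )
}

#' Predict saturation concentration on the concentration scale
#'
#' @inheritParams predict_log10_csat
#' @return Numeric vector of concentrations, `10^log10(C_sat)`, in
#'   `model$csat_units`.
#' @export
predict_csat <- function(model, features) {
  10^predict_log10_csat(model, features)
}

#' @export
print.csat_model <- function(x, ...) {
  co <- x$coefficients
  cat("<csat_model> log10(C_sat [", x$csat_units, "]) =\n", sep = "")
  cat(sprintf(
    "  %+.4g n_polar %+.4g n_hydrophobic %+.4g n_charge %+.4g n_aromatic %+.4g\n",
    co$n_polar, co$n_hydrophobic, co$n_charge, co$n_aromatic, co$intercept
  ))
  if (!is.null(x$fit)) {
    cat(sprintf(
      "  fitted on %d observations, R-squared %.3f\n",
      stats::nobs(x$fit), summary(x$fit)$r.squared
    ))
  }
  invisible(x)
}

#' Serialize / restore a C_sat model as JSON
#'
#' @param model A `csat_model`.
#' @param path Output (input) file path.
#' @return `write_csat_model()` returns `path` invisibly;
#'   `read_csat_model()` returns a `csat_model`.
#' @export
write_csat_model <- function(model, path) {
  jsonlite::write_json(
    list(
      coefficients = model$coefficients,
      csat_units = model$csat_units
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_csat_model
#' @export
read_csat_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_csat_model(as.list(obj$coefficients), csat_units = obj$csat_units)
}
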