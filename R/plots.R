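# ggplot2 methods for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Boltzmann kinetics fit
#'
#' Scattering data as points with the fitted sigmoid and the half-time
#' marked.
#'
#' @param object A `boltzmann_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.boltzmann_fit <- function(object, ...) {
  aug <- augment(object)
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity),
                        alpha = 0.6, size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "#2c7fb8") +
    ggplot2::geom_vline(xintercept = object$t_half, linetype = "dashed") +
    ggplot2::labs(
      x = "Time (s)", y = "Normalized scattering",
      title = sprintf("Assembly kinetics: t1/2 = %.1f s", object$t_half)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a FRAP recovery fit
#'
#' @param object A `frap_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frap_fit <- function(object, ...) {
  aug <- augment(object)
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity),
                        alpha = 0.6, size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = object$A + object$C,
                        linetype = "dashed") +
    ggplot2::labs(
      x = "Time after bleach (s)", y = "Normalized intensity",
      title = sprintf(
        "FRAP: mobile fraction %.2f, t1/2 = %.2f s", object$A, object$t_half
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a phase-regime grid
#'
#' Tile plot of the protein x crowder state matrix in the conventional
#' colouring: soluble pink, LLPS blue, precipitate grey.
#'
#' @param grid Long-format grid (see [csat_from_grid()]).
#' @return A ggplot.
#' @export
plot_phase_grid <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(
    x = factor(.data$crowder_pct), y = factor(.data$protein_conc),
    fill = .data$state
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(
      soluble = "#f8b5c5", LLPS = "#6baed6", precipitate = "grey55"
    )) +
    ggplot2::labs(
      x = "Crowder (% w/v)", y = "Protein concentration",
      fill = "State"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a dissolution titration series
#'
#' Scattering against titration step, coloured by additive stage.
#'
#' @param series Titration tibble (see [dissolution_percentages()]).
#' @return A ggplot.
#' @export
plot_titration <- function(series) {
  dat <- dplyr::mutate(series, .idx = dplyr::row_number())
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$.idx, y = .data$scattering, colour = .data$additive
  )) +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey70") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Titration step", y = "Normalized scattering",
      colour = "Additive"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-residue effective exposure
#'
#' @param exposures Exposure tibble from [residue_exposures()] or
#'   [ensemble_average_exposures()].
#' @return A ggplot of effective exposure along the chain, coloured by
#'   interaction class.
#' @export
plot_exposures <- function(exposures) {
  dat <- exposures |>
    dplyr::mutate(
      position = dplyr::row_number(),
      class = ifelse(
        .data$code %in% residue_classes()$code,
        classify_residue(ifelse(
          .data$code %in% residue_classes()$code, .data$code, "G"
        )),
        "unknown"
      )
    )
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$position, y = .data$effective_exposure, fill = .data$class
  )) +
    ggplot2::geom_col() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = "Residue position", y = "Effective exposure", fill = "Class"
    ) +
    ggplot2::theme_minimal()
}
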