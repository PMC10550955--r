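# Simple correlation / regression analyses on optionally transformed axes.

.transforms <- list(
  identity = identity,
  log10 = log10,
  pow_2_3 = function(v) v^(2 / 3)
)

apply_one_transform <- function(v, transform, axis) {
  transform <- match.arg(transform, names(.transforms))
  if (transform == "log10" && any(v <= 0)) {
    rlang::abort(paste0(
      "log10 of non-positive ", axis, " value at index ",
      which(v <= 0)[1]
    ))
  }
  .transforms[[transform]](v)
}

#' Transform the axes of an x-y series
#'
#' Applies `identity`, `log10` or `pow_2_3` (the surface-area scaling
#' `v^(2/3)`) elementwise to the `x` and/or `y` columns.
#'
#' @param series Data frame with numeric columns `x` and `y`.
#' @param x_transform,y_transform One of `"identity"`, `"log10"`,
#'   `"pow_2_3"`.
#' @return The series with transformed columns; the transforms are recorded
#'   in attributes `x_transform` / `y_transform`.
#' @examples
#' apply_transform(tibble::tibble(x = 8000, y = 100), "pow_2_3", "log10")
#' @export
apply_transform <- function(series, x_transform = "identity",
                            y_transform = "identity") {
  stopifnot(all(c("x", "y") %in% names(series)))
  out <- dplyr::mutate(
    series,
    x = apply_one_transform(.data$x, x_transform, "x"),
    y = apply_one_transform(.data$y, y_transform, "y")
  )
  attr(out, "x_transform") <- x_transform
  attr(out, "y_transform") <- y_transform
  out
}

#' Ordinary least-squares line and Pearson correlation
#'
#' Fits `y ~ x` (after optional axis transforms) and reports the slope,
#' intercept, Pearson r and R-squared. For simple regression R-squared is
#' exactly the squared Pearson correlation. A constant-`y` series returns
#' `r = 0` with a warning; constant `x` is an error.
#'
#' @param series Data frame whose first two columns (or columns named `x`
#'   and `y`) hold the predictor and response.
#' @inheritParams apply_transform
#' @return One-row tibble: `slope`, `intercept`, `r`, `r_squared`, `n`,
#'   `x_transform`, `y_transform`.
#' @examples
#' gly_series() |> linear_fit()
#' @export
linear_fit <- function(series, x_transform = "identity",
                       y_transform = "identity") {
  if (!all(c("x", "y") %in% names(series))) {
    stopifnot(ncol(series) >= 2)
    series <- stats::setNames(series[, 1:2], c("x", "y"))
  }
  series <- series[stats::complete.cases(series[, c("x", "y")]), ]
  if (nrow(series) < 3) rlang::abort("Need at least 3 points to fit")
  series <- apply_transform(series, x_transform, y_transform)
  if (stats::sd(series$x) == 0) {
    rlang::abort("Zero variance in x: no line can be fitted")
  }
  fit <- stats::lm(y ~ x, data = series)
  if (stats::sd(series$y) == 0) {
    rlang::warn("Constant y: correlation reported as 0")
    r <- 0
  } else {
    r <- stats::cor(series$x, series$y)
  }
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = r,
    r_squared = r^2,
    n = nrow(series),
    x_transform = x_transform,
    y_transform = y_transform
  )
}
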