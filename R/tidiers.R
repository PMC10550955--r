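# broom-style tidy()/glance()/augment() methods for the fit classes.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a fitted C_sat model
#'
#' @param x A `csat_model`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`term`, `estimate`, and
#'   `std.error`/`statistic`/`p.value` when the model was fitted rather
#'   than packaged).
#' @export
tidy.csat_model <- function(x, ...) {
  if (!is.null(x$fit)) {
    out <- tibble::as_tibble(
      summary(x$fit)$coefficients, rownames = "term"
    )
    names(out) <- c("term", "estimate", "std.error", "statistic", "p.value")
    out$term[out$term == "(Intercept)"] <- "intercept"
    out
  } else {
    tibble::tibble(
      term = names(x$coefficients),
      estimate = unlist(x$coefficients)
    )
  }
}

#' @rdname tidy.csat_model
#' @export
glance.csat_model <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(
      r.squared = NA_real_, sigma = NA_real_, nobs = NA_integer_,
      csat_units = x$csat_units
    ))
  }
  s <- summary(x$fit)
  tibble::tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    sigma = s$sigma,
    nobs = stats::nobs(x$fit),
    csat_units = x$csat_units
  )
}

nls_tidy <- function(fit) {
  out <- tibble::as_tibble(summary(fit)$coefficients, rownames = "term")
  names(out) <- c("term", "estimate", "std.error", "statistic", "p.value")
  out
}

#' Tidy a Boltzmann kinetics fit
#'
#' @param x A `boltzmann_fit` from [fit_boltzmann()].
#' @param ... Unused.
#' @return `tidy()`: one row per parameter with standard errors.
#'   `glance()`: one-row fit summary (`t_half`, `rss`, `in_window`,
#'   `nobs`). `augment()`: the trace with `.fitted` and `.resid`.
#' @export
tidy.boltzmann_fit <- function(x, ...) nls_tidy(x$fit)

#' @rdname tidy.boltzmann_fit
#' @export
glance.boltzmann_fit <- function(x, ...) {
  tibble::tibble(
    t_half = x$t_half, k = x$k, rss = x$rss,
    in_window = x$in_window, nobs = nrow(x$data)
  )
}

#' @rdname tidy.boltzmann_fit
#' @export
augment.boltzmann_fit <- function(x, ...) {
  dplyr::mutate(
    x$data,
    .fitted = stats::fitted(x$fit),
    .resid = stats::resid(x$fit)
  )
}

#' Tidy a FRAP recovery fit
#'
#' @param x A `frap_fit` from [fit_frap()].
#' @param ... Unused.
#' @return `tidy()`: one row per parameter with standard errors.
#'   `glance()`: one-row summary (`mobile_fraction`, `tau`, `t_half`,
#'   `rss`, `nobs`). `augment()`: the trace with `.fitted` and `.resid`.
#' @export
tidy.frap_fit <- function(x, ...) nls_tidy(x$fit)

#' @rdname tidy.frap_fit
#' @export
glance.frap_fit <- function(x, ...) {
  tibble::tibble(
    mobile_fraction = x$A, tau = x$tau, t_half = x$t_half,
    rss = x$rss, nobs = nrow(x$data)
  )
}

#' @rdname tidy.frap_fit
#' @export
augment.frap_fit <- function(x, ...) {
  dplyr::mutate(
    x$data,
    .fitted = stats::fitted(x$fit),
    .resid = stats::resid(x$fit)
  )
}
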