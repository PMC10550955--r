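# Time-series assay fitting: Boltzmann sigmoid LLPS kinetics and single
# exponential FRAP recovery. Nonlinear least squares via minpack.lm
# (Levenberg-Marquardt), convergence tolerance 1e-10 on the cost.

check_trace <- function(trace, min_points = 8) {
  stopifnot(all(c("time", "intensity") %in% names(trace)))
  if (nrow(trace) < min_points) {
    rlang::abort(paste0("Need at least ", min_points, " points to fit"))
  }
  if (!all(is.finite(trace$time)) || is.unsorted(trace$time, strictly = TRUE)) {
    rlang::abort("Times must be finite and strictly increasing")
  }
  invisible(trace)
}

#' Background-correct and normalize an assay trace
#'
#' Subtracts a baseline — the first point, or a pointwise blank trace — and
#' divides by the post-subtraction maximum so the trace peaks at 1.
#' Idempotent on already-normalized traces.
#'
#' @param trace Data frame with columns `time` (seconds, strictly
#'   increasing) and `intensity` (arbitrary units).
#' @param baseline `"first_point"` (default) or `"blank"`.
#' @param blank Numeric vector of blank intensities (same length as the
#'   trace) when `baseline = "blank"`.
#' @return A tibble with the same columns, `intensity` normalized to
#'   max 1, and a `normalized` attribute.
#' @examples
#' normalize_trace(tibble::tibble(time = 1:4, intensity = c(2, 2, 4, 6)))
#' @export
normalize_trace <- function(trace, baseline = c("first_point", "blank"),
                            blank = NULL) {
  baseline <- match.arg(baseline)
  stopifnot(all(c("time", "intensity") %in% names(trace)))
  y <- trace$intensity
  y <- if (baseline == "first_point") {
    y - y[1]
  } else {
    stopifnot(!is.null(blank), length(blank) == length(y))
    y - blank
  }
  m <- max(y)
  if (m <= 0) rlang::abort("Flat trace: zero post-subtraction maximum")
  out <- tibble::tibble(time = trace$time, intensity = y / m)
  attr(out, "normalized") <- TRUE
  out
}

#' Fit Boltzmann sigmoid assembly kinetics
#'
#' Fits `y = y0 + (ymax - y0) / (1 + exp(-k (t - t_half)))` to a
#' (normalized) light-scattering trace by Levenberg-Marquardt least
#' squares, and reports the assembly half-time `t_half`.
#'
#' Starting values: `y0` from the minimum, `ymax` from the maximum,
#' `t_half` from the linearly interpolated half-crossing, and
#' `k = 4 / (t90 - t10)`. `y0`/`ymax` are bounded in \[-0.2, 1.5\] and
#' `k > 0`; up to 5 deterministically jittered restarts are attempted on
#' failure. A monotone-decreasing trace is fitted with `k < 0` plus a
#' warning.
#'
#' @param trace Data frame with columns `time` and `intensity` (>= 8
#'   points, normalized).
#' @return An object of class `boltzmann_fit` with elements `y0`, `ymax`,
#'   `k` (1/s), `t_half` (s), `rss`, `in_window` (is `t_half` inside the
#'   fitted time range?) and the underlying `nls` fit. Supports
#'   [tidy()][generics::tidy], [glance()][generics::glance] and
#'   [autoplot()][ggplot2::autoplot].
#' @examples
#' tr <- simulate_boltzmann_trace(k = 0.05, t_half = 200, noise_sd = 0)
#' fit_boltzmann(tr)
#' @export
fit_boltzmann <- function(trace) {
  check_trace(trace)
  t <- trace$time
  y <- trace$intensity
  rising <- stats::cor(t, y) >= 0
  if (!rising) {
    rlang::warn("Monotone-decreasing trace: fitting with k < 0")
  }
  yd <- if (rising) y else -y
  half <- (min(yd) + max(yd)) / 2
  cross <- which(yd >= half)[1]
  t_half0 <- if (is.na(cross) || cross == 1) stats::median(t) else {
    stats::approx(yd[(cross - 1):cross], t[(cross - 1):cross], xout = half)$y
  }
  q <- function(p) {
    i <- which(yd >= min(yd) + p * (max(yd) - min(yd)))[1]
    t[max(i, 1)]
  }
  dk <- max(q(0.9) - q(0.1), diff(range(t)) / 100)
  start <- list(
    y0 = min(y), ymax = max(y),
    k = (if (rising) 1 else -1) * 4 / dk, t_half = t_half0
  )
  lower <- c(y0 = -0.2, ymax = -0.2,
             k = if (rising) 1e-12 else -Inf, t_half = -Inf)
  upper <- c(y0 = 1.5, ymax = 1.5,
             k = if (rising) Inf else -1e-12, t_half = Inf)
  fit <- nls_with_restarts(
    intensity ~ y0 + (ymax - y0) / (1 + exp(-k * (time - t_half))),
    data = trace, start = start, lower = lower, upper = upper
  )
  p <- as.list(stats::coef(fit))
  structure(
    list(
      y0 = p$y0, ymax = p$ymax, k = p$k, t_half = p$t_half,
      rss = sum(stats::resid(fit)^2),
      in_window = p$t_half >= min(t) && p$t_half <= max(t),
      fit = fit, data = trace
    ),
    class = "boltzmann_fit"
  )
}

# LM least squares with deterministic jittered restarts on failure
nls_with_restarts <- function(formula, data, start, lower, upper,
                              restarts = 5) {
  last_err <- NULL
  for (attempt in seq_len(restarts)) {
    st <- start
    if (attempt > 1) {
      st <- withr::with_seed(1000L + attempt, {
        lapply(start, function(v) v * stats::runif(1, 0.5, 1.5) +
                 stats::rnorm(1, 0, 0.01))
      })
      st <- Map(function(v, lo, hi) min(max(v, lo + 1e-8), hi - 1e-8),
                st, as.list(lower[names(st)]), as.list(upper[names(st)]))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(
        formula, data = data, start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(
          ftol = 1e-10, ptol = 1e-10, maxiter = 500
        )
      ),
      error = function(e) e
    )
    if (!inherits(fit, "error")) return(fit)
    last_err <- fit
  }
  rlang::abort(c(
    paste0("Fit did not converge after ", restarts, " restarts"),
    conditionMessage(last_err)
  ))
}

#' Background- and photofading-correct a raw FRAP recording
#'
#' Double normalization of the bleached region of interest (ROI): subtract
#' the background ROI, divide by the background-subtracted reference ROI
#' (removing passive bleaching / photofading), then divide by the
#' pre-bleach level so the pre-bleach intensity maps to 1.
#'
#' @param raw Data frame with columns `time` (s; 0 = first post-bleach
#'   frame), `bleach`, `background` and `reference` ROI intensity vectors.
#' @param prebleach Pre-bleach corrected ROI ratio mapped to 1. Defaults to
#'   1, i.e. the bleach and reference ROIs are assumed equally bright
#'   before the bleach.
#' @return Tibble with columns `time` and `intensity`; the correction
#'   recipe is recorded in `attr(, "normalization")`.
#' @examples
#' raw <- simulate_frap_trace(A = 0.8, tau = 5, C = 0.1, noise_sd = 0)
#' preprocess_frap(raw)
#' @export
preprocess_frap <- function(raw, prebleach = 1) {
  stopifnot(
    all(c("time", "bleach", "background", "reference") %in% names(raw)),
    prebleach > 0
  )
  denom <- raw$reference - raw$background
  if (any(denom <= 0)) {
    rlang::abort("Reference ROI must exceed background at every frame")
  }
  out <- tibble::tibble(
    time = raw$time,
    intensity = (raw$bleach - raw$background) / denom / prebleach
  )
  attr(out, "normalization") <-
    "(bleach - background) / (reference - background) / prebleach"
  out
}

#' Fit single exponential FRAP recovery
#'
#' Fits `I(t) = A (1 - exp(-t / tau)) + C` to a normalized post-bleach
#' trace. `A` is the mobile fraction, `C` the intensity immediately after
#' the bleach, and the recovery half-time is the identity
#' `t_half = tau * ln 2`.
#'
#' @param trace Data frame with columns `time` (s, 0 at the bleach) and
#'   `intensity` (normalized).
#' @return An object of class `frap_fit` with elements `A`, `tau` (s), `C`,
#'   `t_half` (s), `rss` and the underlying `nls` fit. Supports
#'   [tidy()][generics::tidy], [glance()][generics::glance] and
#'   [autoplot()][ggplot2::autoplot].
#' @examples
#' simulate_frap_trace(A = 0.8, tau = 5, C = 0.1, noise_sd = 0) |>
#'   preprocess_frap() |>
#'   fit_frap()
#' @export
fit_frap <- function(trace) {
  check_trace(trace)
  t <- trace$time
  y <- trace$intensity
  a0 <- max(y[length(y)] - y[1], 0.05)
  i63 <- which(y >= y[1] + (1 - exp(-1)) * a0)[1]
  tau0 <- if (is.na(i63) || t[i63] <= 0) max(t) / 3 else t[i63]
  fit <- nls_with_restarts(
    intensity ~ A * (1 - exp(-time / tau)) + C,
    data = trace,
    start = list(A = a0, tau = tau0, C = y[1]),
    lower = c(A = -Inf, tau = 1e-9, C = -Inf),
    upper = c(A = Inf, tau = Inf, C = Inf)
  )
  p <- as.list(stats::coef(fit))
  if (p$tau <= 1e-8 || p$A <= 0) {
    rlang::abort("Non-recovering trace: no positive recovery time constant")
  }
  structure(
    list(
      A = p$A, tau = p$tau, C = p$C, t_half = p$tau * log(2),
      rss = sum(stats::resid(fit)^2),
      fit = fit, data = trace
    ),
    class = "frap_fit"
  )
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf(
    "<boltzmann_fit> y0 = %.4g, ymax = %.4g, k = %.4g /s, t_half = %.4g s (rss %.3g)\n",
    x$y0, x$ymax, x$k, x$t_half, x$rss
  ))
  if (!x$in_window) cat("  note: t_half outside the fitted time window\n")
  invisible(x)
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "<frap_fit> mobile fraction A = %.4g, tau = %.4g s, C = %.4g, t_half = %.4g s (rss %.3g)\n",
    x$A, x$tau, x$C, x$t_half, x$rss
  ))
  invisible(x)
}
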