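test_that("normalization subtracts baseline and scales the maximum to 1", {
  tr <- tibble::tibble(time = 1:4, intensity = c(2, 2, 4, 6))
  expect_equal(normalize_trace(tr)$intensity, c(0, 0, 0.5, 1))

  already <- tibble::tibble(time = 1:5, intensity = c(0, 0.2, 0.5, 0.9, 1))
  expect_equal(normalize_trace(already)$intensity, already$intensity)
  # idempotence
  expect_equal(
    normalize_trace(normalize_trace(tr))$intensity,
    normalize_trace(tr)$intensity
  )

  flat <- tibble::tibble(time = 1:3, intensity = c(5, 5, 5))
  expect_error(normalize_trace(flat), "Flat trace")

  blanked <- normalize_trace(
    tibble::tibble(time = 1:4, intensity = c(3, 4, 5, 7)),
    baseline = "blank", blank = c(3, 3, 3, 3)
  )
  expect_equal(blanked$intensity, c(0, 0.25, 0.5, 1))
})

test_that("noiseless sigmoid traces are recovered essentially exactly", {
  tr <- simulate_boltzmann_trace(
    y0 = 0, ymax = 1, k = 0.05, t_half = 200,
    t_grid = seq(0, 600, 5), noise_sd = 0
  )
  fit <- fit_boltzmann(tr)
  expect_equal(fit$t_half, 200, tolerance = 0.1 / 200)
  expect_equal(fit$k, 0.05, tolerance = 1e-4)
  expect_equal(fit$y0, 0, tolerance = 1e-4)
  expect_equal(fit$ymax, 1, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-8)
  expect_true(fit$in_window)

  # sigmoid midpoint identity: fitted value at t_half is (y0 + ymax) / 2
  at_half <- stats::predict(fit$fit, newdata = list(time = fit$t_half))
  expect_equal(at_half, (fit$y0 + fit$ymax) / 2, tolerance = 1e-8)
})

test_that("a noisy sigmoid still localizes the half-time within 5%", {
  tr <- simulate_boltzmann_trace(
    k = 0.05, t_half = 200, noise_sd = 0.02, seed = 11
  )
  fit <- fit_boltzmann(tr)
  expect_lt(abs(fit$t_half - 200) / 200, 0.05)
})

test_that("shifting the time axis shifts only the half-time", {
  tr <- simulate_boltzmann_trace(k = 0.05, t_half = 200, noise_sd = 0)
  f0 <- fit_boltzmann(tr)
  shifted <- dplyr::mutate(tr, time = time + 150)
  f1 <- fit_boltzmann(shifted)
  expect_equal(f1$t_half, f0$t_half + 150, tolerance = 1e-6)
  expect_equal(f1$k, f0$k, tolerance = 1e-6)
  expect_equal(f1$y0, f0$y0, tolerance = 1e-6)
  expect_equal(f1$ymax, f0$ymax, tolerance = 1e-6)
})

test_that("monotone-decreasing traces fit with negative rate and a warning", {
  tr <- simulate_boltzmann_trace(
    y0 = 1, ymax = 0, k = 0.05, t_half = 200, noise_sd = 0
  )
  # y0 > ymax written as decreasing sigmoid: equivalent to k < 0 rising form
  expect_warning(fit <- fit_boltzmann(tr), "k < 0")
  expect_lt(fit$k, 0)
  expect_lt(fit$rss, 1e-8)
})

test_that("FRAP preprocessing applies the double normalization", {
  # background 0, constant reference: output proportional to the bleach ROI
  raw <- tibble::tibble(
    time = seq(0, 10, 0.5),
    bleach = seq(0.2, 0.9, length.out = 21),
    background = 0, reference = 2
  )
  out <- preprocess_frap(raw)
  expect_equal(out$intensity, raw$bleach / 2)

  # bleach identical to reference: flat unity (nothing was bleached)
  nb <- tibble::tibble(
    time = 0:9, bleach = 0.97^(0:9), background = 0, reference = 0.97^(0:9)
  )
  expect_equal(preprocess_frap(nb)$intensity, rep(1, 10))

  bad <- dplyr::mutate(raw, background = 3)
  expect_error(preprocess_frap(bad), "exceed background")
})

test_that("noiseless FRAP parameters are recovered to four decimals", {
  tr <- simulate_frap_trace(
    A = 0.8, tau = 5, C = 0.1, t_grid = seq(0, 60, 0.2), noise_sd = 0
  ) |> preprocess_frap()
  fit <- fit_frap(tr)
  expect_equal(fit$A, 0.8, tolerance = 1e-4)
  expect_equal(fit$tau, 5, tolerance = 1e-4)
  expect_equal(fit$C, 0.1, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-8)
})

test_that("the recovery half-time identity t_half = tau ln 2 is exact", {
  tr <- simulate_frap_trace(A = 0.7, tau = 10, C = 0.2, noise_sd = 0) |>
    preprocess_frap()
  fit <- fit_frap(tr)
  expect_identical(fit$t_half, fit$tau * log(2))
  expect_equal(fit$t_half, 10 * log(2), tolerance = 1e-4)
})

test_that("a noisy recovery still pins the mobile fraction within 0.05", {
  tr <- simulate_frap_trace(A = 0.8, tau = 5, C = 0.1,
                            noise_sd = 0.03, seed = 3) |>
    preprocess_frap()
  fit <- fit_frap(tr)
  expect_lt(abs(fit$A - 0.8), 0.05)
})

test_that("reference-ratio correction removes photofading", {
  for (seed in 1:5) {
    raw <- simulate_frap_trace(
      A = 0.8, tau = 5, C = 0.1, noise_sd = 0,
      fading_per_frame = 0.01, seed = seed
    )
    fit <- fit_frap(preprocess_frap(raw))
    expect_lt(abs(fit$tau - 5) / 5, 0.02)
  }
})

test_that("a non-recovering trace is an error, not a fit", {
  dead <- tibble::tibble(
    time = seq(0, 30, 1),
    intensity = 0.15 + c(0, rep(c(1e-4, -1e-4), 15))
  )
  expect_error(fit_frap(dead), "Non-recovering")
})

test_that("tidy, glance, augment and autoplot work on both fit types", {
  bf <- fit_boltzmann(simulate_boltzmann_trace(noise_sd = 0.01, seed = 2))
  expect_setequal(tidy(bf)$term, c("y0", "ymax", "k", "t_half"))
  expect_equal(nrow(glance(bf)), 1)
  expect_equal(nrow(augment(bf)), nrow(bf$data))
  expect_s3_class(autoplot(bf), "ggplot")

  ff <- fit_frap(preprocess_frap(
    simulate_frap_trace(noise_sd = 0.01, seed = 2)
  ))
  expect_setequal(tidy(ff)$term, c("A", "tau", "C"))
  expect_equal(glance(ff)$t_half, ff$tau * log(2))
  expect_s3_class(autoplot(ff), "ggplot")
})
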