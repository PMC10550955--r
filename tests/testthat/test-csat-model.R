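test_that("residue categories follow the four-way partition", {
  expect_equal(classify_residue("H"), "aromatic")
  expect_equal(classify_residue("G"), "hydrophobic")
  expect_equal(classify_residue("D"), "charged")
  expect_equal(
    classify_residue(c("W", "P", "R", "A")),
    c("aromatic", "polar", "charged", "hydrophobic")
  )
  expect_error(classify_residue("X"), "Non-standard")

  # exhaustive and disjoint over the 20 standard codes
  classes <- residue_classes()
  expect_equal(nrow(classes), 20)
  expect_equal(anyDuplicated(classes$code), 0)
  expect_setequal(classes$code, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
})

test_that("feature sums add effective exposures within each category", {
  wg <- tibble::tibble(code = c("W", "G"), effective_exposure = c(1, 0.5))
  f <- exposure_features(wg)
  expect_equal(f$n_aromatic, 1)
  expect_equal(f$n_hydrophobic, 0.5)
  expect_equal(f$n_polar, 0)
  expect_equal(f$n_charge, 0)

  zeros <- tibble::tibble(
    code = c("W", "G", "S", "D"), effective_exposure = 0
  )
  expect_equal(
    unlist(exposure_features(zeros)[, 2:5], use.names = FALSE),
    rep(0, 4)
  )

  arg10 <- tibble::tibble(code = rep("R", 10), effective_exposure = 1)
  f10 <- exposure_features(arg10)
  expect_equal(f10$n_charge, 10)
  expect_equal(f10$n_polar + f10$n_hydrophobic + f10$n_aromatic, 0)

  # unknown codes are skipped and counted
  mixed <- tibble::tibble(
    code = c("R", "X"), effective_exposure = c(0.5, NA)
  )
  fm <- exposure_features(mixed)
  expect_equal(fm$n_charge, 0.5)
  expect_equal(fm$n_skipped, 1L)
})

test_that("noiseless observations are interpolated exactly", {
  truth <- list(
    n_polar = -0.04, n_hydrophobic = 0.02, n_charge = -0.01,
    n_aromatic = 0.03, intercept = 2.0
  )
  obs <- simulate_feature_table(n = 8, coefs = truth, noise_sd = 0, seed = 5)
  fit <- fit_csat_model(obs)
  expect_equal(unlist(fit$coefficients), unlist(truth), tolerance = 1e-7)
  # base R warns that a perfect fit makes summary() unreliable; expected here
  expect_equal(suppressWarnings(glance(fit)$r.squared), 1, tolerance = 1e-12)
})

test_that("underdetermined and degenerate designs are rejected", {
  obs <- simulate_feature_table(n = 8, noise_sd = 0, seed = 1)
  expect_error(fit_csat_model(obs[1:4, ]), "at least 6")
  collinear <- dplyr::mutate(obs, n_polar = 2 * n_charge)
  expect_error(fit_csat_model(collinear), "Rank-deficient")
  bad <- dplyr::mutate(obs, csat = c(-1, csat[-1]))
  expect_error(fit_csat_model(bad), "positive")
})

test_that("noisy coefficients land within three standard errors of truth", {
  obs <- simulate_feature_table(n = 100, noise_sd = 0.1, seed = 2)
  truth <- attr(obs, "truth")$coefs
  fit <- fit_csat_model(obs)
  td <- tidy(fit)
  for (term in names(truth)) {
    row <- td[td$term == term, ]
    expect_lt(abs(row$estimate - truth[[term]]), 3 * row$std.error)
  }
  expect_gt(glance(fit)$r.squared, 0.8)
})

test_that("the packaged published model carries the printed coefficients", {
  m <- published_csat_model()
  expect_equal(m$coefficients$n_polar, -0.041)
  expect_equal(m$coefficients$n_hydrophobic, 0.016)
  expect_equal(m$coefficients$n_charge, -0.005)
  expect_equal(m$coefficients$n_aromatic, 0.026)
  expect_equal(m$coefficients$intercept, 2.24)
  expect_equal(m$csat_units, "uM")
})

test_that("prediction is the linear predictor and exponentiates correctly", {
  m <- published_csat_model()
  expect_identical(predict_log10_csat(m, zero_features()), 2.24)
  one_polar <- dplyr::mutate(zero_features(), n_polar = 1)
  expect_equal(predict_log10_csat(m, one_polar), 2.24 - 0.041)
  expect_equal(predict_csat(m, zero_features()), 10^2.24)

  # linearity: f(a + b) + f(0) = f(a) + f(b)
  fa <- dplyr::mutate(zero_features(), n_polar = 2, n_aromatic = 1)
  fb <- dplyr::mutate(zero_features(), n_hydrophobic = 3, n_charge = 4)
  fab <- dplyr::mutate(zero_features(),
    n_polar = 2, n_aromatic = 1, n_hydrophobic = 3, n_charge = 4
  )
  expect_equal(
    predict_log10_csat(m, fab) + predict_log10_csat(m, zero_features()),
    predict_log10_csat(m, fa) + predict_log10_csat(m, fb),
    tolerance = 1e-12
  )
})

test_that("fitting a model's own noiseless predictions returns the model", {
  for (seed in 1:3) {
    coefs <- withr::with_seed(seed, list(
      n_polar = stats::runif(1, -0.1, 0.1),
      n_hydrophobic = stats::runif(1, -0.1, 0.1),
      n_charge = stats::runif(1, -0.1, 0.1),
      n_aromatic = stats::runif(1, -0.1, 0.1),
      intercept = stats::runif(1, 1, 3)
    ))
    obs <- simulate_feature_table(
      n = 12, coefs = coefs, noise_sd = 0, seed = seed
    )
    refit <- fit_csat_model(obs)
    expect_equal(unlist(refit$coefficients), unlist(coefs),
                 tolerance = 1e-8)
  }
})

test_that("models serialize to JSON and back unchanged", {
  m <- published_csat_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_csat_model(m, path)
  back <- read_csat_model(path)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$csat_units, m$csat_units)
})

test_that("structure-to-prediction pipeline runs end to end", {
  pep <- make_test_structure("extended_peptide", sequence = "GAVRWSTD")
  pred <- shrake_rupley(pep) |>
    residue_exposures(extract_sequence(pep)) |>
    exposure_features(source_id = "pep") |>
    (\(f) predict_csat(published_csat_model(), f))()
  expect_true(is.finite(pred) && pred > 0)
})
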