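sphere_area <- function(r_vdw, probe = 1.4) 4 * pi * (r_vdw + probe)^2

test_that("an isolated atom reports the full analytic sphere area", {
  res <- shrake_rupley(make_test_structure("single_atom"))
  expect_equal(res$per_atom$area, sphere_area(1.7), tolerance = 1e-12)
})

test_that("widely separated atoms are unoccluded", {
  res <- shrake_rupley(make_test_structure("pair", distance = 100))
  expect_equal(res$per_atom$area, rep(sphere_area(1.7), 2), tolerance = 1e-12)
  expect_equal(sum(res$per_atom$area), 2 * sphere_area(1.7),
               tolerance = 1e-12)
})

test_that("close-pair areas match the Monte-Carlo oracle within 2%", {
  pair <- make_test_structure("pair", distance = 2)
  sr <- shrake_rupley(pair)
  mc <- monte_carlo_sasa(pair, n_samples = 1e5, seed = 7)
  expect_lt(max(abs(sr$per_atom$area - mc$area) / mc$area), 0.02)
})

test_that("the Monte-Carlo oracle matches the analytic sphere and detects burial", {
  mc1 <- monte_carlo_sasa(make_test_structure("single_atom"),
                          n_samples = 1e5, seed = 7)
  expect_lt(abs(mc1$area - sphere_area(1.7)), 3 * max(mc1$se, 1e-12))

  # nitrogen (expanded radius 2.95) centred inside a sulfur sphere (3.2):
  # fully engulfed, zero area by both routes
  atoms <- carbon_cluster(matrix(0, 1, 3))
  engulfed <- phasesep:::new_pdb_atoms(dplyr::bind_rows(
    dplyr::mutate(atoms, element = "S"),
    dplyr::mutate(atoms, element = "N", serial = 2L, residue_index = "2")
  ))
  expect_equal(monte_carlo_sasa(engulfed, n_samples = 1e4, seed = 1)$area[2], 0)
  expect_equal(shrake_rupley(engulfed)$per_atom$area[2], 0)
})

test_that("adding an atom never increases any other atom's area", {
  # exact with the globally oriented lattice, where the test points of the
  # retained atoms are unchanged by the addition
  for (seed in 1:5) {
    base <- random_carbon_cluster(6, seed)
    extra <- withr::with_seed(seed + 100, tibble::tibble(
      model = 1L, serial = 7L, name = "C7", element = "C",
      x = stats::rnorm(1, sd = 2), y = stats::rnorm(1, sd = 2),
      z = stats::rnorm(1, sd = 2),
      residue_name = "UNK", residue_index = "7", chain_id = "A",
      is_hetero = FALSE, occupancy = 1
    ))
    bigger <- phasesep:::new_pdb_atoms(dplyr::bind_rows(base, extra))
    a0 <- shrake_rupley(base, frame = "fixed")$per_atom$area
    a1 <- shrake_rupley(bigger, frame = "fixed")$per_atom$area[1:6]
    expect_true(all(a1 <= a0 + 1e-9))
    # and under the principal-axes lattice it holds to lattice resolution
    p0 <- shrake_rupley(base)$per_atom$area
    p1 <- shrake_rupley(bigger)$per_atom$area[1:6]
    expect_true(all(p1 <= p0 + 0.02 * pmax(p0, 1)))
  }
})

test_that("the two lattice orientations agree to lattice resolution", {
  for (seed in 1:3) {
    cl <- random_carbon_cluster(8, seed)
    a <- shrake_rupley(cl)$per_atom$area
    b <- shrake_rupley(cl, frame = "fixed")$per_atom$area
    expect_lt(max(abs(a - b)) / mean(b), 0.02)
  }
})

test_that("total area is converged at the default point density", {
  for (seed in 1:3) {
    cl <- random_carbon_cluster(8, seed)
    t1 <- sum(shrake_rupley(cl, n_points = 960)$per_atom$area)
    t2 <- sum(shrake_rupley(cl, n_points = 3840)$per_atom$area)
    expect_lt(abs(t1 - t2) / t2, 0.01)
  }
})

test_that("areas are invariant under rotation and translation", {
  xyz <- withr::with_seed(11, matrix(stats::rnorm(24, sd = 2), ncol = 3))
  a <- shrake_rupley(carbon_cluster(xyz))$per_atom$area
  th <- 0.83
  rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rx <- rbind(c(1, 0, 0), c(0, cos(1.1), -sin(1.1)), c(0, sin(1.1), cos(1.1)))
  moved <- sweep(xyz %*% t(rz) %*% t(rx), 2, c(7, -4, 13), "+")
  b <- shrake_rupley(carbon_cluster(moved))$per_atom$area
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("per-residue area is exactly the sum of member-atom areas", {
  pep <- make_test_structure("extended_peptide", sequence = "GAVRW")
  res <- shrake_rupley(pep)
  by_hand <- res$per_atom |>
    dplyr::group_by(residue_index) |>
    dplyr::summarise(area = sum(area))
  expect_equal(
    res$per_residue$area[match(by_hand$residue_index,
                               res$per_residue$residue_index)],
    by_hand$area
  )
})

test_that("effective exposure normalizes, clamps and bounds to [0, 1]", {
  per_res <- tibble::tibble(
    model = 1L, chain_id = "A", residue_index = c("1", "2", "3"),
    residue_name = c("GLY", "GLY", "GLY"),
    area = c(104, 0, 1.2 * 104) # = max, buried, above max (terminal)
  )
  ex <- residue_exposures(fake_sasa_result(per_res), "GGG")
  expect_equal(ex$effective_exposure, c(1, 0, 1))
  expect_true(all(ex$effective_exposure >= 0 & ex$effective_exposure <= 1))
})

test_that("exposure computation rejects mismatched sequence lengths", {
  pep <- make_test_structure("extended_peptide", sequence = "GAV")
  sr <- shrake_rupley(pep)
  expect_error(residue_exposures(sr, "GA"), "does not match")
})

test_that("unknown residue codes get missing exposure with a warning", {
  per_res <- tibble::tibble(
    model = 1L, chain_id = "A", residue_index = c("1", "2"),
    residue_name = c("GLY", "MSE"), area = c(50, 50)
  )
  expect_warning(
    ex <- residue_exposures(fake_sasa_result(per_res), "GX"),
    "unknown code"
  )
  expect_true(is.na(ex$effective_exposure[2]))
  expect_false(is.na(ex$effective_exposure[1]))
})

test_that("ensemble averaging is the unweighted mean over models", {
  # identical models: average equals the single-model result
  same <- make_test_structure(
    "extended_peptide", sequence = "GAV", n_models = 1
  )
  trip <- dplyr::bind_rows(
    same, dplyr::mutate(same, model = 2L), dplyr::mutate(same, model = 3L)
  )
  trip <- phasesep:::new_pdb_atoms(trip)
  avg <- ensemble_average_exposures(trip)
  single <- residue_exposures(shrake_rupley(same), extract_sequence(same))
  expect_equal(avg$effective_exposure, single$effective_exposure,
               tolerance = 1e-12)

  # two models with different occlusion: per-residue SASA is their mean
  near <- make_test_structure("pair", distance = 2)
  far <- dplyr::mutate(make_test_structure("pair", distance = 100),
                       model = 2L)
  ens <- phasesep:::new_pdb_atoms(dplyr::bind_rows(near, far))
  a_near <- shrake_rupley(near)$per_residue$area
  a_far <- shrake_rupley(
    phasesep:::new_pdb_atoms(dplyr::mutate(far, model = 1L))
  )$per_residue$area
  avg2 <- suppressWarnings(ensemble_average_exposures(ens))
  expect_equal(avg2$sasa, (a_near + a_far) / 2, tolerance = 1e-12)
})

test_that("unknown elements fall back to the default radius with a warning", {
  odd <- dplyr::mutate(make_test_structure("single_atom"), element = "ZZ")
  odd <- phasesep:::new_pdb_atoms(odd)
  expect_warning(res <- shrake_rupley(odd), "fallback")
  expect_equal(res$per_atom$area, sphere_area(1.8), tolerance = 1e-12)
})
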