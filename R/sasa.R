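# Shrake-Rupley solvent-accessible surface area and effective exposure.

# Deterministic generalized-spiral (golden-angle) point set on the unit
# sphere; reproducible without a seed.
spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Structure-intrinsic orthonormal frame: principal axes of the atom cloud,
# signs fixed by the third moment along each axis (falling back to a
# largest-component rule when the cloud is symmetric), third axis by cross
# product so the frame is right-handed. Anchoring the test-point lattice to
# this frame makes areas exactly invariant under rigid motion of the input.
principal_frame <- function(xyz) {
  n <- nrow(xyz)
  if (n < 2) return(diag(3))
  centered <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(centered) / n, symmetric = TRUE)
  v <- ev$vectors
  fix_sign <- function(vec) {
    s <- sum((centered %*% vec)^3)
    if (abs(s) > 1e-9) {
      if (s < 0) vec <- -vec
    } else if (vec[which.max(abs(vec))] < 0) {
      vec <- -vec
    }
    vec
  }
  v1 <- fix_sign(v[, 1])
  v2 <- fix_sign(v[, 2])
  v3 <- c(
    v1[2] * v2[3] - v1[3] * v2[2],
    v1[3] * v2[1] - v1[1] * v2[3],
    v1[1] * v2[2] - v1[2] * v2[1]
  )
  cbind(v1, v2, v3)
}

atom_radii <- function(element, radii) {
  r <- unname(radii[element])
  if (anyNA(r)) {
    missing_el <- unique(element[is.na(r)])
    rlang::warn(paste0(
      "No van der Waals radius for element(s) ",
      paste(missing_el, collapse = ", "),
      "; using fallback ", .vdw_fallback, " A"
    ))
    r[is.na(r)] <- .vdw_fallback
  }
  r
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the van der Waals surface by testing a
#' deterministic spiral lattice of points on each atom's solvent-expanded
#' sphere (radius r_vdw + probe). A test point is exposed iff it lies
#' strictly outside every other atom's expanded sphere (a point exactly on a
#' neighbouring sphere counts as exposed, so exactly coincident equal
#' spheres each report full area). Per-atom area = exposed fraction x
#' 4 pi (r_vdw + probe)^2. The lattice is anchored to the structure's
#' principal axes, so areas are invariant under rotation and translation of
#' the input.
#'
#' Heteroatoms (`is_hetero`) are excluded from both area and occlusion
#' unless `include_hetero = TRUE`. Multi-model tables are processed per
#' model.
#'
#' @param atoms A `pdb_atoms` tibble (see [read_structure()]).
#' @param probe_radius Probe radius in Angstroms (default 1.4, water).
#' @param n_points Test points per atom (default 960; minimum 92).
#' @param radii Named vector of element van der Waals radii in Angstroms
#'   (default [vdw_radii()]); unlisted elements fall back to 1.8 A with a
#'   warning.
#' @param include_hetero Include heteroatoms in the calculation?
#' @param frame Orientation of the test-point lattice. `"principal"`
#'   (default) anchors it to the structure's principal axes, making areas
#'   exactly invariant under rigid motion of the input; `"fixed"` uses the
#'   classical globally oriented lattice, under which adding an atom can
#'   never increase another atom's area (exact occlusion monotonicity) but
#'   areas vary by a small discretization amount under rotation. The two
#'   modes agree to within the lattice resolution.
#' @return An object of class `sasa_result`: a list with tibbles `per_atom`
#'   (`model`, `serial`, `name`, `element`, `chain_id`, `residue_index`,
#'   `residue_name`, `area`) and `per_residue` (`model`, `chain_id`,
#'   `residue_index`, `residue_name`, `area`), plus the calculation
#'   parameters. Per-residue area is the exact sum of member-atom areas.
#' @examples
#' make_test_structure("single_atom") |> shrake_rupley()
#' @export
shrake_rupley <- function(atoms, probe_radius = 1.4, n_points = 960,
                          radii = vdw_radii(), include_hetero = FALSE,
                          frame = c("principal", "fixed")) {
  frame <- match.arg(frame)
  stopifnot(probe_radius > 0, n_points >= 92)
  work <- if (include_hetero) atoms else dplyr::filter(atoms, !.data$is_hetero)
  if (nrow(work) == 0) rlang::abort("No atoms eligible for SASA")

  pts0 <- spiral_points(n_points)
  per_model <- lapply(sort(unique(work$model)), function(m) {
    a <- dplyr::filter(work, .data$model == !!m)
    xyz <- cbind(a$x, a$y, a$z)
    rad <- atom_radii(a$element, radii) + probe_radius
    pts <- if (frame == "principal") {
      pts0 %*% t(principal_frame(xyz))
    } else {
      pts0
    }
    area <- vapply(seq_len(nrow(a)), function(i) {
      sph <- 4 * pi * rad[i]^2
      # neighbour prefilter: only spheres that can intersect atom i's
      d2 <- colSums((t(xyz) - xyz[i, ])^2)
      nb <- which(d2 < (rad[i] + rad)^2 & seq_along(d2) != i)
      if (length(nb) == 0) return(sph)
      p <- sweep(pts * rad[i], 2, xyz[i, ], "+")
      exposed <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
               (p[, 3] - xyz[j, 3])^2
        exposed <- exposed & (dj2 >= rad[j]^2 - 1e-9)
        if (!any(exposed)) break
      }
      sum(exposed) / n_points * sph
    }, numeric(1))
    tibble::tibble(
      model = a$model, serial = a$serial, name = a$name,
      element = a$element, chain_id = a$chain_id,
      residue_index = a$residue_index, residue_name = a$residue_name,
      area = area
    )
  })
  per_atom <- dplyr::bind_rows(per_model)
  per_residue <- per_atom |>
    dplyr::group_by(
      .data$model, .data$chain_id, .data$residue_index, .data$residue_name
    ) |>
    dplyr::summarise(area = sum(.data$area), .groups = "drop") |>
    dplyr::arrange(.data$model)
  # restore file residue order within each model
  ord <- residue_table(atoms |> dplyr::filter(!.data$is_hetero | include_hetero),
                       model = min(work$model))
  key <- paste(ord$chain_id, ord$residue_index)
  per_residue <- per_residue |>
    dplyr::arrange(
      .data$model, match(paste(.data$chain_id, .data$residue_index), key)
    )
  structure(
    list(
      per_atom = per_atom, per_residue = per_residue,
      probe_radius = probe_radius, n_points = n_points,
      radii = radii, source_id = attr(atoms, "source_id")
    ),
    class = "sasa_result"
  )
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(
    "<sasa_result> ", nrow(x$per_atom), " atoms, ",
    nrow(x$per_residue), " residues (probe ", x$probe_radius,
    " A, ", x$n_points, " points)\n",
    sep = ""
  )
  print(x$per_residue, ...)
  invisible(x)
}

#' Monte-Carlo SASA oracle
#'
#' Independent estimate of per-atom solvent-accessible area by uniform
#' random sampling on each solvent-expanded sphere. Used to cross-check
#' [shrake_rupley()]; slower and stochastic, with a reported standard error.
#'
#' @inheritParams shrake_rupley
#' @param n_samples Random samples per atom (>= 1e4).
#' @param seed Integer seed for the sampler.
#' @return Tibble with `model`, `serial`, `area` and `se` (standard error of
#'   the area estimate), one row per atom.
#' @export
monte_carlo_sasa <- function(atoms, probe_radius = 1.4, n_samples = 1e5,
                             seed = 1, radii = vdw_radii(),
                             include_hetero = FALSE) {
  stopifnot(probe_radius > 0, n_samples >= 1e4)
  work <- if (include_hetero) atoms else dplyr::filter(atoms, !.data$is_hetero)
  if (nrow(work) == 0) rlang::abort("No atoms eligible for SASA")
  withr::with_seed(seed, {
    res <- lapply(sort(unique(work$model)), function(m) {
      a <- dplyr::filter(work, .data$model == !!m)
      xyz <- cbind(a$x, a$y, a$z)
      rad <- atom_radii(a$element, radii) + probe_radius
      out <- vapply(seq_len(nrow(a)), function(i) {
        sph <- 4 * pi * rad[i]^2
        u <- matrix(stats::rnorm(3 * n_samples), ncol = 3)
        u <- u / sqrt(rowSums(u^2))
        p <- sweep(u * rad[i], 2, xyz[i, ], "+")
        exposed <- rep(TRUE, n_samples)
        for (j in seq_len(nrow(a))) {
          if (j == i) next
          dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
                 (p[, 3] - xyz[j, 3])^2
          exposed <- exposed & (dj2 >= rad[j]^2 - 1e-9)
        }
        frac <- mean(exposed)
        c(frac * sph, sph * sqrt(frac * (1 - frac) / n_samples))
      }, numeric(2))
      tibble::tibble(
        model = a$model, serial = a$serial,
        area = out[1, ], se = out[2, ]
      )
    })
    dplyr::bind_rows(res)
  })
}

#' Per-residue effective solvent exposure
#'
#' Divides each residue's SASA by that residue type's maximum allowed SASA
#' and clamps the ratio into \[0, 1\] (terminal residues can exceed their
#' tripeptide-context maximum). Residues whose one-letter code is `"X"` get
#' a missing exposure and are skipped by downstream feature sums, with a
#' warning.
#'
#' @param sasa A `sasa_result` from [shrake_rupley()] (single model).
#' @param sequence One-letter sequence string matching the residue count
#'   (see [extract_sequence()]).
#' @param table Maximum-SASA lookup, a tibble with columns `code` and
#'   `max_sasa` (default [max_sasa_table()]).
#' @return Tibble with `chain_id`, `residue_index`, `residue_name`, `code`,
#'   `sasa`, `max_sasa` and `effective_exposure`.
#' @examples
#' pdb <- make_test_structure("extended_peptide", sequence = "GAVR")
#' shrake_rupley(pdb) |> residue_exposures(extract_sequence(pdb))
#' @export
residue_exposures <- function(sasa, sequence, table = max_sasa_table()) {
  per_res <- sasa$per_residue
  if (dplyr::n_distinct(per_res$model) > 1) {
    rlang::abort(
      "Multi-model result: use ensemble_average_exposures() instead"
    )
  }
  codes <- strsplit(sequence, "")[[1]]
  if (length(codes) != nrow(per_res)) {
    rlang::abort(paste0(
      "Sequence length (", length(codes), ") does not match residue count (",
      nrow(per_res), ")"
    ))
  }
  exposure_table(per_res, codes, table)
}

exposure_table <- function(per_res, codes, table) {
  out <- per_res |>
    dplyr::select(-"model") |>
    dplyr::mutate(code = codes) |>
    dplyr::left_join(table, by = "code") |>
    dplyr::rename(sasa = "area") |>
    dplyr::mutate(
      effective_exposure = pmin(1, pmax(0, .data$sasa / .data$max_sasa))
    )
  if (anyNA(out$max_sasa)) {
    rlang::warn(paste0(
      sum(is.na(out$max_sasa)),
      " residue(s) with unknown code: exposure recorded as missing"
    ))
  }
  out
}

#' Ensemble-averaged effective exposure
#'
#' For a multi-model structure (e.g. a disordered-state ensemble), averages
#' each residue's SASA over models (unweighted mean) and then normalizes and
#' clamps as in [residue_exposures()].
#'
#' @param atoms A multi-model `pdb_atoms` tibble.
#' @inheritParams shrake_rupley
#' @inheritParams residue_exposures
#' @return Same shape as [residue_exposures()].
#' @export
ensemble_average_exposures <- function(atoms, probe_radius = 1.4,
                                       n_points = 960,
                                       table = max_sasa_table(),
                                       radii = vdw_radii(),
                                       include_hetero = FALSE) {
  v <- validate_ensemble(atoms)
  if (!v$valid) rlang::abort(c("Inconsistent ensemble", v$report))
  sasa <- shrake_rupley(
    atoms, probe_radius = probe_radius, n_points = n_points,
    radii = radii, include_hetero = include_hetero
  )
  ref <- residue_table(atoms, model = min(atoms$model))
  mean_res <- sasa$per_residue |>
    dplyr::group_by(
      .data$chain_id, .data$residue_index, .data$residue_name
    ) |>
    dplyr::summarise(area = mean(.data$area), .groups = "drop") |>
    dplyr::arrange(match(
      paste(.data$chain_id, .data$residue_index),
      paste(ref$chain_id, ref$residue_index)
    )) |>
    dplyr::mutate(model = 1L, .before = 1)
  codes <- unname(.aa_three_to_one[mean_res$residue_name])
  if (anyNA(codes)) {
    rlang::warn(paste0(
      "Unknown residue name(s) mapped to 'X': ",
      paste(unique(mean_res$residue_name[is.na(codes)]), collapse = ", ")
    ))
    codes[is.na(codes)] <- "X"
  }
  exposure_table(mean_res, codes, table)
}
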