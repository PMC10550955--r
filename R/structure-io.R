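# PDB parsing into tidy atom tables.
#
# A structure is a tibble with one row per (model, atom):
#   model, serial, name, element, x, y, z, residue_name, residue_index,
#   chain_id, is_hetero, occupancy
# residue_index is kept verbatim from the file (insertion code appended, no
# renumbering). The file path / identifier travels in attr(x, "source_id").

#' Read a (multi-model) PDB file into a tidy atom table
#'
#' Parses fixed-column ATOM/HETATM/MODEL/ENDMDL/TER records. Waters (residue
#' name HOH) and hydrogens are dropped; other heteroatoms are kept but
#' flagged `is_hetero` so downstream SASA can exclude them. Alternate
#' locations are resolved to the highest-occupancy conformer (ties: first
#' occurrence). Residue numbering is taken verbatim from the file, with any
#' insertion code appended to `residue_index`.
#'
#' @param path Path to a PDB file.
#' @param model `"first"` (default) returns model 1 only; `"all"` returns
#'   every model, validated to share an identical residue list.
#' @return A tibble of class `pdb_atoms` with columns `model`, `serial`,
#'   `name`, `element`, `x`, `y`, `z`, `residue_name`, `residue_index`,
#'   `chain_id`, `is_hetero`, `occupancy`. The file identifier is stored in
#'   `attr(, "source_id")`.
#' @examples
#' pdb <- make_test_structure("extended_peptide", sequence = "GAVR")
#' path <- tempfile(fileext = ".pdb")
#' write_pdb(pdb, path)
#' read_structure(path)
#' @export
read_structure <- function(path, model = c("first", "all")) {
  model <- match.arg(model)
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)

  rec <- substr(lines, 1, 6)
  is_atom <- startsWith(rec, "ATOM") | startsWith(rec, "HETATM")
  if (!any(startsWith(rec, "ATOM"))) {
    rlang::abort(paste0("No ATOM records found in '", path, "'"))
  }

  # assign model numbers by MODEL/ENDMDL blocks; files without MODEL = model 1
  model_id <- cumsum(startsWith(rec, "MODEL "))
  model_id[model_id == 0L] <- 1L

  keep <- which(is_atom)
  al <- lines[keep]
  atoms <- tibble::tibble(
    model = model_id[keep],
    record = trimws(substr(al, 1, 6)),
    serial = suppressWarnings(as.integer(substr(al, 7, 11))),
    name = trimws(substr(al, 13, 16)),
    altloc = substr(al, 17, 17),
    residue_name = trimws(substr(al, 18, 20)),
    chain_id = trimws(substr(al, 22, 22)),
    residue_index = paste0(
      trimws(substr(al, 23, 26)), trimws(substr(al, 27, 27))
    ),
    x = as.numeric(substr(al, 31, 38)),
    y = as.numeric(substr(al, 39, 46)),
    z = as.numeric(substr(al, 47, 54)),
    occupancy = suppressWarnings(as.numeric(substr(al, 55, 60))),
    element = trimws(substr(al, 77, 78))
  )
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$element <- ifelse(
    atoms$element == "", infer_element(atoms$name), toupper(atoms$element)
  )
  if (any(atoms$element == "")) {
    rlang::abort("Could not infer element for one or more atoms")
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    rlang::abort("Non-finite coordinates in PDB file")
  }

  atoms <- atoms |>
    dplyr::filter(.data$residue_name != "HOH") |>        # waters out
    dplyr::filter(!.data$element %in% c("H", "D")) |>    # hydrogens out
    dplyr::mutate(is_hetero = .data$record == "HETATM")

  # altloc: keep the highest-occupancy conformer of each atom, first on ties
  atoms <- atoms |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::group_by(
      .data$model, .data$chain_id, .data$residue_index,
      .data$residue_name, .data$name
    ) |>
    dplyr::slice_max(.data$occupancy, n = 1, with_ties = TRUE) |>
    dplyr::slice_min(.data$.ord, n = 1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord) |>
    dplyr::select(
      "model", "serial", "name", "element", "x", "y", "z",
      "residue_name", "residue_index", "chain_id", "is_hetero", "occupancy"
    )

  if (model == "first") {
    atoms <- dplyr::filter(atoms, .data$model == min(.data$model))
    atoms$model <- 1L
  } else {
    atoms$model <- match(atoms$model, sort(unique(atoms$model)))
    v <- validate_ensemble(structure(atoms, class = class(atoms)))
    if (!v$valid) {
      rlang::abort(c("Models have mismatched residue lists", v$report))
    }
  }
  new_pdb_atoms(atoms, source_id = path)
}

new_pdb_atoms <- function(x, source_id = NA_character_) {
  x <- tibble::as_tibble(x)
  class(x) <- c("pdb_atoms", class(x))
  attr(x, "source_id") <- source_id
  x
}

# element from atom name: strip digits/primes, first letter (col-13 names
# like "CA", "OXT"; two-letter hetero elements must carry columns 77-78)
infer_element <- function(name) {
  toupper(substr(gsub("[^A-Za-z]", "", name), 1, 1))
}

#' Number of models in an atom table
#' @param atoms A `pdb_atoms` tibble from [read_structure()].
#' @return Integer count of distinct models.
#' @export
n_models <- function(atoms) {
  length(unique(atoms$model))
}

#' Per-model residue table
#'
#' @param atoms A `pdb_atoms` tibble.
#' @param model Which model to list residues for (default 1).
#' @return Tibble with `chain_id`, `residue_index`, `residue_name` in file
#'   order.
#' @export
residue_table <- function(atoms, model = 1L) {
  d <- atoms |>
    dplyr::filter(.data$model == !!model) |>
    dplyr::distinct(.data$chain_id, .data$residue_index, .data$residue_name)
  tibble::tibble(
    chain_id = d$chain_id,
    residue_index = d$residue_index,
    residue_name = d$residue_name
  )
}

#' Extract a one-letter sequence from an atom table
#'
#' One character per residue, in file order (model 1 for ensembles).
#' Non-standard residue names map to `"X"` with a warning.
#'
#' @param atoms A `pdb_atoms` tibble.
#' @return A single character string.
#' @examples
#' make_test_structure("extended_peptide", sequence = "GVR") |>
#'   extract_sequence()
#' @export
extract_sequence <- function(atoms) {
  res <- residue_table(atoms, model = min(atoms$model))
  codes <- unname(.aa_three_to_one[res$residue_name])
  if (anyNA(codes)) {
    unknown <- unique(res$residue_name[is.na(codes)])
    rlang::warn(paste0(
      "Unknown residue name(s) mapped to 'X': ",
      paste(unknown, collapse = ", ")
    ))
    codes[is.na(codes)] <- "X"
  }
  paste(codes, collapse = "")
}

#' Check that all models of an ensemble share one residue list
#'
#' @param atoms A `pdb_atoms` tibble (possibly multi-model).
#' @return A list with elements `valid` (logical) and `report` (character;
#'   names the first mismatching model/residue when invalid).
#' @export
validate_ensemble <- function(atoms) {
  if (nrow(atoms) == 0) rlang::abort("Empty ensemble")
  models <- sort(unique(atoms$model))
  ref <- residue_table(atoms, models[1])
  for (m in models[-1]) {
    cur <- residue_table(atoms, m)
    if (nrow(cur) != nrow(ref) ||
        !all(cur$chain_id == ref$chain_id &
             cur$residue_index == ref$residue_index &
             cur$residue_name == ref$residue_name)) {
      n <- min(nrow(cur), nrow(ref))
      diff_at <- if (n > 0) {
        which(
          cur$chain_id[seq_len(n)] != ref$chain_id[seq_len(n)] |
          cur$residue_index[seq_len(n)] != ref$residue_index[seq_len(n)] |
          cur$residue_name[seq_len(n)] != ref$residue_name[seq_len(n)]
        )[1]
      } else NA_integer_
      where <- if (!is.na(diff_at)) {
        paste0(
          "residue ", ref$residue_name[diff_at], " ",
          ref$chain_id[diff_at], ref$residue_index[diff_at]
        )
      } else {
        paste0("residue count ", nrow(cur), " vs ", nrow(ref))
      }
      return(list(
        valid = FALSE,
        report = paste0("model ", m, " differs from model 1 at ", where)
      ))
    }
  }
  list(valid = TRUE, report = "all models share an identical residue list")
}

#' Write an atom table back to PDB fixed-column format
#'
#' Multi-model tables are wrapped in MODEL/ENDMDL blocks. Coordinates are
#' written at standard PDB precision (3 decimals).
#'
#' @param atoms A `pdb_atoms` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path) {
  fmt <- function(a) {
    sprintf(
      "%-6s%5d %-4s %-3s %1s%4s    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ifelse(a$is_hetero, "HETATM", "ATOM"),
      a$serial,
      ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
      a$residue_name, a$chain_id, a$residue_index,
      a$x, a$y, a$z, a$occupancy, 0, a$element
    )
  }
  models <- sort(unique(atoms$model))
  out <- character(0)
  for (m in models) {
    block <- fmt(dplyr::filter(atoms, .data$model == m))
    if (length(models) > 1) {
      block <- c(sprintf("MODEL     %4d", m), block, "ENDMDL")
    }
    out <- c(out, block)
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}
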