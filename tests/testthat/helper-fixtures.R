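# Shared in-code fixtures.

# random cluster of n carbon atoms (Gaussian cloud, sd in Angstroms)
random_carbon_cluster <- function(n, seed, sd = 2) {
  xyz <- withr::with_seed(seed, matrix(stats::rnorm(3 * n, sd = sd), ncol = 3))
  carbon_cluster(xyz)
}

carbon_cluster <- function(xyz) {
  phasesep:::new_pdb_atoms(tibble::tibble(
    model = 1L,
    serial = seq_len(nrow(xyz)),
    name = paste0("C", seq_len(nrow(xyz))),
    element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    residue_name = "UNK",
    residue_index = as.character(seq_len(nrow(xyz))),
    chain_id = "A",
    is_hetero = FALSE,
    occupancy = 1
  ), source_id = "test-cluster")
}

# hand-written PDB text: 1 glycine (4 heavy atoms + 2 hydrogens) + 1 water
glycine_water_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  H   GLY A   1      -0.500  -0.800   0.000  1.00  0.00           H",
    "ATOM      6  HA  GLY A   1       1.800  -0.500   0.800  1.00  0.00           H",
    "HETATM    7  O   HOH A   2       5.000   5.000   5.000  1.00  0.00           O",
    "END"
  ), path)
  path
}

# minimal sasa_result wrapper for exposure unit tests
fake_sasa_result <- function(per_residue) {
  structure(
    list(
      per_atom = NULL, per_residue = per_residue,
      probe_radius = 1.4, n_points = 960,
      radii = vdw_radii(), source_id = "fake"
    ),
    class = "sasa_result"
  )
}
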