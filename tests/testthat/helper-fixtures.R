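# Fixtures built in code: a tiny hand-written PDB/mmCIF pair, point-cloud
# helpers, and a cheap single-axis hinge map builder shared across tests.

write_mini_pdb <- function(path = tempfile(fileext = ".pdb")) {
  lines <- c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.000   2.500   3.500  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       3.200   2.100   2.900  1.00  0.00           C",
    "ATOM      4  N   GLY A   2       4.000   3.000   3.000  1.00  0.00           N",
    "ATOM      5  CA  GLY A   2       5.100   3.600   3.400  1.00  0.00           C",
    "ATOM      6  CA  SER B   7      -1.000   0.000   5.000  1.00  0.00           C",
    "TER",
    "END")
  writeLines(lines, path)
  path
}

write_mini_cif <- function(path = tempfile(fileext = ".cif")) {
  lines <- c(
    "data_mini",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 1.000 2.000 3.000 1.00 0.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 2.000 2.500 3.500 1.00 0.00 ? 1 ALA A CA 1",
    "ATOM 3 C CA . GLY A 1 2 ? 5.100 3.600 3.400 1.00 0.00 ? 2 GLY A CA 1",
    "#")
  writeLines(lines, path)
  path
}

point_cloud <- function(xyz) {
  xyz <- matrix(xyz, ncol = 3)
  structure(list(positions = xyz, weights = rep(1 / nrow(xyz), nrow(xyz)),
                 attachment = colMeans(xyz), linker_length = Inf,
                 linker_width = 4.5, dye_radius = 3.5, grid_pitch = 1),
            class = "dye_cloud")
}

# single-axis hinge map: cheap ensemble used by several property tests
one_axis_hinge <- function(range_deg, axis = c("out_of_plane", "in_plane"),
                           splay = 0, noise_sd = 0, seed = 1) {
  axis <- match.arg(axis)
  truth <- if (axis == "out_of_plane")
    hinge_truth(0, range_deg, splay = splay, noise_sd = noise_sd)
  else hinge_truth(range_deg, 0, splay = splay, noise_sd = noise_sd)
  toy <- make_toy_hinge_model(truth)
  pm <- make_pivot_map(toy, seed = seed)
  list(toy = toy, pm = pm, axis = axis)
}
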