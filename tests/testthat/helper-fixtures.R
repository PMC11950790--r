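# small text fixtures written on the fly

# 3-residue, one-chain fragment with 3-decimal coordinates (so a PDB write/
# read round trip is exact), as both PDB and mmCIF serializations
fixture_tripeptide <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  atoms <- data.frame(
    chain = "A", resno = 1:3, insert = "",
    resid = c("ALA", "LEU", "GLY"), elety = "CA", element = "C",
    x = c(1.000, 4.800, 8.600), y = c(0.250, -0.250, 0.125),
    z = c(0.500, 1.500, 2.500), o = 1, stringsAsFactors = FALSE)
  pdb <- file.path(dir, "tri.pdb")
  write_structure_pdb(structure_model(atoms, "tri"), pdb)
  cif <- file.path(dir, "tri.cif")
  hdr <- c("data_tri", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  rows <- sprintf("ATOM %d %s %s . %s A 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s A %s 1",
                  seq_len(nrow(atoms)), atoms$element, atoms$elety,
                  atoms$resid, atoms$resno, atoms$x, atoms$y, atoms$z,
                  atoms$resno, atoms$resid, atoms$elety)
  writeLines(c(hdr, rows, "#"), cif)
  list(pdb = pdb, cif = cif, atoms = atoms)
}

# PDB text with an A/B altloc pair of known occupancies on residue 1 CA
fixture_altloc <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "altloc.pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.30  0.00           C",
    "ATOM      3  CA BALA A   1       9.000   0.000   0.000  0.70  0.00           C",
    "ATOM      4  C   ALA A   1       2.000   1.000   0.000  1.00  0.00           C",
    "END"), path)
  path
}

rotation_z_test <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# drop a set of residue numbers from one chain of a model
drop_residues <- function(model, chain, resnos) {
  keep <- !(model$atoms$chain == chain & model$atoms$resno %in% resnos)
  model$atoms <- model$atoms[keep, , drop = FALSE]
  model
}
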