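# Tiny text fixtures built in code.

pdb_line <- function(serial, name, resid, chain, resno, x, y, z,
                     occ = 1, alt = " ", elem = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name), alt,
          resid, chain, resno, x, y, z, occ, 0, elem)
}

two_atom_pdb <- function(path) {
  writeLines(c(
    pdb_line(1, "N", "ALA", "A", 1, 11.104, 6.134, -6.504),
    pdb_line(2, "CA", "ALA", "A", 1, 11.639, 6.071, -5.147, elem = "C"),
    "END"), path)
  path
}

two_atom_cif <- function(path) {
  writeLines(c(
    "data_fixture",
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
    "ATOM 1 N N . ALA A 1 1 ? 11.104 6.134 -6.504 1.00 0.00 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 11.639 6.071 -5.147 1.00 0.00 ? 1 ALA A CA 1"
  ), path)
  path
}

altloc_pdb <- function(path) {
  # CA has two conformers: A at occupancy 0.4, B at 0.6 -> B retained;
  # CB has a tie at 0.5/0.5 -> altloc A retained
  writeLines(c(
    pdb_line(1, "N", "SER", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "SER", "A", 1, 1, 0, 0, occ = 0.4, alt = "A", elem = "C"),
    pdb_line(3, "CA", "SER", "A", 1, 2, 0, 0, occ = 0.6, alt = "B", elem = "C"),
    pdb_line(4, "CB", "SER", "A", 1, 3, 0, 0, occ = 0.5, alt = "A", elem = "C"),
    pdb_line(5, "CB", "SER", "A", 1, 4, 0, 0, occ = 0.5, alt = "B", elem = "C"),
    pdb_line(6, "OG", "SER", "A", 1, 5, 0, 0),
    "END"), path)
  path
}

multi_model_pdb <- function(path, n_models = 3, drop_atom_in = NULL) {
  lines <- character(0)
  for (m in seq_len(n_models)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    lines <- c(lines, pdb_line(1, "N", "ALA", "A", 1, m, 0, 0))
    if (is.null(drop_atom_in) || m != drop_atom_in)
      lines <- c(lines, pdb_line(2, "CA", "ALA", "A", 1, m + 1, 0, 0,
                                 elem = "C"))
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# one-atom-per-residue structure at given coordinates (for distance tests)
point_structure <- function(coords, chain = "A", resid = "ALA",
                            elety = "CA") {
  n <- nrow(coords)
  new_structure(data.frame(
    chain = chain, resno = seq_len(n), insert = "", resid = resid,
    elety = elety, elesy = substr(elety, 1, 1),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    o = 1, is_h = FALSE, stringsAsFactors = FALSE))
}

# schematic residue placement (package-internal generator primitive)
place_residue_fixture <- function(chain, resno, resid, ca, sc_dir) {
  gpcrprofiler:::place_residue(chain, resno, resid, ca, sc_dir)
}
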