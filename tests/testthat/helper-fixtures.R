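# fixtures built in code: ideal helices, tiny PDB text, small ensemble specs

make_helix <- function(n = 20, phi = -57, psi = -47, aa = "A", id = "helix") {
  build_chain(strrep(aa, n), rep(phi, n), rep(psi, n), id = id)
}

# a small 3-helix bundle spec that keeps ensemble tests fast
small_spec <- function(seed = 1L, regime = "distinct", n_proper = 8L,
                       n_mirror = 8L, ...) {
  segments <- paste0(strrep("H", 14), strrep("L", 4), strrep("H", 14),
                     strrep("L", 4), strrep("H", 14))
  sequence <- paste0(strrep("A", 14), "GSGN", strrep("L", 14), "GSGN",
                     strrep("E", 14))
  ensemble_spec(sequence, segments, regime = regime, n_proper = n_proper,
                n_mirror = n_mirror, seed = seed, ...)
}

# hand-written 3-residue PDB fixture (fixed columns)
tiny_pdb_lines <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.421   0.000  1.00  0.00           C",
    "ATOM      4  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      5  CA  GLY A   2       4.042   2.796   0.150  1.00  0.00           C",
    "ATOM      6  C   GLY A   2       5.479   2.705   0.651  1.00  0.00           C",
    "ATOM      7  N   SER A   3       6.044   3.885   0.845  1.00  0.00           N",
    "ATOM      8  CA  SER A   3       7.426   4.012   1.285  1.00  0.00           C",
    "ATOM      9  C   SER A   3       8.382   3.174   0.445  1.00  0.00           C")
}

write_tiny_pdb <- function(lines = tiny_pdb_lines()) {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "TER", "END"), path)
  path
}
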