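# Hand-written PDB fixture builders (fixed-width ATOM records).

pdb_atom <- function(serial, name, resn, chain, resi, x, y, z,
                     alt = " ", icode = " ", occ = 1.00, rec = "ATOM",
                     elem = substr(trimws(name), 1, 1)) {
  name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf(
    "%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, serial, name_fmt, alt, resn, chain, resi, icode, x, y, z, occ, 0, elem
  )
}

write_pdb_lines <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# three-residue single-chain fragment, one CA each, with a CB on residue 2
pdb_three_residues <- function() {
  write_pdb_lines(c(
    pdb_atom(1, "N", "ALA", "A", 1, 0.0, 0.0, 0.0, elem = "N"),
    pdb_atom(2, "CA", "ALA", "A", 1, 1.5, 0.0, 0.0),
    pdb_atom(3, "CA", "GLY", "A", 2, 5.3, 0.0, 0.0),
    pdb_atom(4, "CA", "SER", "A", 3, 9.1, 0.5, 0.2),
    pdb_atom(5, "CB", "SER", "A", 3, 9.9, 1.8, 0.2)
  ))
}
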