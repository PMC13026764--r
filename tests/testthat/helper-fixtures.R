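# Programmatic fixtures: small PDB texts written on the fly, and XTC/DCD
# trajectory files produced by the system Python's MDAnalysis (used purely
# as an independent fixture writer; the package never calls Python).

pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          occ = 1.0, b = 0.0, alt = " ", icode = " ",
                          element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name), alt, resn,
          chain, resno, icode, x, y, z, occ, b, element)
}

# 5-residue CA-only peptide, n_models frames, with a per-model z offset
write_toy_multimodel_pdb <- function(path, n_models = 3, n_res = 5,
                                     drop_atom_in_model = NULL) {
  lines <- character(0)
  for (m in seq_len(n_models)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    for (i in seq_len(n_res)) {
      if (!is.null(drop_atom_in_model) && m == drop_atom_in_model && i == n_res) next
      lines <- c(lines, pdb_atom_line(i, "CA", "ALA", "A", i,
                                      3.8 * i, 0, 0.5 * (m - 1), element = "C"))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

traj_fixture_dir <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    dir <- file.path(tempdir(), "ensdyn-traj-fixtures")
    dir.create(dir, showWarnings = FALSE)
    script <- file.path(dir, "make_traj.py")
    writeLines(c(
      "import sys, numpy as np",
      "import MDAnalysis as mda",
      "out = sys.argv[1]",
      "def build(n_res, atoms_per_res, names, elements):",
      "    n_atoms = n_res * atoms_per_res",
      "    u = mda.Universe.empty(n_atoms, n_residues=n_res,",
      "        atom_resindex=np.repeat(np.arange(n_res), atoms_per_res),",
      "        residue_segindex=np.zeros(n_res, dtype=int), trajectory=True)",
      "    u.add_TopologyAttr('names', names * n_res)",
      "    u.add_TopologyAttr('elements', elements * n_res)",
      "    u.add_TopologyAttr('resnames', ['ALA'] * n_res)",
      "    u.add_TopologyAttr('resids', np.arange(1, n_res + 1))",
      "    u.add_TopologyAttr('chainIDs', ['A'] * n_atoms)",
      "    u.add_TopologyAttr('occupancies', np.ones(n_atoms))",
      "    u.add_TopologyAttr('tempfactors', np.zeros(n_atoms))",
      "    return u",
      "rng = np.random.default_rng(11)",
      "# medium system: exercises the compressed XTC path",
      "u = build(15, 5, ['N','CA','C','O','CB'], ['N','C','C','O','C'])",
      "base = rng.uniform(-20, 20, (u.atoms.n_atoms, 3))",
      "frames = base[None] + rng.normal(0, 0.5, (20, u.atoms.n_atoms, 3))",
      "u.atoms.positions = frames[0]",
      "u.atoms.write(out + '/med_top.pdb')",
      "with mda.coordinates.XTC.XTCWriter(out + '/med.xtc', u.atoms.n_atoms,",
      "        precision=5) as w:",
      "    for f in frames:",
      "        u.atoms.positions = f",
      "        w.write(u.atoms)",
      "with mda.coordinates.DCD.DCDWriter(out + '/med.dcd', u.atoms.n_atoms) as w:",
      "    for f in frames:",
      "        u.atoms.positions = f",
      "        w.write(u.atoms)",
      "np.savetxt(out + '/med_last_frame.txt', frames[-1])",
      "# tiny system (<= 9 atoms): exercises the uncompressed XTC path",
      "u2 = build(3, 1, ['CA'], ['C'])",
      "f2 = rng.uniform(-5, 5, (4, 3, 3))",
      "u2.atoms.positions = f2[0]",
      "u2.atoms.write(out + '/tiny_top.pdb')",
      "with mda.coordinates.XTC.XTCWriter(out + '/tiny.xtc', 3) as w:",
      "    for f in f2:",
      "        u2.atoms.positions = f",
      "        w.write(u2.atoms)",
      "np.savetxt(out + '/tiny_frames.txt', f2.reshape(4, 9))",
      "print('ok')"
    ), script)
    res <- suppressWarnings(system2("python", c(script, dir),
                                    stdout = TRUE, stderr = TRUE))
    if (!any(grepl("^ok$", res))) {
      stop("trajectory fixture generation failed:\n", paste(res, collapse = "\n"))
    }
    cache <<- dir
    dir
  }
})
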