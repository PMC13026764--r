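#' Read a (multi-model) PDB file as a conformational ensemble
#'
#' Each `MODEL` becomes one frame; a single-structure file yields a one-frame
#' ensemble. The topology is taken from the first model and every model is
#' validated against it. Alternate locations are resolved by keeping the
#' highest-occupancy altloc of each atom; insertion-coded residues are
#' dropped with a warning so that residue indexing stays unambiguous.
#'
#' @param path path to a PDB file
#' @return a [conf_ensemble()]
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  atom <- pdb$atom
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  keep <- resolve_altloc_keep(atom)
  if (any(nzchar(trimws(atom$insert)) & !is.na(atom$insert))) {
    ins <- nzchar(trimws(atom$insert)) & !is.na(atom$insert)
    warning("dropping ", sum(ins & keep), " atom(s) in insertion-coded residues")
    keep <- keep & !ins
  }
  atom <- atom[keep, , drop = FALSE]
  xyz <- xyz[, bio3d::atom2xyz(which(keep)), drop = FALSE]
  atom$chain[is.na(atom$chain)] <- "A"
  conf_ensemble(
    data.frame(elety = atom$elety, resid = atom$resid, chain = atom$chain,
               resno = atom$resno, elesy = atom$elesy,
               stringsAsFactors = FALSE),
    xyz
  )
}

# quick structural scan: per-model atom counts must agree and coordinate
# fields must parse; gives errors that name the offending model/line, which
# full parsers report less helpfully
validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  bad <- which(is_atom & nchar(lines) >= 54 &
                 (is.na(suppressWarnings(as.numeric(substr(lines, 31, 38)))) |
                  is.na(suppressWarnings(as.numeric(substr(lines, 39, 46)))) |
                  is.na(suppressWarnings(as.numeric(substr(lines, 47, 54))))))
  short <- which(is_atom & nchar(lines) < 54)
  if (length(short) > 0) {
    stop("unparseable ATOM record (too short) at line ", short[1])
  }
  if (length(bad) > 0) {
    stop("unparseable coordinates in ATOM record at line ", bad[1])
  }
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) > 1) {
    model_of <- findInterval(which(is_atom), model_starts)
    counts <- tabulate(model_of, nbins = length(model_starts))
    if (length(unique(counts[counts > 0])) > 1) {
      off <- which(counts != counts[1] & counts > 0)[1]
      stop("model ", off, " has ", counts[off],
           " atoms but model 1 has ", counts[1])
    }
  }
  invisible(TRUE)
}

resolve_altloc_keep <- function(atom) {
  alt <- trimws(ifelse(is.na(atom$alt), "", atom$alt))
  keep <- rep(TRUE, nrow(atom))
  has_alt <- which(nzchar(alt))
  if (length(has_alt) == 0) return(keep)
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety)
  occ <- ifelse(is.na(atom$o), 1, atom$o)
  for (k in unique(key[has_alt])) {
    idx <- which(key == k)
    if (length(idx) > 1) {
      best <- idx[order(-occ[idx], alt[idx])][1]
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  keep
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ens a [conf_ensemble()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_multimodel_pdb <- function(ens, path) {
  stopifnot(inherits(ens, "conf_ensemble"))
  bio3d::write.pdb(
    file = path,
    xyz = ens$xyz,
    type = rep("ATOM", ens$n_atoms),
    resno = ens$atom$resno,
    resid = ens$atom$resid,
    eleno = seq_len(ens$n_atoms),
    elety = ens$atom$elety,
    chain = ens$atom$chain,
    elesy = ens$atom$elesy
  )
  invisible(path)
}

#' Read a trajectory (DCD or XTC) with a PDB topology
#'
#' Frames are returned in file order; XTC coordinates (stored in nm) are
#' converted to Angstrom at read time. The trajectory's atom count must match
#' the topology's.
#'
#' @param topology_path path to a PDB file defining the topology
#' @param trajectory_path path to a `.dcd` or `.xtc` trajectory
#' @return a [conf_ensemble()]
#' @export
read_trajectory <- function(topology_path, trajectory_path) {
  top <- read_multimodel_pdb(topology_path)
  if (top$n_frames > 1) top <- conf_ensemble(top$atom, top$xyz[1, , drop = FALSE])
  ext <- tolower(tools::file_ext(trajectory_path))
  xyz <- switch(ext,
    dcd = unclass(bio3d::read.dcd(trajectory_path, verbose = FALSE)),
    xtc = read_xtc_coords(trajectory_path) * 10,
    stop("unsupported trajectory format: .", ext, " (expected .dcd or .xtc)")
  )
  if (ncol(xyz) != 3L * top$n_atoms) {
    stop("trajectory has ", ncol(xyz) / 3, " atoms but topology has ",
         top$n_atoms)
  }
  conf_ensemble(top$atom, xyz)
}
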