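#' Construct a conformational ensemble
#'
#' A `conf_ensemble` couples a molecular topology (an atom table) with the
#' per-frame coordinates of every atom. It is the substrate of all metrics in
#' the package: flexibility profiles, cross-correlation matrices, contact
#' maps, landscape projections and pocket analyses all start from one.
#'
#' The coordinate layout follows the bio3d convention: `xyz` is an
#' `n_frames x (3 * n_atoms)` matrix where columns `(3i-2):(3i)` hold the
#' x, y, z position of atom `i` (in Angstrom).
#'
#' @param atom data.frame describing the topology, with columns
#'   `elety` (atom name), `resid` (3-letter residue name), `chain`
#'   (chain identifier), `resno` (residue number as in the source PDB) and
#'   `elesy` (element symbol). Atom order is fixed and shared by all frames.
#' @param xyz numeric matrix of coordinates, one row per frame,
#'   `3 * nrow(atom)` columns, in Angstrom.
#' @return An object of class `conf_ensemble`: a list with elements `atom`,
#'   `xyz`, `n_frames` and `n_atoms`.
#' @examples
#' bb <- make_backbone(5)
#' ens <- conf_ensemble(bb$atom, rbind(bb$xyz, bb$xyz))
#' ens$n_frames
#' @export
conf_ensemble <- function(atom, xyz) {
  stopifnot(is.data.frame(atom))
  required <- c("elety", "resid", "chain", "resno")
  missing_cols <- setdiff(required, names(atom))
  if (length(missing_cols) > 0) {
    stop("topology is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(atom$elesy)) {
    atom$elesy <- guess_element(atom$elety)
  }
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(atom)) {
    stop("xyz has ", ncol(xyz), " columns but the topology has ", nrow(atom),
         " atoms (expected ", 3L * nrow(atom), " columns)")
  }
  if (nrow(xyz) < 1L) stop("an ensemble needs at least one frame")
  if (!all(is.finite(xyz))) stop("all coordinates must be finite")
  res_key <- residue_keys(atom)
  structure(
    list(atom = atom, xyz = xyz,
         n_frames = nrow(xyz), n_atoms = nrow(atom),
         residue_key = res_key),
    class = "conf_ensemble"
  )
}

# one key per atom identifying its residue; order of first appearance defines
# the (1-based) residue position used throughout
residue_keys <- function(atom) {
  paste(atom$chain, atom$resno, atom$resid, sep = "|")
}

#' Residue table of an ensemble topology
#'
#' @param ens a `conf_ensemble`
#' @return data.frame with one row per residue: `pos` (1-based position),
#'   `resno` (original PDB number), `resid`, `chain` and `label`
#'   (e.g. `"GLY12"`).
#' @export
residues <- function(ens) {
  stopifnot(inherits(ens, "conf_ensemble"))
  keys <- ens$residue_key
  first <- !duplicated(keys)
  data.frame(
    pos = seq_len(sum(first)),
    resno = ens$atom$resno[first],
    resid = ens$atom$resid[first],
    chain = ens$atom$chain[first],
    label = paste0(ens$atom$resid[first], ens$atom$resno[first]),
    stringsAsFactors = FALSE
  )
}

#' @export
print.conf_ensemble <- function(x, ...) {
  res <- residues(x)
  cat("Conformational ensemble:", x$n_frames, "frame(s),",
      x$n_atoms, "atoms,", nrow(res), "residues\n")
  cat("  chains:", paste(unique(res$chain), collapse = " "), "\n")
  cat("  atom types:", paste(utils::head(unique(x$atom$elety), 8), collapse = " "),
      if (length(unique(x$atom$elety)) > 8) "..." else "", "\n")
  invisible(x)
}

#' Extract one frame as an n_atoms x 3 coordinate matrix
#'
#' @param ens a `conf_ensemble`
#' @param i frame index
#' @return numeric matrix `n_atoms x 3` (Angstrom)
#' @export
frame_coords <- function(ens, i = 1L) {
  stopifnot(inherits(ens, "conf_ensemble"))
  if (i < 1L || i > ens$n_frames) stop("frame index ", i, " out of range")
  matrix(ens$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' Concatenate ensembles sharing a topology
#'
#' Used to pool independent trajectories of the same system into one ensemble
#' (e.g. pooling three replicate trajectories into a single combined
#' ensemble before computing metrics).
#'
#' @param ... `conf_ensemble` objects, or a single list of them.
#' @return A `conf_ensemble` whose frames are the inputs' frames in order.
#' @export
concat_ensembles <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !inherits(parts[[1]], "conf_ensemble")) {
    parts <- parts[[1]]
  }
  if (length(parts) == 0L) stop("no ensembles supplied")
  lapply(parts, function(p) stopifnot(inherits(p, "conf_ensemble")))
  if (length(parts) == 1L) return(parts[[1]])
  ref <- parts[[1]]$atom
  for (k in seq_along(parts)[-1]) {
    a <- parts[[k]]$atom
    if (nrow(a) != nrow(ref)) {
      stop("ensemble ", k, " has ", nrow(a), " atoms; expected ", nrow(ref))
    }
    same <- a$elety == ref$elety & a$resid == ref$resid &
      a$resno == ref$resno & a$chain == ref$chain
    if (!all(same)) {
      i <- which(!same)[1]
      stop("ensemble ", k, " differs from the first at atom ", i, " (",
           a$elety[i], " ", a$resid[i], a$resno[i], " vs ",
           ref$elety[i], " ", ref$resid[i], ref$resno[i], ")")
    }
  }
  conf_ensemble(ref, do.call(rbind, lapply(parts, function(p) p$xyz)))
}

guess_element <- function(elety) {
  nm <- gsub("[^A-Za-z].*$", "", trimws(elety))
  two <- toupper(substr(nm, 1, 2))
  out <- toupper(substr(nm, 1, 1))
  out[two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE")] <-
    two[two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE")]
  out
}
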