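#' Resolve an atom selection on a topology
#'
#' Three named selections cover the coarse-grained backbone + C-beta
#' representation used throughout: `calpha` (exactly one CA per residue),
#' `backbone_cb` (N, CA, C, O and, where present, CB -- glycine contributes
#' only four atoms), and `heavy` (all non-hydrogen atoms). A `custom`
#' selection takes explicit atom indices.
#'
#' @param ens a [conf_ensemble()] (or anything with `$atom` and
#'   `$residue_key` fields)
#' @param name one of `"calpha"`, `"backbone_cb"`, `"heavy"`, `"custom"`
#' @param indices explicit atom indices, required when `name = "custom"`
#' @return an `atom_selection`: list with `name`, `indices` (strictly
#'   increasing atom indices) and `groups` (per-residue list of selected
#'   atom indices, named by residue label).
#' @export
resolve_selection <- function(ens, name = c("calpha", "backbone_cb", "heavy", "custom"),
                              indices = NULL) {
  if (!name[1] %in% c("calpha", "backbone_cb", "heavy", "custom")) {
    stop("unrecognized selection: '", name[1], "'")
  }
  name <- match.arg(name)
  atom <- ens$atom
  elety <- trimws(atom$elety)
  elesy <- trimws(ens$atom$elesy)
  idx <- switch(name,
    calpha = which(elety == "CA"),
    backbone_cb = which(elety %in% c("N", "CA", "C", "O", "CB")),
    heavy = which(toupper(elesy) != "H"),
    custom = {
      if (is.null(indices)) stop("custom selection requires explicit indices")
      indices <- as.integer(indices)
      if (any(indices < 1 | indices > nrow(atom))) {
        stop("custom selection index out of range (1..", nrow(atom), ")")
      }
      sort(unique(indices))
    }
  )
  keys <- ens$residue_key
  res <- residues(ens)
  if (name == "calpha") {
    per_res <- table(factor(keys[idx], levels = unique(keys)))
    if (any(per_res == 0)) {
      stop("residue(s) lacking a CA atom: ",
           paste(res$label[per_res == 0], collapse = ", "))
    }
    if (any(per_res > 1)) {
      stop("residue(s) with multiple CA atoms: ",
           paste(res$label[per_res > 1], collapse = ", "))
    }
  }
  groups <- split(idx, factor(keys[idx], levels = unique(keys)))
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  names(groups) <- res$label[match(names(groups), unique(keys))]
  structure(list(name = name, indices = idx, groups = groups),
            class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("Atom selection '", x$name, "': ", length(x$indices), " atoms over ",
      length(x$groups), " residues\n", sep = "")
  invisible(x)
}

# xyz-column indices (3i-2, 3i-1, 3i) for the atoms of a selection
sel_xyz_cols <- function(selection) {
  idx <- selection$indices
  as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
}

# coordinates of the selected atoms in one frame, as n_sel x 3
sel_coords <- function(ens, selection, frame = 1L) {
  matrix(ens$xyz[frame, sel_xyz_cols(selection)], ncol = 3, byrow = TRUE)
}
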