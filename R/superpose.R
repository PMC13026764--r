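#' Optimal rigid superposition of two point sets (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD
#' between the transformed mobile points (`x %*% t(R) + t`, row vectors) and
#' the reference points. Reflections are excluded: the determinant of the
#' returned rotation is always +1, obtained by flipping the sign of the
#' smallest singular vector pair when the naive solution is improper.
#'
#' @param mobile numeric `n x 3` matrix of points to transform (Angstrom)
#' @param reference numeric `n x 3` matrix of target points
#' @return a `superposition`: list with `rotation` (3x3, det +1),
#'   `translation` (length-3, Angstrom) and `fit_rmsd` (Angstrom).
#' @examples
#' pts <- matrix(rnorm(15), ncol = 3)
#' s <- kabsch_superpose(pts, pts)
#' s$fit_rmsd  # 0
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (ncol(mobile) != 3 || ncol(reference) != 3) {
    stop("coordinate matrices must have 3 columns")
  }
  if (nrow(mobile) != nrow(reference)) {
    stop("point counts differ: ", nrow(mobile), " vs ", nrow(reference))
  }
  n <- nrow(mobile)
  if (n < 3) stop("at least 3 points are required for superposition")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  a <- sweep(mobile, 2, cm)
  b <- sweep(reference, 2, cr)
  h <- crossprod(a, b)  # 3x3 covariance of centered point sets
  sv <- svd(h)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-30)) {
    stop("degenerate (rank-deficient) point configuration: ",
         "points are collinear or coincident")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cr - as.vector(rot %*% cm)
  fitted <- a %*% t(rot)  # centered fit; translation aligns centroids
  rmsd <- sqrt(sum((fitted - b)^2) / n)
  structure(list(rotation = rot, translation = as.vector(trans),
                 fit_rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("Rigid superposition: fit RMSD", format(x$fit_rmsd, digits = 6), "A\n")
  invisible(x)
}

#' Apply a superposition to a coordinate matrix
#'
#' @param sup a `superposition` from [kabsch_superpose()]
#' @param coords numeric `n x 3` matrix
#' @return transformed `n x 3` matrix
#' @export
apply_superposition <- function(sup, coords) {
  stopifnot(inherits(sup, "superposition"))
  sweep(as.matrix(coords) %*% t(sup$rotation), 2, sup$translation, "+")
}

#' Root-mean-square deviation between two coordinate sets (no fitting)
#'
#' @param a,b numeric `n x 3` matrices
#' @return RMSD in Angstrom
#' @export
coord_rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b), ncol(a) == 3, ncol(b) == 3)
  sqrt(sum((a - b)^2) / nrow(a))
}

#' Superpose every frame of an ensemble onto a reference
#'
#' Each frame gets its own rigid superposition, computed on the fit
#' selection's atoms and applied to all atoms of the frame. This removes
#' translational and rotational degrees of freedom before flexibility,
#' correlation or landscape analysis.
#'
#' @param ens a [conf_ensemble()]
#' @param reference either a full-topology `n_atoms x 3` coordinate matrix, a
#'   matrix covering exactly the fit-selection atoms, a one-frame
#'   [conf_ensemble()], or `NULL` to use the ensemble's first frame.
#' @param fit_selection an `atom_selection` (default: C-alpha atoms)
#' @return a new [conf_ensemble()] with transformed coordinates
#' @export
align_ensemble <- function(ens, reference = NULL, fit_selection = NULL) {
  stopifnot(inherits(ens, "conf_ensemble"))
  if (is.null(fit_selection)) fit_selection <- resolve_selection(ens, "calpha")
  if (is.null(reference)) reference <- frame_coords(ens, 1L)
  if (inherits(reference, "conf_ensemble")) reference <- frame_coords(reference, 1L)
  reference <- as.matrix(reference)
  n_sel <- length(fit_selection$indices)
  ref_sel <- if (nrow(reference) == ens$n_atoms) {
    reference[fit_selection$indices, , drop = FALSE]
  } else if (nrow(reference) == n_sel) {
    reference
  } else {
    stop("reference has ", nrow(reference), " atoms; expected ", ens$n_atoms,
         " (full topology) or ", n_sel, " (fit selection)")
  }
  cols <- sel_xyz_cols(fit_selection)
  xyz <- ens$xyz
  for (t in seq_len(ens$n_frames)) {
    mob <- matrix(xyz[t, cols], ncol = 3, byrow = TRUE)
    sup <- kabsch_superpose(mob, ref_sel)
    all_crd <- matrix(xyz[t, ], ncol = 3, byrow = TRUE)
    xyz[t, ] <- as.vector(t(apply_superposition(sup, all_crd)))
  }
  out <- conf_ensemble(ens$atom, xyz)
  out
}

#' Per-frame RMSD of an ensemble to a reference structure
#'
#' Each frame is first rigidly superposed onto the reference on the given
#' selection, then the RMSD over the selection's atoms is computed. The
#' result is therefore invariant to rigid motions of the frames.
#'
#' @param ens a [conf_ensemble()]
#' @param ref reference coordinates: full-topology or selection-sized
#'   `n x 3` matrix
#' @param selection an `atom_selection` (default: C-alpha)
#' @return numeric vector of per-frame RMSD values (Angstrom)
#' @export
rmsd_to_reference <- function(ens, ref, selection = NULL) {
  stopifnot(inherits(ens, "conf_ensemble"))
  if (is.null(selection)) selection <- resolve_selection(ens, "calpha")
  if (inherits(ref, "conf_ensemble")) ref <- frame_coords(ref, 1L)
  ref <- as.matrix(ref)
  n_sel <- length(selection$indices)
  ref_sel <- if (nrow(ref) == ens$n_atoms) {
    ref[selection$indices, , drop = FALSE]
  } else if (nrow(ref) == n_sel) {
    ref
  } else {
    stop("reference has ", nrow(ref), " rows; expected ", ens$n_atoms,
         " or ", n_sel)
  }
  cols <- sel_xyz_cols(selection)
  vapply(seq_len(ens$n_frames), function(t) {
    mob <- matrix(ens$xyz[t, cols], ncol = 3, byrow = TRUE)
    kabsch_superpose(mob, ref_sel)$fit_rmsd
  }, numeric(1))
}
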