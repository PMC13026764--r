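#' Center an aligned ensemble on its mean structure
#'
#' Computes, for the selected atoms, the per-atom mean position over frames
#' and the per-frame displacement vectors about it. The ensemble must already
#' be superposed onto a common reference ([align_ensemble()]); otherwise
#' rigid-body motion contaminates the displacements.
#'
#' @param ens an aligned [conf_ensemble()]
#' @param selection an `atom_selection` (default: C-alpha)
#' @return a `centered_ensemble`: list with `mean` (`n_sel x 3` Angstrom),
#'   `disp` (`n_frames x (3 n_sel)` displacement matrix satisfying
#'   `x = mean + disp` exactly), `labels` (residue labels of the selection)
#'   and `n_frames`.
#' @export
center_ensemble <- function(ens, selection = NULL) {
  stopifnot(inherits(ens, "conf_ensemble"))
  if (is.null(selection)) selection <- resolve_selection(ens, "calpha")
  if (length(selection$indices) == 0) stop("empty atom selection")
  cols <- sel_xyz_cols(selection)
  x <- ens$xyz[, cols, drop = FALSE]
  mu <- colMeans(x)
  disp <- sweep(x, 2, mu)
  structure(
    list(mean = matrix(mu, ncol = 3, byrow = TRUE),
         mean_flat = mu,
         disp = disp,
         labels = names(selection$groups),
         n_frames = nrow(x)),
    class = "centered_ensemble"
  )
}

#' @export
print.centered_ensemble <- function(x, ...) {
  cat("Centered ensemble:", x$n_frames, "frames,",
      length(x$labels), "selected residues/atoms\n")
  invisible(x)
}

#' Per-residue root-mean-square fluctuation (RMSF)
#'
#' `RMSF_i = sqrt(mean_t |dx_i(t)|^2)`, the root-mean-square norm of the
#' displacement of atom i about its ensemble-average position. With a
#' C-alpha selection this is the standard per-residue flexibility profile.
#'
#' @param centered a `centered_ensemble` from [center_ensemble()]
#' @return a `flexibility_profile`: named numeric vector of RMSF values
#'   (Angstrom), one per selected atom, named by residue label.
#' @export
compute_rmsf <- function(centered) {
  stopifnot(inherits(centered, "centered_ensemble"))
  if (centered$n_frames < 2) {
    stop("RMSF is undefined for a single frame (need n_frames >= 2)")
  }
  d <- centered$disp
  n_atoms <- ncol(d) / 3
  msd <- matrix(colMeans(d^2), ncol = 3, byrow = TRUE)  # per atom, per axis
  vals <- sqrt(rowSums(msd))
  names(vals) <- if (length(centered$labels) == n_atoms) centered$labels else NULL
  structure(vals, class = c("flexibility_profile", "numeric"))
}

#' Pearson correlation between two flexibility profiles
#'
#' The agreement statistic for RMSF profiles from two ensembles of the same
#' protein: correlation of the per-residue values, insensitive to a global
#' scale difference between the ensembles (e.g. different sampling
#' timescales).
#'
#' @param a,b numeric vectors (e.g. `flexibility_profile`s) of equal length
#' @return Pearson correlation coefficient in `[-1, 1]`
#' @export
profile_pcc <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("profiles differ in length: ", length(a), " vs ", length(b))
  }
  if (length(a) < 3) stop("need at least 3 values to correlate")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined: a profile has zero variance")
  }
  stats::cor(a, b)
}

#' Symmetric residue-residue pair matrix
#'
#' Container for residue-by-residue matrices: motion cross-correlations
#' (`correlation`), mean minimum inter-residue distances
#' (`mean_min_distance`), or a two-ensemble display combining one matrix's
#' upper triangle with another's lower triangle (`combined_display`).
#'
#' @param values square numeric matrix
#' @param kind one of `"correlation"`, `"mean_min_distance"`,
#'   `"combined_display"`
#' @param labels residue labels (row/column names)
#' @return a `pair_matrix` (matrix with `kind` attribute)
#' @export
pair_matrix <- function(values, kind = c("correlation", "mean_min_distance",
                                         "combined_display"),
                        labels = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("pair matrix must be square")
  if (kind == "correlation") {
    if (max(abs(values)) > 1 + 1e-9) stop("correlation entries must lie in [-1, 1]")
  }
  if (kind == "mean_min_distance" && min(values) < 0) {
    stop("distances must be non-negative")
  }
  if (!is.null(labels)) dimnames(values) <- list(labels, labels)
  attr(values, "kind") <- kind
  class(values) <- c("pair_matrix", "matrix", "array")
  values
}

pm_kind <- function(m) attr(m, "kind")

#' @export
print.pair_matrix <- function(x, ...) {
  cat("Pair matrix (", pm_kind(x), "): ", nrow(x), " x ", ncol(x),
      " residues\n", sep = "")
  if (nrow(x) <= 8) print(unclass(x)[, ]) else {
    print(unclass(x)[1:6, 1:6])
    cat("...\n")
  }
  invisible(x)
}

#' Image plot of a pair matrix
#'
#' @param x a `pair_matrix`
#' @param ... passed to [graphics::image()]
#' @export
plot.pair_matrix <- function(x, ...) {
  n <- nrow(x)
  kind <- pm_kind(x)
  pal <- if (kind == "mean_min_distance") {
    grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  } else {
    grDevices::hcl.colors(64, "Blue-Red 3")
  }
  zlim <- if (kind == "mean_min_distance") NULL else c(-1, 1)
  graphics::image(seq_len(n), seq_len(n), t(unclass(x))[, n:1],
                  col = pal, zlim = zlim,
                  xlab = "residue", ylab = "residue",
                  main = paste0("pair matrix (", kind, ")"), ...)
  invisible(x)
}

#' Dynamic cross-correlation matrix (DCCM)
#'
#' For each residue pair (i, j), the normalized inner product of the
#' displacement series:
#' `C_ij = sum_t dx_i(t).dx_j(t) / sqrt(sum_t |dx_i(t)|^2 sum_t |dx_j(t)|^2)`.
#' The diagonal is exactly 1 and values near +/-1 indicate correlated /
#' anticorrelated motion.
#'
#' @param centered a `centered_ensemble` (C-alpha selection)
#' @return a `pair_matrix` of kind `correlation`
#' @export
compute_dccm <- function(centered) {
  stopifnot(inherits(centered, "centered_ensemble"))
  if (centered$n_frames < 2) stop("DCCM needs at least 2 frames")
  d <- centered$disp
  n_res <- ncol(d) / 3
  dx <- d[, seq(1, ncol(d), 3), drop = FALSE]
  dy <- d[, seq(2, ncol(d), 3), drop = FALSE]
  dz <- d[, seq(3, ncol(d), 3), drop = FALSE]
  inner <- crossprod(dx) + crossprod(dy) + crossprod(dz)  # sum_t dx_i . dx_j
  norms <- diag(inner)
  if (any(norms <= 0)) {
    bad <- which(norms <= 0)
    stop("residue(s) with zero total displacement: ",
         paste(centered$labels[bad], collapse = ", "))
  }
  cmat <- inner / sqrt(outer(norms, norms))
  cmat <- (cmat + t(cmat)) / 2
  diag(cmat) <- 1
  cmat[cmat > 1] <- 1
  cmat[cmat < -1] <- -1
  pair_matrix(cmat, "correlation", labels = centered$labels)
}

#' Mean absolute error between two pair matrices
#'
#' Element-wise mean of `|M - M_ref|`. By default the mean runs over all
#' `n^2` elements (including the diagonal); set `diagonal = FALSE` to
#' average over off-diagonal elements only. The agreement statistic for
#' DCCMs and contact maps from two ensembles.
#'
#' @param m,ref `pair_matrix` objects of the same kind and shape
#' @param diagonal include the diagonal in the mean? (default `TRUE`)
#' @return mean absolute error (correlation units, or Angstrom for
#'   distance matrices)
#' @export
matrix_mae <- function(m, ref, diagonal = TRUE) {
  if (!is.null(pm_kind(m)) && !is.null(pm_kind(ref)) &&
      pm_kind(m) != pm_kind(ref)) {
    stop("pair matrices have different kinds: ", pm_kind(m), " vs ", pm_kind(ref))
  }
  if (!all(dim(m) == dim(ref))) {
    stop("pair matrices have different shapes: ", nrow(m), " vs ", nrow(ref))
  }
  diffs <- abs(unclass(m) - unclass(ref))
  if (!diagonal) diag(diffs) <- NA
  mean(diffs, na.rm = TRUE)
}

#' Distance-based residue contact map
#'
#' `D_ij` is the mean over frames of the minimum distance between any
#' selected atom of residue i and any selected atom of residue j in that
#' frame. With the backbone + C-beta selection this matches the contact
#' representation available for coarse-grained model output. The diagonal
#' is 0.
#'
#' @param ens a [conf_ensemble()]
#' @param selection an `atom_selection`; default `backbone_cb`
#' @return a `pair_matrix` of kind `mean_min_distance` (Angstrom)
#' @export
compute_contact_map <- function(ens, selection = NULL) {
  stopifnot(inherits(ens, "conf_ensemble"))
  if (is.null(selection)) selection <- resolve_selection(ens, "backbone_cb")
  groups <- selection$groups
  n_res <- length(groups)
  if (n_res < 2) stop("need at least 2 residues with selected atoms")
  group_id <- rep(seq_len(n_res), vapply(groups, length, integer(1)))
  idx <- unlist(groups, use.names = FALSE)
  acc <- matrix(0, n_res, n_res)
  for (t in seq_len(ens$n_frames)) {
    crd <- matrix(ens$xyz[t, as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))],
                  ncol = 3, byrow = TRUE)
    dm <- as.matrix(stats::dist(crd))
    # min over atom pairs within each residue-pair block
    dmin <- vapply(seq_len(n_res), function(j) {
      cols <- group_id == j
      vapply(seq_len(n_res), function(i) min(dm[group_id == i, cols]), numeric(1))
    }, numeric(n_res))
    acc <- acc + dmin
  }
  d <- acc / ens$n_frames
  d <- (d + t(d)) / 2
  diag(d) <- 0
  pair_matrix(d, "mean_min_distance", labels = names(groups))
}

#' Combine two matrices into one display matrix
#'
#' Builds the conventional side-by-side comparison figure matrix: the strict
#' upper triangle (and diagonal) from one ensemble's matrix and the strict
#' lower triangle from the other's.
#'
#' @param upper,lower `pair_matrix` objects of the same kind and shape
#' @return a `pair_matrix` of kind `combined_display`
#' @export
combine_triangles <- function(upper, lower) {
  if (pm_kind(upper) != pm_kind(lower)) {
    stop("matrices have different kinds: ", pm_kind(upper), " vs ", pm_kind(lower))
  }
  if (!all(dim(upper) == dim(lower))) stop("matrices have different shapes")
  out <- unclass(upper)
  lt <- lower.tri(out)
  out[lt] <- unclass(lower)[lt]
  pair_matrix(out, "combined_display", labels = rownames(upper))
}
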