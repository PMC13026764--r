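#' Read per-frame pocket grid files (PDB point clouds)
#'
#' Pocket-detection tools represent candidate pockets as clusters of grid
#' points. This reader consumes one PDB-format point-cloud file per frame:
#' each grid point is an ATOM/HETATM record, pockets within a frame are
#' distinguished by residue number, and the pocket energy (more negative =
#' more favorable) is carried in the B-factor column (the per-pocket energy
#' is taken as the minimum B-factor over its points).
#'
#' @param paths character vector of per-frame grid files, in frame order
#' @return a `pocket_grid_set`: list (one element per frame) of lists of
#'   pockets, each pocket a list with `coords` (`n x 3` Angstrom) and
#'   `energy`.
#' @export
read_pocket_grids <- function(paths) {
  frames <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("grid file not found: ", p)
    pdb <- bio3d::read.pdb(p, verbose = FALSE)
    a <- pdb$atom
    if (nrow(a) == 0) return(list())
    lapply(split(seq_len(nrow(a)), a$resno), function(i) {
      list(coords = as.matrix(a[i, c("x", "y", "z")]),
           energy = min(a$b[i]))
    })
  })
  structure(frames, class = "pocket_grid_set")
}

#' Write a pocket grid set to per-frame PDB point-cloud files
#'
#' Inverse of [read_pocket_grids()]; used by the synthetic scene generator.
#'
#' @param grids a `pocket_grid_set`
#' @param dir output directory (created if missing)
#' @param prefix file-name prefix
#' @return character vector of written paths
#' @export
write_pocket_grids <- function(grids, dir, prefix = "frame") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(grids))
  for (f in seq_along(grids)) {
    path <- file.path(dir, sprintf("%s_%04d.pdb", prefix, f))
    lines <- character(0)
    eleno <- 0
    for (p in seq_along(grids[[f]])) {
      pk <- grids[[f]][[p]]
      for (g in seq_len(nrow(pk$coords))) {
        eleno <- eleno + 1
        lines <- c(lines, sprintf(
          "ATOM  %5d  PT  GRD %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          eleno, "A", p,
          pk$coords[g, 1], pk$coords[g, 2], pk$coords[g, 3],
          1.0, pk$energy))
      }
    }
    writeLines(c(lines, "END"), path)
    paths[f] <- path
  }
  paths
}

#' Read reference-ligand heavy-atom coordinates from a PDB file
#'
#' @param path PDB file holding the ligand (ATOM or HETATM records)
#' @return `n x 3` coordinate matrix (Angstrom)
#' @export
read_ligand <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  a <- a[toupper(trimws(a$elesy)) != "H", , drop = FALSE]
  if (nrow(a) == 0) stop("no heavy atoms found in ", path)
  as.matrix(a[, c("x", "y", "z")])
}

#' Overlap of one pocket's grid with a reference ligand
#'
#' The fraction of ligand atoms whose nearest grid point lies within
#' `radius`. A value of 1 means the pocket grid covers the whole ligand.
#'
#' @param grid_coords `n x 3` matrix of grid-point coordinates
#' @param ligand_coords `m x 3` matrix of ligand heavy-atom coordinates
#' @param radius coverage radius in Angstrom (default 1)
#' @return overlap fraction in `[0, 1]`
#' @export
pocket_overlap <- function(grid_coords, ligand_coords, radius = 1) {
  stopifnot(radius > 0)
  ligand_coords <- as.matrix(ligand_coords)
  if (is.null(grid_coords) || length(grid_coords) == 0 ||
      nrow(as.matrix(grid_coords)) == 0) {
    warning("empty pocket grid: overlap is 0")
    return(0)
  }
  grid_coords <- as.matrix(grid_coords)
  covered <- vapply(seq_len(nrow(ligand_coords)), function(i) {
    d2 <- rowSums(sweep(grid_coords, 2, ligand_coords[i, ])^2)
    min(d2) <= radius^2
  }, logical(1))
  mean(covered)
}

#' Pocket exposure score of one frame
#'
#' The maximum [pocket_overlap()] over all pockets detected in the frame;
#' 0 when no pockets were detected.
#'
#' @param pockets list of pockets (each with a `coords` field), possibly empty
#' @param ligand_coords ligand heavy-atom coordinates
#' @param radius coverage radius in Angstrom (default 1)
#' @return exposure score in `[0, 1]`
#' @export
frame_exposure <- function(pockets, ligand_coords, radius = 1) {
  if (length(pockets) == 0) return(0)
  max(vapply(pockets, function(p) pocket_overlap(p$coords, ligand_coords, radius),
             numeric(1)))
}

#' Pocket exposure scores for every frame of a grid set
#'
#' @param grids a `pocket_grid_set`
#' @param ligand_coords ligand heavy-atom coordinates
#' @param radius coverage radius in Angstrom (default 1)
#' @return numeric vector of per-frame exposure scores
#' @export
exposure_series <- function(grids, ligand_coords, radius = 1) {
  vapply(grids, frame_exposure, numeric(1),
         ligand_coords = ligand_coords, radius = radius)
}

#' Adaptive exposure-cutoff filtering of frames
#'
#' Retains frames whose exposure score is at least the current cutoff,
#' starting from `start_cutoff`. Whenever no more than `min_retained`
#' frames survive, the cutoff is lowered by `step` and the filter re-run;
#' at a cutoff of 0 every frame is retained regardless. The trade-off: a
#' high cutoff keeps only well-exposed pockets but may leave too few
#' structures for diverse downstream selection.
#'
#' @param scores numeric vector of per-frame exposure scores
#' @param start_cutoff initial cutoff (default 0.5)
#' @param step cutoff decrement (default 0.1)
#' @param min_retained the filter demands strictly more than this many
#'   frames (default 100)
#' @return a `filter_result`: list with `final_cutoff`, `retained` (strictly
#'   increasing frame indices) and `trace` (data.frame of every cutoff
#'   tried and the retained count).
#' @export
adaptive_filter <- function(scores, start_cutoff = 0.5, step = 0.1,
                            min_retained = 100) {
  if (length(scores) == 0) stop("empty exposure series")
  stopifnot(start_cutoff > 0, start_cutoff <= 1, step > 0)
  cutoff <- start_cutoff
  trace <- data.frame(cutoff = numeric(0), n_retained = integer(0))
  repeat {
    retained <- which(scores >= cutoff)
    trace <- rbind(trace, data.frame(cutoff = cutoff,
                                     n_retained = length(retained)))
    if (length(retained) > min_retained || cutoff <= 0) break
    cutoff <- max(0, cutoff - step)
  }
  structure(list(final_cutoff = cutoff, retained = retained, trace = trace),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("Adaptive exposure filter: final cutoff", x$final_cutoff, "->",
      length(x$retained), "frames retained\n")
  print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Protein heavy atoms lining the reference ligand (pocket atoms)
#'
#' Indices (in topology order) of heavy atoms of the reference structure
#' whose nearest ligand atom lies within `radius`. These atoms define the
#' pocket whose conformational diversity is tracked across frames.
#'
#' @param ens a [conf_ensemble()]; the first frame is the reference structure
#' @param ligand_coords ligand heavy-atom coordinates (`m x 3`, Angstrom)
#' @param radius shell radius in Angstrom (default 1; widen for a more
#'   inclusive pocket definition)
#' @return integer vector of atom indices
#' @export
extract_pocket_atoms <- function(ens, ligand_coords, radius = 1) {
  stopifnot(inherits(ens, "conf_ensemble"), radius > 0)
  heavy <- resolve_selection(ens, "heavy")
  crd <- frame_coords(ens, 1L)[heavy$indices, , drop = FALSE]
  ligand_coords <- as.matrix(ligand_coords)
  near <- vapply(seq_len(nrow(crd)), function(i) {
    min(rowSums(sweep(ligand_coords, 2, crd[i, ])^2)) <= radius^2
  }, logical(1))
  idx <- heavy$indices[near]
  if (length(idx) == 0) {
    stop("no protein heavy atoms within ", radius,
         " A of the ligand; consider a larger radius")
  }
  idx
}

#' Cluster retained frames and select representative structures
#'
#' The retained frames' pocket-atom coordinates are reduced to two
#' principal components ([fit_projection()] machinery) and partitioned with
#' k-means (seeded, multiple restarts, best inertia kept). Each cluster's
#' representative is its lowest-energy frame (ties broken by the lower
#' frame index), mirroring the choice of the most favorable pocket energy
#' as the structure taken forward to docking.
#'
#' @param pocket_coords `n_frames x (3 n_pocket_atoms)` matrix of flattened
#'   pocket-atom coordinates of the retained frames
#' @param energies per-frame pocket energies (more negative = better),
#'   aligned with the rows of `pocket_coords`
#' @param k number of clusters (default 5)
#' @param seed integer seed making the k-means deterministic
#' @param n_components PCA components before clustering (default 2)
#' @param nstart k-means restarts (default 10)
#' @return a `cluster_selection`: list with `labels` (per-frame cluster id,
#'   1..k), `representatives` (per-cluster row index into `pocket_coords`),
#'   `representative_energies` and `reduced` (the `n x 2` reduced
#'   coordinates).
#' @export
cluster_and_select <- function(pocket_coords, energies, k = 5, seed = 1,
                               n_components = 2, nstart = 10) {
  pocket_coords <- as.matrix(pocket_coords)
  n <- nrow(pocket_coords)
  if (length(energies) != n) {
    stop("energies length ", length(energies), " != frame count ", n)
  }
  if (n < k) stop("fewer frames (", n, ") than clusters (", k, ")")
  mu <- colMeans(pocket_coords)
  xc <- sweep(pocket_coords, 2, mu)
  if (max(abs(xc)) < 1e-12) {
    stop("all frames identical: clustering is degenerate")
  }
  sv <- svd(xc, nu = 0, nv = n_components)
  red <- xc %*% sv$v
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  km <- tryCatch(
    stats::kmeans(red, centers = k, nstart = nstart, iter.max = 100),
    error = function(e) stop("k-means failed (degenerate input?): ",
                             conditionMessage(e))
  )
  labels <- km$cluster
  reps <- vapply(seq_len(k), function(cl) {
    members <- which(labels == cl)
    members[order(energies[members], members)][1]
  }, integer(1))
  structure(list(labels = labels, representatives = reps,
                 representative_energies = energies[reps],
                 reduced = red, k = k, seed = seed),
            class = "cluster_selection")
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat("Cluster selection: k =", x$k, "over", length(x$labels), "frames\n")
  cat("  representatives (frame index): ",
      paste(x$representatives, collapse = ", "), "\n")
  cat("  representative energies: ",
      paste(format(x$representative_energies, digits = 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Pocket-based structure selection, end to end
#'
#' Score exposures, filter adaptively, extract pocket atoms from the
#' reference, collect the retained frames' pocket coordinates, cluster and
#' pick representatives.
#'
#' @param ens aligned [conf_ensemble()] (frame order matching `grids`)
#' @param grids a `pocket_grid_set`, one entry per frame
#' @param ligand_coords reference-ligand heavy atoms
#' @param radius exposure/pocket-shell radius (default 1)
#' @param start_cutoff,step,min_retained see [adaptive_filter()]
#' @param k,seed see [cluster_and_select()]
#' @return list with `exposures`, `filter` (a `filter_result`),
#'   `pocket_atoms`, `selection` (a `cluster_selection`) and
#'   `selected_frames` (ensemble frame indices of the representatives).
#' @export
pocket_select <- function(ens, grids, ligand_coords, radius = 1,
                          start_cutoff = 0.5, step = 0.1, min_retained = 100,
                          k = 5, seed = 1) {
  stopifnot(inherits(ens, "conf_ensemble"))
  if (length(grids) != ens$n_frames) {
    stop("grid set covers ", length(grids), " frames; ensemble has ",
         ens$n_frames)
  }
  exposures <- exposure_series(grids, ligand_coords, radius)
  filt <- adaptive_filter(exposures, start_cutoff, step, min_retained)
  pocket_atoms <- extract_pocket_atoms(ens, ligand_coords, radius)
  cols <- as.vector(rbind(3 * pocket_atoms - 2, 3 * pocket_atoms - 1,
                          3 * pocket_atoms))
  coords <- ens$xyz[filt$retained, cols, drop = FALSE]
  energies <- vapply(grids[filt$retained], function(fr) {
    if (length(fr) == 0) return(Inf)
    min(vapply(fr, function(p) p$energy, numeric(1)))
  }, numeric(1))
  sel <- cluster_and_select(coords, energies, k = k, seed = seed)
  list(exposures = exposures, filter = filt, pocket_atoms = pocket_atoms,
       selection = sel, selected_frames = filt$retained[sel$representatives])
}
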