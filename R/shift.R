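#' Fit a 2D principal-component projection of C-alpha coordinates
#'
#' PCA of the flattened C-alpha coordinate vectors of an ensemble, keeping
#' the top two components. To compare several variants of one protein, fit
#' the model once on the combined (pooled) ensemble of all variants -- all
#' aligned to one common reference beforehand -- and then [project()] each
#' variant with the same model, so every ensemble lands in the same plane.
#'
#' Component signs are fixed deterministically (the largest-magnitude entry
#' of each component is made positive) so projections are reproducible.
#'
#' @param combined an aligned [conf_ensemble()] pooling all frames
#' @param selection an `atom_selection` (default: C-alpha)
#' @return a `projection_model`: list with `mean_vector` (length `3 n_sel`),
#'   `components` (`2 x 3 n_sel`, orthonormal rows) and
#'   `explained_variance` (the two leading eigenvalues of the coordinate
#'   covariance).
#' @export
fit_projection <- function(combined, selection = NULL) {
  stopifnot(inherits(combined, "conf_ensemble"))
  if (combined$n_frames < 3) stop("PCA needs at least 3 frames")
  if (is.null(selection)) selection <- resolve_selection(combined, "calpha")
  x <- combined$xyz[, sel_xyz_cols(selection), drop = FALSE]
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc, nu = 0, nv = 2)
  comps <- t(sv$v)  # 2 x 3n
  for (k in 1:2) {
    j <- which.max(abs(comps[k, ]))
    if (comps[k, j] < 0) comps[k, ] <- -comps[k, ]
  }
  ev <- (sv$d[1:2]^2) / nrow(x)  # population covariance eigenvalues
  structure(list(mean_vector = mu, components = comps,
                 explained_variance = ev,
                 n_fit_frames = nrow(x)),
            class = "projection_model")
}

#' @export
print.projection_model <- function(x, ...) {
  tot <- x$explained_variance
  cat("2-component coordinate PCA (fit on", x$n_fit_frames, "frames)\n")
  cat("  eigenvalues:", format(tot, digits = 5), "\n")
  invisible(x)
}

#' Project an ensemble onto a fitted principal-component plane
#'
#' @param ens an aligned [conf_ensemble()] (same reference frame as the
#'   model's fitting ensemble)
#' @param model a `projection_model` from [fit_projection()]
#' @param selection an `atom_selection` (default: C-alpha)
#' @return `n_frames x 2` matrix of (PC1, PC2) scores
#' @export
project_ensemble <- function(ens, model, selection = NULL) {
  stopifnot(inherits(ens, "conf_ensemble"), inherits(model, "projection_model"))
  if (is.null(selection)) selection <- resolve_selection(ens, "calpha")
  x <- ens$xyz[, sel_xyz_cols(selection), drop = FALSE]
  if (ncol(x) != length(model$mean_vector)) {
    stop("ensemble has ", ncol(x) / 3, " selected atoms; model was fitted on ",
         length(model$mean_vector) / 3)
  }
  pts <- sweep(x, 2, model$mean_vector) %*% t(model$components)
  colnames(pts) <- c("PC1", "PC2")
  pts
}

#' Shared-bin 2D histograms of projected ensembles
#'
#' Builds one normalized 2D histogram per group over a single common grid:
#' uniform bins spanning the pooled min/max of all groups on each axis.
#' Identical bin edges are what make the histograms comparable by
#' [kl_divergence()].
#'
#' @param groups list of `n x 2` point matrices (from [project_ensemble()])
#' @param n_bins bins per axis (default 50)
#' @return list of `grid_histogram` objects (fields `x_edges`, `y_edges`,
#'   `prob`), one per group, sharing identical edges
#' @export
shared_histogram <- function(groups, n_bins = 50) {
  stopifnot(is.list(groups), length(groups) >= 2, n_bins >= 2)
  groups <- lapply(groups, function(g) {
    g <- as.matrix(g)
    stopifnot(ncol(g) == 2)
    g
  })
  all_pts <- do.call(rbind, groups)
  rng_x <- range(all_pts[, 1])
  rng_y <- range(all_pts[, 2])
  if (diff(rng_x) == 0 || diff(rng_y) == 0) {
    stop("zero range on a projection axis: all points identical")
  }
  x_edges <- seq(rng_x[1], rng_x[2], length.out = n_bins + 1)
  y_edges <- seq(rng_y[1], rng_y[2], length.out = n_bins + 1)
  lapply(groups, function(g) {
    ix <- findInterval(g[, 1], x_edges, rightmost.closed = TRUE, all.inside = TRUE)
    iy <- findInterval(g[, 2], y_edges, rightmost.closed = TRUE, all.inside = TRUE)
    counts <- matrix(0, n_bins, n_bins)
    for (k in seq_len(nrow(g))) {
      counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
    }
    structure(list(x_edges = x_edges, y_edges = y_edges,
                   prob = counts / sum(counts)),
              class = "grid_histogram")
  })
}

#' @export
print.grid_histogram <- function(x, ...) {
  cat("Grid histogram:", length(x$x_edges) - 1, "x", length(x$y_edges) - 1,
      "bins, total mass", format(sum(x$prob), digits = 10), "\n")
  invisible(x)
}

#' Kullback-Leibler divergence between two shared-grid histograms
#'
#' `KL(WT || Mut) = sum_i B_i^WT ln(B_i^WT / B_i^Mut)` in nats, with the
#' wild-type (reference) distribution leading. Because the ratio is
#' undefined where a mutant bin is empty, both tables are first augmented
#' by an additive pseudocount per bin and renormalized; the default
#' (`1e-6` of total mass) keeps the divergence finite while being
#' negligible for well-populated bins. The bin grid and the pseudocount are
#' part of the quantity's definition and should be reported with it.
#'
#' @param wt,mut `grid_histogram` objects with identical edges
#' @param pseudocount additive mass per bin before renormalization
#' @return KL divergence in nats (non-negative; exactly 0 when `wt == mut`)
#' @export
kl_divergence <- function(wt, mut, pseudocount = 1e-6) {
  stopifnot(inherits(wt, "grid_histogram"), inherits(mut, "grid_histogram"),
            pseudocount > 0)
  if (!isTRUE(all.equal(wt$x_edges, mut$x_edges)) ||
      !isTRUE(all.equal(wt$y_edges, mut$y_edges))) {
    stop("histograms do not share bin edges; build them with shared_histogram()")
  }
  p <- wt$prob + pseudocount
  q <- mut$prob + pseudocount
  p <- p / sum(p)
  q <- q / sum(q)
  sum(p * log(p / q))
}

#' Distribution shift of variant ensembles relative to a wild type
#'
#' The complete shift pipeline: pool all ensembles, fit one PC projection,
#' project each ensemble, histogram them on a shared grid, and return the
#' KL divergence of each variant from the wild type.
#'
#' @param wt aligned wild-type [conf_ensemble()]
#' @param mutants named list of aligned variant ensembles
#' @param n_bins bins per axis (default 50)
#' @param pseudocount see [kl_divergence()]
#' @return list with `kl` (named numeric vector, nats), `model` (the fitted
#'   `projection_model`), `projections` (named list of point matrices) and
#'   the binning parameters.
#' @export
ensemble_shift <- function(wt, mutants, n_bins = 50, pseudocount = 1e-6) {
  stopifnot(inherits(wt, "conf_ensemble"), is.list(mutants), length(mutants) >= 1)
  if (is.null(names(mutants))) {
    names(mutants) <- paste0("mut", seq_along(mutants))
  }
  combined <- concat_ensembles(c(list(wt), mutants))
  model <- fit_projection(combined)
  projections <- c(list(WT = project_ensemble(wt, model)),
                   lapply(mutants, project_ensemble, model = model))
  hists <- shared_histogram(projections, n_bins = n_bins)
  kl <- vapply(seq_along(mutants), function(k) {
    kl_divergence(hists[[1]], hists[[k + 1]], pseudocount = pseudocount)
  }, numeric(1))
  names(kl) <- names(mutants)
  list(kl = kl, model = model, projections = projections,
       n_bins = n_bins, pseudocount = pseudocount, log_base = "e")
}
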