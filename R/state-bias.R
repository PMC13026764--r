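#' Two-state (apo/holo) RMSD projection of an ensemble
#'
#' For every frame, the C-alpha RMSD to the apo reference and to the holo
#' reference, each after an independent rigid superposition onto that
#' reference. Plotting the two series against each other shows which of two
#' known end states an ensemble's samples resemble, and whether sampling is
#' biased towards one of them.
#'
#' @param ens a [conf_ensemble()]
#' @param apo,holo matched reference coordinate matrices (`n x 3`, Angstrom)
#'   covering the same residues; row counts must equal each other and the
#'   ensemble's selection size. Matching equivalent residues between the
#'   two structures is the caller's responsibility.
#' @param selection an `atom_selection` (default: C-alpha)
#' @return a `two_state_projection`: data.frame with columns `rmsd_apo` and
#'   `rmsd_holo` (Angstrom), one row per frame, with attribute
#'   `reference_rmsd` (the fitted RMSD between apo and holo themselves).
#' @export
two_state_project <- function(ens, apo, holo, selection = NULL) {
  stopifnot(inherits(ens, "conf_ensemble"))
  if (is.null(selection)) selection <- resolve_selection(ens, "calpha")
  apo <- as.matrix(apo); holo <- as.matrix(holo)
  if (nrow(apo) != nrow(holo)) {
    stop("apo and holo references differ in size: ", nrow(apo), " vs ", nrow(holo))
  }
  n_sel <- length(selection$indices)
  if (nrow(apo) != n_sel && nrow(apo) != ens$n_atoms) {
    stop("references have ", nrow(apo), " atoms; ensemble selection has ", n_sel)
  }
  ra <- rmsd_to_reference(ens, apo, selection)
  rh <- rmsd_to_reference(ens, holo, selection)
  apo_sel <- if (nrow(apo) == n_sel) apo else apo[selection$indices, , drop = FALSE]
  holo_sel <- if (nrow(holo) == n_sel) holo else holo[selection$indices, , drop = FALSE]
  out <- data.frame(rmsd_apo = ra, rmsd_holo = rh)
  attr(out, "reference_rmsd") <- kabsch_superpose(holo_sel, apo_sel)$fit_rmsd
  class(out) <- c("two_state_projection", "data.frame")
  out
}

#' @export
print.two_state_projection <- function(x, ...) {
  cat("Two-state RMSD projection:", nrow(x), "frames; apo<->holo RMSD",
      format(attr(x, "reference_rmsd"), digits = 4), "A\n")
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Plot a two-state projection
#'
#' @param x a `two_state_projection`
#' @param cutoff optional state cutoff (Angstrom) drawn as guide lines
#' @param ... passed to [graphics::plot()]
#' @export
plot.two_state_projection <- function(x, cutoff = 3, ...) {
  graphics::plot(x$rmsd_apo, x$rmsd_holo, pch = 16, cex = 0.5,
                 col = grDevices::adjustcolor("steelblue", 0.5),
                 xlab = "RMSD to apo (A)", ylab = "RMSD to holo (A)", ...)
  if (!is.null(cutoff)) graphics::abline(v = cutoff, h = cutoff, lty = 2)
  graphics::abline(0, 1, col = "grey")
  invisible(x)
}

#' State occupancy summary of a two-state projection
#'
#' Counts frames within `cutoff` of the apo state, of the holo state, of
#' both, and of neither (strict inequality: a frame exactly at the cutoff
#' is outside the state), plus the fraction of frames lying closer to holo
#' than to apo (`holo_bias_fraction`). An ensemble "sampled both states"
#' when both state counts are positive.
#'
#' @param proj a `two_state_projection`
#' @param cutoff state membership cutoff in Angstrom (default 3)
#' @return an `occupancy_summary` list: `n_frames`, `n_apo_like`,
#'   `n_holo_like`, `n_both`, `n_neither`, `holo_bias_fraction`,
#'   `sampled_both`, `cutoff`.
#' @export
occupancy <- function(proj, cutoff = 3) {
  stopifnot(inherits(proj, "two_state_projection"), cutoff > 0)
  apo_like <- proj$rmsd_apo < cutoff
  holo_like <- proj$rmsd_holo < cutoff
  out <- list(
    n_frames = nrow(proj),
    n_apo_like = sum(apo_like),
    n_holo_like = sum(holo_like),
    n_both = sum(apo_like & holo_like),
    n_neither = sum(!apo_like & !holo_like),
    holo_bias_fraction = mean(proj$rmsd_holo < proj$rmsd_apo),
    sampled_both = sum(apo_like) > 0 && sum(holo_like) > 0,
    cutoff = cutoff
  )
  class(out) <- "occupancy_summary"
  out
}

#' @export
print.occupancy_summary <- function(x, ...) {
  cat("Occupancy at cutoff ", x$cutoff, " A over ", x$n_frames, " frames:\n",
      "  apo-like ", x$n_apo_like, ", holo-like ", x$n_holo_like,
      ", both ", x$n_both, ", neither ", x$n_neither, "\n",
      "  holo bias fraction ", format(x$holo_bias_fraction, digits = 4),
      "; sampled both states: ", x$sampled_both, "\n", sep = "")
  invisible(x)
}
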