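#' Stratify residue pairs by sequence separation
#'
#' Labels each residue pair (i, j) by its relative sequence separation
#' `|i - j| / n_res`: `close` below `near_frac`, `far` above `far_frac`,
#' `middle` otherwise. Boundaries are exclusive (a pair exactly at
#' `near_frac` or `far_frac` falls to `middle`). Used to ask whether
#' short-range or long-range correlations are better preserved.
#'
#' @param n_res number of residues
#' @param near_frac close/middle boundary as a fraction of chain length
#'   (default 0.2)
#' @param far_frac middle/far boundary (default 0.8)
#' @return `n_res x n_res` character matrix of labels (`NA` diagonal),
#'   class `pair_strata`
#' @export
stratify_sequence_separation <- function(n_res, near_frac = 0.2, far_frac = 0.8) {
  stopifnot(n_res >= 2, near_frac < far_frac)
  sep <- abs(outer(seq_len(n_res), seq_len(n_res), "-")) / n_res
  lab <- matrix("middle", n_res, n_res)
  lab[sep < near_frac] <- "close"
  lab[sep > far_frac] <- "far"
  diag(lab) <- NA_character_
  structure(lab, class = c("pair_strata", "matrix", "array"))
}

#' Stratify residues into terminal vs middle regions
#'
#' The first and last `terminal_len` residues are labeled `terminal`, the
#' rest `middle`. Flexibility recovery is typically compared between these
#' regions because terminal flexibility has a simpler (monotone) shape.
#'
#' @param n_res number of residues
#' @param terminal_len residues per terminus; default
#'   `max(5, round(0.1 * n_res))`
#' @return character vector of length `n_res` with values
#'   `"terminal"`/`"middle"`
#' @export
stratify_termini <- function(n_res, terminal_len = max(5, round(0.1 * n_res))) {
  stopifnot(n_res >= 2, terminal_len >= 0)
  if (2 * terminal_len >= n_res) {
    stop("terminal_len = ", terminal_len, " leaves no middle region for n_res = ",
         n_res)
  }
  lab <- rep("middle", n_res)
  if (terminal_len > 0) {
    lab[seq_len(terminal_len)] <- "terminal"
    lab[seq(n_res - terminal_len + 1, n_res)] <- "terminal"
  }
  lab
}

# conventional biochemistry groupings; HIS counted aromatic (not basic)
.acidic_residues <- c("ASP", "GLU")
.basic_residues <- c("LYS", "ARG")
.aromatic_residues <- c("PHE", "TYR", "TRP", "HIS")
.apolar_residues <- c("ALA", "VAL", "LEU", "ILE", "MET", "PRO", "GLY")

#' Classify close-contact residue pairs by interaction chemistry
#'
#' From the set of close contacts on a reference mean-minimum-distance map,
#' pairs are labeled `polar_polar` (one acidic + one basic residue, i.e.
#' oppositely charged), `pi_pi` (both aromatic), `non_polar` (both apolar)
#' or `other`. Pairs at or beyond the cutoff are excluded (`NA`).
#'
#' @param ens a [conf_ensemble()] (topology source) or a `residues()` table
#' @param reference_map `pair_matrix` of kind `mean_min_distance` computed
#'   on the reference ensemble
#' @param close_cutoff contact cutoff in Angstrom (default 5)
#' @param sets optional named list overriding the residue sets
#'   (`acidic`, `basic`, `aromatic`, `apolar`)
#' @return `pair_strata` character matrix (`NA` for non-contacts and the
#'   diagonal)
#' @export
classify_interaction_pairs <- function(ens, reference_map, close_cutoff = 5,
                                       sets = list()) {
  res <- if (inherits(ens, "conf_ensemble")) residues(ens) else ens
  stopifnot(pm_kind(reference_map) == "mean_min_distance")
  n_res <- nrow(res)
  if (nrow(reference_map) != n_res) {
    stop("reference map has ", nrow(reference_map), " residues; topology has ",
         n_res)
  }
  acidic <- if (!is.null(sets$acidic)) sets$acidic else .acidic_residues
  basic <- if (!is.null(sets$basic)) sets$basic else .basic_residues
  aromatic <- if (!is.null(sets$aromatic)) sets$aromatic else .aromatic_residues
  apolar <- if (!is.null(sets$apolar)) sets$apolar else .apolar_residues
  known <- unique(c(acidic, basic, aromatic, apolar,
                    "SER", "THR", "ASN", "GLN", "CYS"))
  unknown <- setdiff(unique(res$resid), known)
  if (length(unknown) > 0) {
    warning("unknown residue name(s) labeled 'other': ",
            paste(unknown, collapse = ", "))
  }
  is_acid <- res$resid %in% acidic
  is_base <- res$resid %in% basic
  is_arom <- res$resid %in% aromatic
  is_apol <- res$resid %in% apolar
  lab <- matrix(NA_character_, n_res, n_res)
  close <- unclass(reference_map) < close_cutoff
  diag(close) <- FALSE
  for (i in seq_len(n_res - 1)) {
    for (j in seq(i + 1, n_res)) {
      if (!close[i, j]) next
      l <- if ((is_acid[i] && is_base[j]) || (is_base[i] && is_acid[j])) {
        "polar_polar"
      } else if (is_arom[i] && is_arom[j]) {
        "pi_pi"
      } else if (is_apol[i] && is_apol[j]) {
        "non_polar"
      } else {
        "other"
      }
      lab[i, j] <- l
      lab[j, i] <- l
    }
  }
  structure(lab, class = c("pair_strata", "matrix", "array"))
}

#' Per-stratum mean absolute error between two pair matrices
#'
#' The MAE of [matrix_mae()] broken down by a pair-level stratum assignment
#' (sequence separation or interaction class). Each stratum's MAE is the
#' mean over its unique unordered pairs (i < j); pairs with an `NA` label
#' are excluded. An empty stratum yields `NA`, not zero.
#'
#' @param m,ref `pair_matrix` objects of the same kind and shape
#' @param strata `pair_strata` matrix of labels (or any character matrix of
#'   matching shape)
#' @return named numeric vector of per-label MAEs, plus attribute
#'   `n_pairs` (pair counts per label)
#' @export
stratified_mae <- function(m, ref, strata) {
  if (!all(dim(m) == dim(ref)) || !all(dim(m) == dim(strata))) {
    stop("matrix and strata shapes are inconsistent")
  }
  ut <- upper.tri(m)
  labs <- strata[ut]
  diffs <- abs(unclass(m) - unclass(ref))[ut]
  keep <- !is.na(labs)
  levels <- sort(unique(labs[keep]))
  out <- vapply(levels, function(l) mean(diffs[keep & labs == l]), numeric(1))
  counts <- vapply(levels, function(l) sum(keep & labs == l), numeric(1))
  names(out) <- levels
  attr(out, "n_pairs") <- counts
  out
}

#' Per-stratum Pearson correlation between two per-residue profiles
#'
#' Companion to [stratified_mae()] for residue-level strata (terminal vs
#' middle regions, secondary-structure classes): the profile correlation
#' computed within each stratum separately.
#'
#' @param a,b numeric vectors of equal length (e.g. RMSF profiles)
#' @param strata character vector of per-residue labels, same length
#' @return named numeric vector of per-label correlations (`NA` where a
#'   stratum has fewer than 3 residues or zero variance)
#' @export
stratified_pcc <- function(a, b, strata) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b) || length(a) != length(strata)) {
    stop("profiles and strata must have equal length")
  }
  levels <- sort(unique(strata[!is.na(strata)]))
  out <- vapply(levels, function(l) {
    i <- which(strata == l)
    if (length(i) < 3 || stats::sd(a[i]) == 0 || stats::sd(b[i]) == 0) {
      return(NA_real_)
    }
    stats::cor(a[i], b[i])
  }, numeric(1))
  names(out) <- levels
  out
}

#' Read a per-residue secondary-structure annotation file
#'
#' Expects a two-column whitespace- or tab-separated file: residue position
#' (1-based) and class (`H` helix, `E` sheet/extended, `C` coil/loop).
#' The package does not assign secondary structure itself; annotations come
#' from an external tool.
#'
#' @param path annotation file
#' @param n_res expected residue count (validated if given)
#' @return character vector of classes, one per residue
#' @export
read_ss_annotation <- function(path, n_res = NULL) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("annotation file needs two columns: position, class")
  cls <- rep(NA_character_, max(tab[[1]]))
  cls[tab[[1]]] <- toupper(trimws(tab[[2]]))
  bad <- setdiff(unique(cls[!is.na(cls)]), c("H", "E", "C"))
  if (length(bad) > 0) {
    stop("unknown secondary-structure class(es): ", paste(bad, collapse = ", "))
  }
  if (!is.null(n_res) && length(cls) != n_res) {
    stop("annotation covers ", length(cls), " residues; expected ", n_res)
  }
  cls
}
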