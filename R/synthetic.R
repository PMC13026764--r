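# Seeded generators producing ensembles, scenes and score tables with known
# ground truth. They emulate the *statistical* structure the analysis
# modules measure (fluctuation scale, inter-residue correlation, two-state
# mixtures, designed pocket exposures, class-separated score distributions),
# not force-field physics.

# evaluate code under a seed, leaving the caller's RNG state untouched
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Ideal-helix reference structure
#'
#' A single-frame ensemble tracing an ideal helix with the coarse-grained
#' backbone + C-beta atom set: C-alpha positions on a helix (rise 1.5 A,
#' 100 degree turn, radius 2.3 A) and N, C, O, CB at fixed offsets from
#' each C-alpha. Glycine residues get no C-beta. The geometry constants are
#' arbitrary but fixed; they produce a valid self-avoiding trace with
#' realistic consecutive C-alpha distances (~3.8 A).
#'
#' @param n_res number of residues (>= 2)
#' @param residues residue names, recycled to length `n_res`
#'   (default `"ALA"`); use e.g. `"GLY"` entries to exercise the missing-CB
#'   case or charged/aromatic names for interaction-class analyses
#' @param chain chain identifier
#' @return a one-frame [conf_ensemble()]
#' @export
make_backbone <- function(n_res, residues = "ALA", chain = "A") {
  stopifnot(n_res >= 2)
  residues <- rep(toupper(residues), length.out = n_res)
  rise <- 1.5
  turn <- 100 * pi / 180
  radius <- 2.3
  offsets <- list(
    N = c(-0.90, 0.60, -0.80),
    CA = c(0, 0, 0),
    C = c(0.95, 0.55, 0.75),
    O = c(1.10, 1.70, 0.95),
    CB = c(-0.55, -1.30, 0.55)
  )
  atom_rows <- list()
  coords <- list()
  for (i in seq_len(n_res)) {
    ca <- c(radius * cos(i * turn), radius * sin(i * turn), rise * i)
    names_i <- c("N", "CA", "C", "O", if (residues[i] != "GLY") "CB")
    for (nm in names_i) {
      atom_rows[[length(atom_rows) + 1]] <- data.frame(
        elety = nm, resid = residues[i], chain = chain, resno = i,
        elesy = substr(nm, 1, 1), stringsAsFactors = FALSE)
      coords[[length(coords) + 1]] <- ca + offsets[[nm]]
    }
  }
  atom <- do.call(rbind, atom_rows)
  conf_ensemble(atom, matrix(unlist(coords), nrow = 1))
}

# per-frame, per-residue displacement field with optional correlated blocks;
# returns n_frames x (3 n_res) matrix (Angstrom). Correlation is induced by
# a shared standard-normal latent per block and axis:
# dx = sqrt(1 - rho) e_i + sqrt(rho) e_shared, giving pairwise correlation
# exactly rho within the block and positive definiteness by construction.
residue_displacements <- function(n_res, n_frames, sigma_profile,
                                  correlation_blocks = NULL) {
  sigma <- rep(sigma_profile, length.out = n_res)
  stopifnot(all(sigma > 0))
  eps <- array(stats::rnorm(n_frames * n_res * 3), dim = c(n_frames, n_res, 3))
  if (!is.null(correlation_blocks)) {
    seen <- integer(0)
    for (blk in correlation_blocks) {
      members <- sort(unique(c(blk$a, blk$b)))
      rho <- blk$rho
      if (rho < 0 || rho >= 1) {
        stop("block correlation must satisfy 0 <= rho < 1 (got ", rho, ")")
      }
      if (any(members < 1 | members > n_res)) stop("block residues out of range")
      if (length(intersect(members, seen)) > 0) {
        stop("correlation blocks overlap; the latent-factor construction ",
             "needs disjoint blocks")
      }
      seen <- c(seen, members)
      shared <- array(stats::rnorm(n_frames * 3), dim = c(n_frames, 1, 3))
      eps[, members, ] <- sqrt(1 - rho) * eps[, members, , drop = FALSE] +
        sqrt(rho) * shared[, rep(1, length(members)), , drop = FALSE]
    }
  }
  disp <- sweep(eps, 2, sigma, "*")
  out <- matrix(0, n_frames, 3 * n_res)
  out[, seq(1, 3 * n_res, 3)] <- disp[, , 1]
  out[, seq(2, 3 * n_res, 3)] <- disp[, , 2]
  out[, seq(3, 3 * n_res, 3)] <- disp[, , 3]
  out
}

# expand a per-residue displacement matrix to all atoms of the topology
# (each residue moves rigidly)
expand_to_atoms <- function(ref, res_disp) {
  keys <- ref$residue_key
  res_of_atom <- match(keys, unique(keys))
  n_frames <- nrow(res_disp)
  xyz <- matrix(rep(ref$xyz[1, ], each = n_frames), nrow = n_frames)
  for (a in seq_len(ref$n_atoms)) {
    r <- res_of_atom[a]
    xyz[, 3 * a - 2] <- xyz[, 3 * a - 2] + res_disp[, 3 * r - 2]
    xyz[, 3 * a - 1] <- xyz[, 3 * a - 1] + res_disp[, 3 * r - 1]
    xyz[, 3 * a] <- xyz[, 3 * a] + res_disp[, 3 * r]
  }
  xyz
}

#' Harmonic ensemble with prescribed flexibility and correlation
#'
#' Frames are the reference plus zero-mean Gaussian residue displacements
#' (each residue moves rigidly) with per-residue, per-coordinate standard
#' deviation `sigma_profile`. The expected C-alpha RMSF of residue i is
#' therefore `sigma_i * sqrt(3)`. Optional correlation blocks impose a
#' target displacement correlation `rho` between all residues of a block
#' via a shared latent factor.
#'
#' @param reference a one-frame [conf_ensemble()] (e.g. [make_backbone()])
#' @param n_frames frames to generate
#' @param sigma_profile per-residue displacement scale in Angstrom per
#'   coordinate (scalar or length `n_res`)
#' @param correlation_blocks list of blocks, each a list with residue index
#'   vectors `a` and `b` and target correlation `rho` in `[0, 1)`; blocks
#'   must be disjoint
#' @param seed integer seed (reproducible, leaves the global RNG untouched)
#' @return a [conf_ensemble()] with attribute `ground_truth` (the inputs)
#' @export
make_harmonic_ensemble <- function(reference, n_frames, sigma_profile = 0.5,
                                   correlation_blocks = NULL, seed = 1) {
  stopifnot(inherits(reference, "conf_ensemble"), n_frames >= 1)
  n_res <- nrow(residues(reference))
  xyz <- with_seed(seed, {
    rd <- residue_displacements(n_res, n_frames, sigma_profile,
                                correlation_blocks)
    expand_to_atoms(reference, rd)
  })
  out <- conf_ensemble(reference$atom, xyz)
  attr(out, "ground_truth") <- list(
    sigma_profile = rep(sigma_profile, length.out = n_res),
    correlation_blocks = correlation_blocks, seed = seed)
  out
}

#' Two-state mixture ensemble around apo/holo references
#'
#' Each frame is a copy of the apo or the holo reference (Bernoulli with
#' probability `holo_weight` of holo) plus isotropic Gaussian jitter on
#' every atom. The true per-frame state labels are attached, so state
#' recovery by the two-state RMSD projection can be checked exactly.
#'
#' @param apo,holo one-frame [conf_ensemble()]s sharing a topology
#' @param holo_weight probability of the holo state in `[0, 1]`
#' @param jitter_sigma isotropic per-coordinate jitter (Angstrom)
#' @param n_frames frames to generate
#' @param seed integer seed
#' @return a [conf_ensemble()] with attribute `state` (character vector,
#'   `"apo"`/`"holo"` per frame)
#' @export
make_two_state_ensemble <- function(apo, holo, holo_weight = 0.5,
                                    jitter_sigma = 0.5, n_frames = 1000,
                                    seed = 1) {
  stopifnot(inherits(apo, "conf_ensemble"), inherits(holo, "conf_ensemble"),
            holo_weight >= 0, holo_weight <= 1, jitter_sigma >= 0)
  if (apo$n_atoms != holo$n_atoms) {
    stop("apo and holo topologies differ in atom count")
  }
  res <- with_seed(seed, {
    state <- ifelse(stats::runif(n_frames) < holo_weight, "holo", "apo")
    base <- rbind(apo$xyz[1, ], holo$xyz[1, ])
    xyz <- base[ifelse(state == "holo", 2, 1), , drop = FALSE]
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = jitter_sigma),
                        nrow = n_frames)
    list(xyz = xyz, state = state)
  })
  out <- conf_ensemble(apo$atom, res$xyz)
  attr(out, "state") <- res$state
  out
}

#' Ensembles displaced along a fixed mode ("mutant" shifts)
#'
#' Generates one harmonic ensemble per requested magnitude, each with its
#' reference displaced along a fixed, normalized per-residue mode by
#' `magnitude * sigma` (so magnitude is expressed in units of the
#' per-coordinate noise scale). Magnitude 0 reproduces the base
#' distribution. All ensembles share the mode, so a distribution-shift
#' statistic should grow monotonically with the magnitude.
#'
#' @param reference a one-frame [conf_ensemble()]
#' @param shift_magnitudes numeric vector of non-negative magnitudes
#' @param n_frames frames per ensemble
#' @param sigma per-coordinate noise scale in Angstrom (scalar)
#' @param seed integer seed; the mode is drawn once from it and each
#'   ensemble gets an independent sub-seed
#' @return named list of [conf_ensemble()]s (names `shift_<magnitude>`),
#'   with attribute `mode` (the `n_res x 3` unit displacement mode)
#' @export
make_shifted_ensemble <- function(reference, shift_magnitudes,
                                  n_frames = 2000, sigma = 0.5, seed = 1) {
  stopifnot(inherits(reference, "conf_ensemble"), all(shift_magnitudes >= 0))
  n_res <- nrow(residues(reference))
  mode <- with_seed(seed, {
    m <- matrix(stats::rnorm(3 * n_res), ncol = 3)
    m / sqrt(sum(m^2))
  })
  mode_flat <- as.vector(t(mode))
  out <- vector("list", length(shift_magnitudes))
  names(out) <- paste0("shift_", shift_magnitudes)
  for (k in seq_along(shift_magnitudes)) {
    shifted_ref <- reference
    res_shift <- shift_magnitudes[k] * sigma * mode_flat
    xyz <- reference$xyz
    keys <- reference$residue_key
    res_of_atom <- match(keys, unique(keys))
    for (a in seq_len(reference$n_atoms)) {
      r <- res_of_atom[a]
      xyz[1, (3 * a - 2):(3 * a)] <- xyz[1, (3 * a - 2):(3 * a)] +
        res_shift[(3 * r - 2):(3 * r)]
    }
    shifted_ref <- conf_ensemble(reference$atom, xyz)
    out[[k]] <- make_harmonic_ensemble(shifted_ref, n_frames = n_frames,
                                       sigma_profile = sigma,
                                       seed = seed + 1000 * k)
  }
  attr(out, "mode") <- mode
  out
}

#' Synthetic pocket scene with designed exposures
#'
#' Builds a reference ligand (heavy atoms spaced 3 A apart on a line) and,
#' for each frame, a pocket grid covering exactly `round(e * n)` of the `n`
#' ligand atoms, so that the frame's exposure score equals the designed
#' value `e` exactly at any radius below the atom spacing. Each frame also
#' gets a decoy pocket far from the ligand (exposure 0) with an unfavorable
#' energy, so the per-frame maximum genuinely exercises the scoring.
#'
#' @param exposures designed per-frame exposure values; each must be
#'   realizable as `k / n_ligand_atoms` with integer `k`
#' @param n_ligand_atoms ligand heavy-atom count (default 8)
#' @param energies per-frame energy of the ligand-covering pocket (more
#'   negative = better); default: seeded draws in `[-15, -5]`
#' @param seed integer seed (only used for default energies)
#' @return list with `grids` (a `pocket_grid_set`), `ligand` (`n x 3`
#'   coordinates), `exposures` and `energies`
#' @export
make_pocket_scene <- function(exposures, n_ligand_atoms = 8, energies = NULL,
                              seed = 1) {
  k <- exposures * n_ligand_atoms
  if (any(abs(k - round(k)) > 1e-9)) {
    bad <- exposures[abs(k - round(k)) > 1e-9][1]
    stop("exposure ", bad, " is not realizable as k/", n_ligand_atoms,
         " with integer k")
  }
  k <- as.integer(round(k))
  n_frames <- length(exposures)
  if (is.null(energies)) {
    energies <- with_seed(seed, stats::runif(n_frames, -15, -5))
  }
  stopifnot(length(energies) == n_frames)
  ligand <- cbind(3 * seq_len(n_ligand_atoms), 0, 0)
  decoy <- cbind(3 * seq_len(4), 0, 100)  # > any sensible radius away
  frames <- lapply(seq_len(n_frames), function(f) {
    pockets <- list(list(coords = decoy, energy = -1))
    if (k[f] > 0) {
      pockets <- c(pockets, list(list(
        coords = ligand[seq_len(k[f]), , drop = FALSE],
        energy = energies[f])))
    }
    pockets
  })
  list(grids = structure(frames, class = "pocket_grid_set"),
       ligand = ligand, exposures = exposures, energies = energies)
}

#' Synthetic screening table with known class separability
#'
#' Aggregated (best) scores of actives are drawn from `Normal(-delta, 1)`
#' and decoys from `Normal(0, 1)` (lower = better), so the expected ROC AUC
#' is `pnorm(delta / sqrt(2))` in closed form. With several structure
#' columns, the first column holds the ligand's base score and the others
#' add a positive (less favorable) offset, so best-score aggregation
#' recovers the base score exactly.
#'
#' @param n_active,n_decoy class sizes
#' @param delta class separation of the score means
#' @param n_structures number of per-structure score columns (default 1)
#' @param seed integer seed
#' @return a `screening_table` data.frame
#' @export
make_screening_table <- function(n_active, n_decoy, delta = 1,
                                 n_structures = 1, seed = 1) {
  stopifnot(n_active >= 1, n_decoy >= 1, n_structures >= 1)
  with_seed(seed, {
    n <- n_active + n_decoy
    label <- c(rep("active", n_active), rep("decoy", n_decoy))
    base <- stats::rnorm(n, mean = ifelse(label == "active", -delta, 0), sd = 1)
    scores <- matrix(base, n, n_structures)
    if (n_structures > 1) {
      scores[, -1] <- scores[, -1] +
        matrix(abs(stats::rnorm(n * (n_structures - 1), sd = 1)),
               n, n_structures - 1)
    }
    colnames(scores) <- paste0("score_struct", seq_len(n_structures))
    tab <- data.frame(ligand_id = sprintf("lig%05d", seq_len(n)),
                      label = label, stringsAsFactors = FALSE)
    tab <- cbind(tab, as.data.frame(scores))
    class(tab) <- c("screening_table", "data.frame")
    attr(tab, "score_cols") <- colnames(scores)
    tab
  })
}
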