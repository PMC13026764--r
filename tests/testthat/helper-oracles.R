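# Independent oracles used to check the package's implementations.
# These deliberately use different algorithms (direct enumeration, rotation
# search) from the code under test.

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# brute-force minimum RMSD over rotations: random quaternion grid followed by
# Nelder-Mead polish on the best candidate (never touches svd/Kabsch)
brute_force_min_rmsd <- function(mobile, reference, n_grid = 2000,
                                 grid_seed = 42) {
  a <- sweep(mobile, 2, colMeans(mobile))
  b <- sweep(reference, 2, colMeans(reference))
  f <- function(q) sqrt(sum((a %*% t(quat_to_rot(q)) - b)^2) / nrow(a))
  qs <- matrix(ensdyn:::with_seed(grid_seed, stats::rnorm(4 * n_grid)), ncol = 4)
  vals <- apply(qs, 1, f)
  best_q <- qs[which.min(vals), ]
  opt <- stats::optim(best_q, f, control = list(maxit = 5000, reltol = 1e-15))
  min(min(vals), opt$value)
}

# exhaustive DCCM by the definition, double loop over residue pairs
brute_force_dccm <- function(disp) {
  n_res <- ncol(disp) / 3
  cmat <- matrix(NA_real_, n_res, n_res)
  for (i in seq_len(n_res)) {
    di <- disp[, (3 * i - 2):(3 * i), drop = FALSE]
    for (j in seq_len(n_res)) {
      dj <- disp[, (3 * j - 2):(3 * j), drop = FALSE]
      num <- sum(di * dj)
      cmat[i, j] <- num / sqrt(sum(di^2) * sum(dj^2))
    }
  }
  cmat
}

# exhaustive mean-min-distance contact map: triple loop frames x pairs x atoms
brute_force_contact_map <- function(ens, selection) {
  groups <- selection$groups
  n_res <- length(groups)
  acc <- matrix(0, n_res, n_res)
  for (t in seq_len(ens$n_frames)) {
    crd <- matrix(ens$xyz[t, ], ncol = 3, byrow = TRUE)
    for (i in seq_len(n_res)) {
      for (j in seq_len(n_res)) {
        if (i == j) next
        best <- Inf
        for (ai in groups[[i]]) {
          for (aj in groups[[j]]) {
            d <- sqrt(sum((crd[ai, ] - crd[aj, ])^2))
            if (d < best) best <- d
          }
        }
        acc[i, j] <- acc[i, j] + best
      }
    }
  }
  acc / ens$n_frames
}

# pairwise-comparison AUC estimator: (wins + 0.5 ties) / (n_a * n_d),
# lower score = predicted active
pairwise_auc <- function(labels, scores) {
  if (is.character(labels)) labels <- labels == "active"
  act <- scores[labels]
  dec <- scores[!labels]
  tot <- 0
  for (a in act) tot <- tot + sum(a < dec) + 0.5 * sum(a == dec)
  tot / (length(act) * length(dec))
}

rigid_move <- function(coords, angle = 0.7, axis = c(0, 0, 1),
                       shift = c(5, -2, 1)) {
  axis <- axis / sqrt(sum(axis^2))
  q <- c(cos(angle / 2), sin(angle / 2) * axis)
  sweep(coords %*% t(quat_to_rot(q)), 2, shift, "+")
}
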