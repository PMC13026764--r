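test_that("centering decomposes coordinates exactly", {
  ref <- make_backbone(6)
  ens <- make_harmonic_ensemble(ref, n_frames = 20, sigma_profile = 0.5,
                                seed = 4)
  sel <- resolve_selection(ens, "calpha")
  ce <- center_ensemble(ens, sel)
  # mean of displacements is zero and mean + disp reconstructs the input
  expect_lt(max(abs(colMeans(ce$disp))), 1e-9)
  recon <- sweep(ce$disp, 2, ce$mean_flat, "+")
  expect_equal(recon, ens$xyz[, ensdyn:::sel_xyz_cols(sel)],
               tolerance = 1e-12)

  const <- conf_ensemble(ref$atom, rbind(ref$xyz, ref$xyz, ref$xyz))
  expect_equal(max(abs(center_ensemble(const)$disp)), 0)
})

test_that("RMSF matches hand values and the isotropic-Gaussian expectation", {
  ref <- make_backbone(4)
  # two frames at +/- d along x for every residue -> RMSF = d exactly
  d <- 0.7
  shift <- rep(c(d, 0, 0), ref$n_atoms)
  ens <- conf_ensemble(ref$atom, rbind(ref$xyz + shift, ref$xyz - shift))
  rmsf <- compute_rmsf(center_ensemble(ens))
  expect_equal(unname(as.numeric(rmsf)), rep(d, 4), tolerance = 1e-12)

  # sigma = 0.5 A per coordinate -> E[RMSF] ~ sigma * sqrt(3)
  big <- make_harmonic_ensemble(make_backbone(20), n_frames = 5000,
                                sigma_profile = 0.5, seed = 8)
  r <- compute_rmsf(center_ensemble(big))
  expect_true(all(abs(as.numeric(r) - 0.5 * sqrt(3)) / (0.5 * sqrt(3)) < 0.03))

  expect_error(compute_rmsf(center_ensemble(
    conf_ensemble(ref$atom, ref$xyz))), "single frame")
})

test_that("a ramped flexibility profile is recovered with high correlation", {
  n_res <- 30
  sigma <- seq(0.2, 1.2, length.out = n_res)
  ens <- make_harmonic_ensemble(make_backbone(n_res), n_frames = 5000,
                                sigma_profile = sigma, seed = 12)
  r <- compute_rmsf(center_ensemble(ens))
  expect_gt(profile_pcc(r, sigma * sqrt(3)), 0.99)
  expect_true(all(abs(as.numeric(r) - sigma * sqrt(3)) / (sigma * sqrt(3)) < 0.05))
})

test_that("profile correlation follows the textbook definition", {
  expect_equal(profile_pcc(1:5, 1:5), 1.0)
  expect_equal(profile_pcc(1:5, -(1:5) + 10), -1.0)
  a <- c(1, 2, 3, 4); b <- c(1, 2, 3, 5)
  # direct summation oracle
  pcc_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(profile_pcc(a, b), pcc_hand)
  expect_equal(round(pcc_hand, 4), 0.9827)
  expect_error(profile_pcc(rep(1, 5), 1:5), "zero variance")
  expect_error(profile_pcc(1:4, 1:5), "length")
})

test_that("DCCM obeys its definition on toys and matches brute force", {
  ref <- make_backbone(4)
  ens <- make_harmonic_ensemble(ref, n_frames = 8, sigma_profile = 0.6,
                                seed = 21)
  ce <- center_ensemble(ens)
  dccm <- compute_dccm(ce)
  expect_equal(unclass(dccm), brute_force_dccm(ce$disp), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(diag(unclass(dccm)), rep(1, 4), ignore_attr = TRUE)
  expect_identical(unclass(dccm), t(unclass(dccm)))

  # identical displacement series -> +1; opposed series -> -1
  disp <- matrix(rnorm(30), ncol = 3)
  xyz <- matrix(rep(make_backbone(3)$xyz, each = 10), nrow = 10)
  cols1 <- 3 * (1:3) - 2  # x of CA atoms not needed; build per-residue moves
  top3 <- make_backbone(3)
  move <- cbind(disp, disp, -disp)  # res2 copies res1, res3 opposes
  xyz <- ensdyn:::expand_to_atoms(top3, move)
  d3 <- compute_dccm(center_ensemble(conf_ensemble(top3$atom, xyz)))
  expect_equal(d3[1, 2], 1, tolerance = 1e-12)
  expect_equal(d3[1, 3], -1, tolerance = 1e-12)
})

test_that("DCCM recovers designed block correlations", {
  n_res <- 30
  blocks <- list(list(a = 3:8, b = 17:22, rho = 0.8))
  ens <- make_harmonic_ensemble(make_backbone(n_res), n_frames = 5000,
                                sigma_profile = 0.5,
                                correlation_blocks = blocks, seed = 31)
  dccm <- compute_dccm(center_ensemble(ens))
  members <- c(3:8, 17:22)
  block_vals <- unclass(dccm)[members, members]
  off_diag <- block_vals[row(block_vals) != col(block_vals)]
  expect_true(all(abs(off_diag - 0.8) < 0.05))
  outside <- setdiff(seq_len(n_res), members)
  indep <- unclass(dccm)[outside, members]
  expect_true(all(abs(indep) < 0.05))
  indep2 <- unclass(dccm)[outside, outside]
  expect_true(all(abs(indep2[row(indep2) != col(indep2)]) < 0.05))
})

test_that("matrix MAE satisfies its identities", {
  m <- pair_matrix(matrix(c(1, .2, .2, 1), 2), "correlation")
  expect_equal(matrix_mae(m, m), 0)
  shifted <- pair_matrix(unclass(m) - 0.15, "correlation")
  expect_equal(matrix_mae(shifted, m), 0.15)
  a <- pair_matrix(matrix(c(0.5, 0.1, 0.1, 0.5), 2), "correlation")
  b <- pair_matrix(unclass(a) + c(0.1, 0.3, 0.3, 0.1), "correlation")
  expect_equal(matrix_mae(b, a), 0.2)
  d <- pair_matrix(matrix(0, 3, 3), "mean_min_distance")
  expect_error(matrix_mae(m, d), "kind")
  expect_error(matrix_mae(m, pair_matrix(diag(3), "correlation")), "shape")
})

test_that("contact maps equal brute force and hand arithmetic", {
  ref <- make_backbone(4, residues = c("ALA", "GLY", "ASP", "LYS"))
  ens <- make_harmonic_ensemble(ref, n_frames = 3, sigma_profile = 0.8,
                                seed = 41)
  sel <- resolve_selection(ens, "backbone_cb")
  cm <- compute_contact_map(ens, sel)
  bf <- brute_force_contact_map(ens, sel)
  expect_equal(unclass(cm), bf, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(unclass(cm), t(unclass(cm)))
  expect_equal(diag(unclass(cm)), rep(0, 4), ignore_attr = TRUE)
  expect_true(all(unclass(cm) >= 0))

  # single frame: mean of one equals that frame's minima
  one <- conf_ensemble(ref$atom, ens$xyz[1, , drop = FALSE])
  expect_equal(unclass(compute_contact_map(one, sel)),
               brute_force_contact_map(one, sel), tolerance = 1e-12,
               ignore_attr = TRUE)

  # two frames with per-pair minima 3.0 and 5.0 -> mean 4.0
  atom2 <- data.frame(elety = c("CA", "CA"), resid = c("ALA", "ALA"),
                      chain = "A", resno = 1:2, elesy = "C")
  two <- conf_ensemble(atom2, rbind(c(0, 0, 0, 3, 0, 0), c(0, 0, 0, 5, 0, 0)))
  cm2 <- compute_contact_map(two, resolve_selection(two, "calpha"))
  expect_equal(cm2[1, 2], 4.0)
})

test_that("triangle combination places each source where documented", {
  a <- pair_matrix(matrix(runif(16, -1, 1), 4) * 0 + diag(4), "correlation")
  up <- ensdyn:::with_seed(1, {
    m <- matrix(runif(16, -1, 1), 4); m <- (m + t(m)) / 2; diag(m) <- 1
    pair_matrix(m, "correlation")
  })
  lo <- ensdyn:::with_seed(2, {
    m <- matrix(runif(16, -1, 1), 4); m <- (m + t(m)) / 2; diag(m) <- 1
    pair_matrix(m, "correlation")
  })
  comb <- combine_triangles(up, lo)
  expect_equal(comb[1, 3], up[1, 3])
  expect_equal(comb[3, 1], lo[3, 1])
  expect_equal(diag(unclass(comb)), diag(unclass(up)), ignore_attr = TRUE)
  # transpose identity off the diagonal
  ba <- combine_triangles(lo, up)
  off <- row(comb) != col(comb)
  expect_equal(t(unclass(comb))[off], unclass(ba)[off])
  # identical inputs give a symmetric display
  same <- combine_triangles(up, up)
  expect_identical(unclass(same), t(unclass(same)))
})
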