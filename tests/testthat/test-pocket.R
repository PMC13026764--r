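test_that("pocket overlap counts covered ligand atoms exactly", {
  lig <- cbind(3 * (1:4), 0, 0)
  expect_equal(pocket_overlap(lig, lig, radius = 1), 1.0)
  half <- lig[1:2, , drop = FALSE]
  expect_equal(pocket_overlap(half, lig, radius = 1), 0.5)
  expect_warning(o <- pocket_overlap(matrix(numeric(0), 0, 3), lig), "empty")
  expect_equal(o, 0)

  # random scene vs brute-force all-pairs check
  grid <- ensdyn:::with_seed(3, matrix(runif(60, 0, 10), ncol = 3))
  ligand <- ensdyn:::with_seed(4, matrix(runif(24, 0, 10), ncol = 3))
  radius <- 1.5
  bf <- mean(vapply(seq_len(nrow(ligand)), function(i) {
    any(sqrt(colSums((t(grid) - ligand[i, ])^2)) <= radius)
  }, logical(1)))
  expect_equal(pocket_overlap(grid, ligand, radius), bf)

  # monotone in radius; invariant under a common rigid motion
  radii <- c(0.5, 1, 2, 4, 8)
  vals <- vapply(radii, function(r) pocket_overlap(grid, ligand, r), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_equal(pocket_overlap(rigid_move(grid), rigid_move(ligand), radius),
               pocket_overlap(grid, ligand, radius))
})

test_that("frame exposure is the max over pockets, 0 when none", {
  lig <- cbind(3 * (1:4), 0, 0)
  p25 <- list(coords = lig[1, , drop = FALSE])
  p75 <- list(coords = lig[1:3, , drop = FALSE])
  expect_equal(frame_exposure(list(p25, p75), lig), 0.75)
  expect_equal(frame_exposure(list(), lig), 0)
  expect_equal(frame_exposure(list(p25), lig),
               pocket_overlap(p25$coords, lig, 1))
})

test_that("adaptive filtering walks the cutoff down as specified", {
  scores <- c(rep(0.55, 60), rep(0.45, 90))
  fr <- adaptive_filter(scores)
  expect_equal(fr$final_cutoff, 0.4, tolerance = 1e-12)
  expect_length(fr$retained, 150)
  expect_equal(fr$trace$cutoff, c(0.5, 0.4), tolerance = 1e-12)
  expect_equal(fr$trace$n_retained, c(60, 150))
  expect_true(all(diff(fr$retained) > 0))
  expect_true(all(scores[fr$retained] >= fr$final_cutoff))

  # first pass already succeeds
  ok <- adaptive_filter(rep(0.9, 500))
  expect_equal(ok$final_cutoff, 0.5)
  expect_length(ok$retained, 500)
  expect_equal(nrow(ok$trace), 1)

  # floor at zero retains everything
  low <- adaptive_filter(rep(0.05, 50))
  expect_equal(low$final_cutoff, 0)
  expect_length(low$retained, 50)
  # trace cutoffs strictly decrease
  expect_true(all(diff(low$trace$cutoff) < 0))
  expect_error(adaptive_filter(numeric(0)), "empty")
})

test_that("pocket atoms are the heavy shell around the ligand", {
  ref <- make_backbone(10)
  crd <- frame_coords(ref, 1)
  # ligand placed on top of atoms 12..18 (within 0.5 A)
  target <- 12:18
  lig <- crd[target, ] + 0.3
  idx <- extract_pocket_atoms(ref, lig, radius = 1)
  bf <- which(vapply(seq_len(nrow(crd)), function(i) {
    min(sqrt(colSums((t(lig) - crd[i, ])^2))) <= 1
  }, logical(1)))
  expect_equal(idx, bf)
  expect_true(all(target %in% idx))

  # nesting in radius
  idx2 <- extract_pocket_atoms(ref, lig, radius = 3)
  expect_true(all(idx %in% idx2))

  far <- crd[1:3, ] + 100
  expect_error(extract_pocket_atoms(ref, far, radius = 1), "larger radius")
})

test_that("clustering separates designed blobs and picks min-energy reps", {
  # five well-separated blobs of 50 frames in a 12-dim coordinate space
  centers <- ensdyn:::with_seed(41, matrix(runif(5 * 12, -50, 50), 5))
  coords <- do.call(rbind, lapply(1:5, function(b) {
    ensdyn:::with_seed(50 + b,
      matrix(rnorm(50 * 12, sd = 0.5), 50, 12) +
        matrix(centers[b, ], 50, 12, byrow = TRUE))
  }))
  truth <- rep(1:5, each = 50)
  energies <- ensdyn:::with_seed(60, runif(250, -15, -5))
  sel <- cluster_and_select(coords, energies, k = 5, seed = 7)
  # 100% purity: each found cluster maps to exactly one true blob
  tab <- table(truth, sel$labels)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
  # representatives minimize energy within their cluster
  for (cl in 1:5) {
    members <- which(sel$labels == cl)
    expect_equal(energies[sel$representatives[cl]], min(energies[members]))
  }
  # determinism given the seed
  sel2 <- cluster_and_select(coords, energies, k = 5, seed = 7)
  expect_identical(sel$labels, sel2$labels)
  expect_identical(sel$representatives, sel2$representatives)

  expect_error(cluster_and_select(coords[1:4, ], energies[1:4], k = 5),
               "fewer frames")
  same <- matrix(1, 10, 6)
  expect_error(cluster_and_select(same, rep(-1, 10), k = 2), "degenerate")
})

test_that("grid files round trip and the full selection pipeline runs", {
  expo <- c(rep(0.5, 60), rep(0.25, 90))
  scene <- make_pocket_scene(expo, n_ligand_atoms = 8, seed = 9)
  dir <- file.path(tempdir(), "ensdyn-grids")
  unlink(dir, recursive = TRUE)
  paths <- write_pocket_grids(scene$grids, dir)
  back <- read_pocket_grids(paths)
  expect_length(back, length(expo))
  expect_equal(exposure_series(back, scene$ligand), expo)
  # energies survive the B-factor column (2 decimal places in PDB)
  e_back <- vapply(back, function(fr) {
    min(vapply(fr, function(p) p$energy, numeric(1)))
  }, numeric(1))
  expect_equal(e_back, pmin(scene$energies, -1), tolerance = 0.005)

  # end-to-end: a protein whose atoms line the ligand within the 1 A shell
  atom8 <- data.frame(elety = "CA", resid = "ALA", chain = "A", resno = 1:8,
                      elesy = "C")
  prot <- conf_ensemble(atom8, matrix(as.vector(t(scene$ligand + 0.3)), 1))
  ens <- make_harmonic_ensemble(prot, n_frames = length(expo),
                                sigma_profile = 0.1, seed = 10)
  res <- pocket_select(ens, scene$grids, scene$ligand,
                       radius = 1, min_retained = 40, k = 3, seed = 2)
  expect_equal(res$filter$final_cutoff, 0.5)
  expect_length(res$filter$retained, 60)
  expect_length(res$selected_frames, 3)
  expect_true(all(res$selected_frames %in% res$filter$retained))
  expect_true(all(res$exposures[res$selected_frames] >= res$filter$final_cutoff))
})

test_that("unrealizable designed exposures are rejected", {
  expect_error(make_pocket_scene(c(0.5, 0.3), n_ligand_atoms = 8),
               "not realizable")
  ok <- make_pocket_scene(c(0, 1), n_ligand_atoms = 4)
  expect_equal(exposure_series(ok$grids, ok$ligand), c(0, 1))
})
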