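test_that("multi-model PDB files parse into validated ensembles", {
  path <- write_toy_multimodel_pdb(tempfile(fileext = ".pdb"), n_models = 3)
  ens <- read_multimodel_pdb(path)
  expect_s3_class(ens, "conf_ensemble")
  expect_equal(ens$n_frames, 3)
  expect_equal(ens$n_atoms, 5)
  expect_equal(residues(ens)$resid, rep("ALA", 5))
  # model offsets preserved: frame 3 sits 1.0 A above frame 1 in z
  expect_equal(frame_coords(ens, 3)[, 3] - frame_coords(ens, 1)[, 3],
               rep(1.0, 5), tolerance = 1e-6)

  single <- write_toy_multimodel_pdb(tempfile(fileext = ".pdb"), n_models = 1)
  expect_equal(read_multimodel_pdb(single)$n_frames, 1)
})

test_that("malformed PDB input is rejected with a located error", {
  bad_model <- write_toy_multimodel_pdb(tempfile(fileext = ".pdb"),
                                        n_models = 3, drop_atom_in_model = 2)
  expect_error(read_multimodel_pdb(bad_model), "model 2")

  p <- tempfile(fileext = ".pdb")
  writeLines(c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
               "ATOM      2  CA", "END"), p)
  expect_error(read_multimodel_pdb(p), "line 2")

  expect_error(read_multimodel_pdb(tempfile(fileext = ".pdb")), "not found")
})

test_that("altloc duplicates resolve to the highest-occupancy copy", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 9, 9, 9, occ = 0.6, alt = "B"),
    pdb_atom_line(3, "CA", "ALA", "A", 2, 3.8, 0, 0),
    pdb_atom_line(4, "CA", "ALA", "A", 3, 7.6, 0, 0),
    "END"), p)
  ens <- read_multimodel_pdb(p)
  expect_equal(ens$n_atoms, 3)
  expect_equal(frame_coords(ens, 1)[1, ], c(9, 9, 9))  # occupancy 0.6 wins
})

test_that("PDB write/read round trip preserves coordinates to file precision", {
  ref <- make_backbone(8, residues = c("ALA", "GLY"))
  ens <- make_harmonic_ensemble(ref, n_frames = 4, sigma_profile = 0.4,
                                seed = 3)
  path <- tempfile(fileext = ".pdb")
  write_multimodel_pdb(ens, path)
  back <- read_multimodel_pdb(path)
  expect_equal(back$n_frames, 4)
  expect_equal(back$atom$elety, ens$atom$elety)
  expect_lt(max(abs(back$xyz - ens$xyz)), 1e-3 + 1e-9)
})

test_that("concatenation pools frames and validates topology", {
  ref <- make_backbone(6)
  parts <- lapply(1:3, function(s) {
    make_harmonic_ensemble(ref, n_frames = 1000, sigma_profile = 0.3, seed = s)
  })
  pooled <- concat_ensembles(parts)
  expect_equal(pooled$n_frames, 3000)
  expect_equal(pooled$xyz[1001, ], parts[[2]]$xyz[1, ])

  expect_identical(concat_ensembles(parts[[1]]), parts[[1]])

  other <- make_backbone(6, residues = c("ALA", "ALA", "ASP", "ALA", "ALA", "ALA"))
  mism <- make_harmonic_ensemble(other, n_frames = 2, seed = 1)
  expect_error(concat_ensembles(parts[[1]], mism), "atom")
})

test_that("named selections resolve the documented atom sets", {
  ref <- make_backbone(10, residues = c(rep("ALA", 4), "GLY", rep("ALA", 5)))
  ca <- resolve_selection(ref, "calpha")
  expect_length(ca$indices, 10)
  expect_true(all(diff(ca$indices) > 0))

  bb <- resolve_selection(ref, "backbone_cb")
  # glycine contributes 4 atoms (no CB), the rest 5
  expect_length(bb$indices, 9 * 5 + 4)
  expect_length(bb$groups[["GLY5"]], 4)

  heavy <- resolve_selection(ref, "heavy")
  expect_equal(heavy$indices, seq_len(ref$n_atoms))

  expect_error(resolve_selection(ref, "sidechain"), "unrecognized")

  no_ca <- conf_ensemble(
    data.frame(elety = c("N", "C"), resid = "ALA", chain = "A",
               resno = c(1, 1), elesy = c("N", "C")),
    matrix(rnorm(6), nrow = 1))
  expect_error(resolve_selection(no_ca, "calpha"), "lacking a CA")
})

test_that("Kabsch superposition recovers exact rigid motions", {
  pts <- ensdyn:::with_seed(5, matrix(rnorm(30, sd = 3), ncol = 3))
  s0 <- kabsch_superpose(pts, pts)
  expect_equal(s0$fit_rmsd, 0, tolerance = 1e-10)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)

  moved <- rigid_move(pts, angle = pi / 2, axis = c(0, 0, 1),
                      shift = c(5, 0, 0))
  s1 <- kabsch_superpose(moved, pts)
  expect_lt(s1$fit_rmsd, 1e-6)
  expect_lt(max(abs(apply_superposition(s1, moved) - pts)), 1e-6)
  expect_equal(det(s1$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch RMSD matches a quaternion-search brute-force minimum", {
  for (s in 1:20) {
    mobile <- ensdyn:::with_seed(100 + s, matrix(rnorm(15, sd = 2), ncol = 3))
    reference <- ensdyn:::with_seed(200 + s, matrix(rnorm(15, sd = 2), ncol = 3))
    k <- kabsch_superpose(mobile, reference)
    oracle <- brute_force_min_rmsd(mobile, reference)
    expect_lt(abs(k$fit_rmsd - oracle), 1e-3)
    expect_lte(k$fit_rmsd, oracle + 1e-9)  # never beaten by the search
    expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  }
})

test_that("degenerate superposition inputs are rejected", {
  expect_error(kabsch_superpose(matrix(rnorm(6), ncol = 3),
                                matrix(rnorm(6), ncol = 3)),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate|rank")
  expect_error(kabsch_superpose(matrix(rnorm(9), ncol = 3),
                                matrix(rnorm(12), ncol = 3)),
               "differ")
})

test_that("ensemble alignment removes rigid motion and is idempotent", {
  ref <- make_backbone(12)
  base <- frame_coords(ref, 1)
  frames <- lapply(1:5, function(i) {
    rigid_move(base, angle = 0.3 * i, axis = c(1, i, 0), shift = c(i, -i, 2))
  })
  ens <- conf_ensemble(ref$atom,
                       do.call(rbind, lapply(frames, function(f) as.vector(t(f)))))
  aligned <- align_ensemble(ens, base)
  for (t in 1:5) {
    expect_lt(max(abs(frame_coords(aligned, t) - base)), 1e-6)
  }

  wob <- make_harmonic_ensemble(ref, n_frames = 10, sigma_profile = 0.5, seed = 2)
  a1 <- align_ensemble(wob, base)
  a2 <- align_ensemble(a1, base)
  expect_lt(max(abs(a2$xyz - a1$xyz)), 1e-9)

  # fitting never increases the RMSD to the reference
  sel <- resolve_selection(wob, "calpha")
  for (t in 1:10) {
    raw <- coord_rmsd(ensdyn:::sel_coords(wob, sel, t),
                      base[sel$indices, ])
    fit <- coord_rmsd(ensdyn:::sel_coords(a1, sel, t),
                      base[sel$indices, ])
    expect_lte(fit, raw + 1e-9)
  }
})

test_that("no rotation in a random sample beats the Kabsch optimum", {
  mobile <- ensdyn:::with_seed(9, matrix(rnorm(21, sd = 2), ncol = 3))
  reference <- ensdyn:::with_seed(10, matrix(rnorm(21, sd = 2), ncol = 3))
  k <- kabsch_superpose(mobile, reference)
  a <- sweep(mobile, 2, colMeans(mobile))
  b <- sweep(reference, 2, colMeans(reference))
  qs <- matrix(ensdyn:::with_seed(11, rnorm(4000)), ncol = 4)
  rmsds <- apply(qs, 1, function(q) {
    sqrt(sum((a %*% t(quat_to_rot(q)) - b)^2) / nrow(a))
  })
  expect_true(all(rmsds >= k$fit_rmsd - 1e-12))
})
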