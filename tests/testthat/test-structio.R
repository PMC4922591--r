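test_that("PDB read/write round-trips coordinates, numbering and models", {
  s <- make_chain(3, "helix", seed = 2)
  expect_equal(n_residues(s), 3)
  expect_equal(nrow(s$atoms), 15)

  p1 <- tempfile(fileext = ".pdb")
  write_pdb(s, p1)
  r1 <- read_pdb(p1)
  expect_equal(coords(r1), coords(s), tolerance = 1e-3)
  expect_equal(r1$atoms$resno, s$atoms$resno)
  expect_equal(r1$atoms$elety, s$atoms$elety)

  # idempotence at PDB precision: second round-trip is exact
  p2 <- tempfile(fileext = ".pdb")
  write_pdb(r1, p2)
  r2 <- read_pdb(p2)
  expect_identical(coords(r2), coords(r1))

  # author numbering survives byte-for-byte
  s2 <- enx_structure(transform(s$atoms, resno = resno + 41L))
  p3 <- tempfile(fileext = ".pdb")
  write_pdb(s2, p3)
  expect_true(all(grepl(" 4[234] ", grep("^ATOM", readLines(p3),
                                         value = TRUE))))

  # ensembles: 3 conformers -> 3 MODEL blocks, read back by index
  ens <- list(s, perturb(s, 0.3, 7), perturb(s, 0.3, 8))
  p4 <- tempfile(fileext = ".pdb")
  write_pdb(ens, p4)
  expect_equal(sum(grepl("^MODEL", readLines(p4))), 3)
  expect_equal(coords(read_pdb(p4, model_index = 2)),
               coords(ens[[2]]), tolerance = 1e-3)
  expect_error(read_pdb(p4, model_index = 4), "out of range")
})

test_that("alternate locations resolve to the highest occupancy", {
  path <- write_mini_pdb(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      4  C   ALA A   1       3.000   0.000   0.000  1.00  0.00           C",
    "END"))
  s <- read_pdb(path)
  ca <- s$atoms[s$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$x, 2.0)  # B has occupancy 0.60

  # tie on occupancy: label order wins (A kept)
  path2 <- write_mini_pdb(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.50  0.00           C",
    "END"))
  s2 <- read_pdb(path2)
  expect_equal(nrow(s2$atoms), 1)
  expect_equal(s2$atoms$x, 1.0)
})

test_that("coarse graining takes heavy-atom means per residue", {
  # single heavy atom
  one <- enx_structure(data.frame(
    eleno = 1L, elety = "CA", elesy = "C", resid = "GLY", chain = "A",
    resno = 1L, insert = "", x = 1, y = 2, z = 3))
  expect_equal(coarse_grain(one)$centroids[1, ], c(1, 2, 3))

  # two heavy atoms + a hydrogen that must not contribute
  two <- enx_structure(data.frame(
    eleno = 1:3, elety = c("CA", "CB", "HA"), elesy = c("C", "C", "H"),
    resid = "ALA", chain = "A", resno = 1L, insert = "",
    x = c(0, 2, 50), y = 0, z = 0))
  expect_equal(coarse_grain(two)$centroids[1, ], c(1, 0, 0))

  # glycine backbone: centroid equals the hand-summed arithmetic mean
  gly_xyz <- rbind(N = c(1.20, 0.10, -0.30), CA = c(2.44, 0.85, -0.10),
                   C = c(3.60, 0.00, 0.40), O = c(3.55, -1.20, 0.60))
  gly <- enx_structure(data.frame(
    eleno = 1:4, elety = rownames(gly_xyz), elesy = c("N", "C", "C", "O"),
    resid = "GLY", chain = "A", resno = 5L, insert = "",
    x = gly_xyz[, 1], y = gly_xyz[, 2], z = gly_xyz[, 3]))
  hand_mean <- c((1.20 + 2.44 + 3.60 + 3.55) / 4,
                 (0.10 + 0.85 + 0.00 - 1.20) / 4,
                 (-0.30 - 0.10 + 0.40 + 0.60) / 4)
  expect_equal(coarse_grain(gly)$centroids[1, ], hand_mean)

  # membership partitions all atoms
  s <- make_chain(6, seed = 3)
  cg <- coarse_grain(s)
  expect_equal(unname(sort(unlist(cg$membership))),
               seq_len(nrow(s$atoms)))
})

test_that("superposition is optimal, proper and matches external oracles", {
  s <- get_hinge(1)$open

  sp <- superpose(s, s)
  expect_equal(sp$rmsd, 0, tolerance = 1e-8)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-6)

  # rigid-motion invariance and recovery
  m <- random_rigid(s, seed = 11)
  sp2 <- superpose(m, s)
  expect_equal(sp2$rmsd, 0, tolerance = 1e-6)
  expect_equal(det(sp2$rotation), 1, tolerance = 1e-8)
  back <- apply_superposition(m, sp2)
  expect_equal(coords(back), coords(s), tolerance = 1e-6)

  # 4-point toy sets against the brute-force rotational search
  a <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  b <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 2))
  expect_equal(enmexplore:::.kabsch(a, b)$rmsd, brute_force_rmsd(a, b),
               tolerance = 1e-5)

  # compiled quaternion path == base-svd reference == bio3d, on noisy sets
  for (seed in 1:5) {
    x <- enmexplore:::.with_seed(seed, matrix(stats::rnorm(60), ncol = 3))
    y <- x + enmexplore:::.with_seed(seed + 50,
                                     matrix(stats::rnorm(60, 0, 0.7),
                                            ncol = 3))
    r_cpp <- enmexplore:::.kabsch(x, y)
    r_svd <- enmexplore:::.kabsch_svd(x, y)
    expect_equal(r_cpp$rmsd, r_svd$rmsd, tolerance = 1e-8)
    expect_equal(r_cpp$rotation, r_svd$rotation, tolerance = 1e-6)
    r_bio3d <- bio3d::rmsd(as.vector(t(x)), as.vector(t(y)),
                           fit = TRUE)
    expect_equal(r_cpp$rmsd, r_bio3d, tolerance = 1e-3)
  }
})

test_that("CA RMSD is a symmetric, rigid-invariant metric", {
  hf <- get_hinge(1)
  a <- hf$open; b <- hf$closed
  expect_equal(rmsd_ca(a, a), 0, tolerance = 1e-8)
  expect_equal(rmsd_ca(a, b), rmsd_ca(b, a), tolerance = 1e-8)
  for (seed in c(3, 4)) {
    expect_equal(rmsd_ca(random_rigid(a, seed), b), rmsd_ca(a, b),
                 tolerance = 1e-6)
    expect_equal(rmsd_ca(a, random_rigid(b, seed)), rmsd_ca(a, b),
                 tolerance = 1e-6)
  }

  # fitted RMSD never exceeds the raw displacement RMSD
  for (seed in 5:7) {
    p <- perturb(a, 1.5, seed)
    raw <- deformation_rmsd(a, p)
    expect_lte(rmsd_ca(a, p), raw + 1e-10)
  }

  # known displacement field, cross-checked by brute force
  ca_a <- ca_coords(a)
  disp <- enmexplore:::.with_seed(21, matrix(stats::rnorm(length(ca_a),
                                                          0, 0.8),
                                             ncol = 3))
  shifted <- a
  mat <- coords(a)
  mat[a$atoms$elety == "CA", ] <- ca_a + disp
  shifted <- set_coords(a, mat)
  expect_equal(rmsd_ca(a, shifted),
               brute_force_rmsd(ca_a + disp, ca_a), tolerance = 1e-4)

  # pairing is by author numbering; disjoint sets error
  off <- enx_structure(transform(a$atoms, resno = resno + 500L))
  expect_error(rmsd_ca(a, off), "common")
})

test_that("radius of gyration matches the direct formula and is rigid-invariant", {
  # single CA -> 0
  one <- enx_structure(data.frame(
    eleno = 1L, elety = "CA", elesy = "C", resid = "GLY", chain = "A",
    resno = 1L, insert = "", x = 4, y = 5, z = 6))
  expect_equal(radius_of_gyration(one), 0)

  # two CA at distance 2 -> 1
  two <- enx_structure(data.frame(
    eleno = 1:2, elety = "CA", elesy = "C", resid = "GLY", chain = "A",
    resno = 1:2, insert = "", x = c(0, 2), y = 0, z = 0))
  expect_equal(radius_of_gyration(two), 1.0)

  # 10-residue helix vs hand-computed formula
  s <- make_chain(10, "helix", seed = 4)
  ca <- ca_coords(s)
  expect_equal(radius_of_gyration(s),
               sqrt(sum(sweep(ca, 2, colMeans(ca))^2) / nrow(ca)))
  expect_equal(radius_of_gyration(random_rigid(s, 9)),
               radius_of_gyration(s), tolerance = 1e-8)

  # per-chain RG on a two-chain structure
  b <- s$atoms; b$chain <- "B"; b$eleno <- b$eleno + 100L
  b[, c("x", "y", "z")] <- b[, c("x", "y", "z")] + 30
  both <- enx_structure(rbind(s$atoms, b))
  expect_equal(unname(rg_by_chain(both)["A"]), radius_of_gyration(s))
  expect_equal(radius_of_gyration(both, chains = "B"),
               radius_of_gyration(s), tolerance = 1e-8)
})
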