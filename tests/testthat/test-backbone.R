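# Backbone I/O and geometry

test_that("PDB read converts Angstrom to nm and filters incomplete/non-standard residues", {
  pdb <- c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.000   2.000   3.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       3.000   2.500   3.000  1.00  0.00           C",
    "ATOM      4  N   GLY A   2       4.300   2.500   3.000  1.00  0.00           N",
    "ATOM      5  CA  GLY A   2       5.300   2.900   3.000  1.00  0.00           C",
    "ATOM      6  C   GLY A   2       6.300   3.400   3.000  1.00  0.00           C",
    "END")
  s <- read_backbone(pdb)
  expect_equal(n_res(s), 2L)
  expect_equal(s$sequence, c("A", "G"))
  expect_equal(s$coords[1, 1, ], c(0.1, 0.2, 0.3))  # Angstrom/10
  expect_equal(s$coords[2, 3, ], c(0.63, 0.34, 0.3))

  # an ACE cap record is excluded from the output sequence
  cap <- c(
    "ATOM      0  C   ACE A   0       0.000   2.000   3.000  1.00  0.00           C",
    pdb)
  s2 <- read_backbone(cap)
  expect_equal(s2$sequence, c("A", "G"))

  # a residue missing its C atom is dropped with a warning
  incomplete <- c(pdb[1:6],
    "ATOM      7  N   ALA A   3       7.600   3.400   3.000  1.00  0.00           N",
    "ATOM      8  CA  ALA A   3       8.600   3.800   3.000  1.00  0.00           C",
    "END")
  expect_warning(s3 <- read_backbone(incomplete), "missing")
  expect_equal(n_res(s3), 2L)
})

test_that("malformed and empty PDB inputs raise errors", {
  expect_error(read_backbone("this is not a pdb"), "malformed|no ATOM")
  expect_error(read_backbone(
    "ATOM      1  ZN  XYZ A   1       1.000   2.000   3.000  1.00  0.00          ZN"),
    "no standard|malformed")
})

test_that("write/read round trip preserves coordinates to PDB precision", {
  s <- fix_mixed()
  s2 <- read_backbone(write_backbone(s))
  expect_equal(n_res(s2), n_res(s))
  expect_lt(max(abs(atom_matrix(s) - atom_matrix(s2))), 1e-4)
  # model framing
  txt <- write_backbone(s, model_index = 2)
  expect_match(txt, "MODEL        2")
  expect_match(txt, "ENDMDL")
  # chain filter keeps all residues of the only chain
  s3 <- read_backbone(write_backbone(s), chain = s$chain_id)
  expect_equal(n_res(s3), n_res(s))
})

test_that("multi-model trajectories round-trip through PDB text", {
  frames <- list(fix_helix(6), rigid_move(fix_helix(6), t = c(1, 0, 0)))
  txt <- write_trajectory(frames)
  back <- read_backbone_models(txt)
  expect_length(back, 2L)
  expect_lt(max(abs(atom_matrix(frames[[2]]) - atom_matrix(back[[2]]))), 1e-4)
})

test_that("kabsch_rmsd: identity, rigid invariance, symmetry and masks", {
  s <- fix_mixed()
  expect_equal(kabsch_rmsd(s, s), 0)
  set.seed(4)
  moved <- rigid_move(s)
  expect_lt(kabsch_rmsd(s, moved), 1e-9)
  # symmetry and invariance to motions of either argument
  s2 <- fix_mixed(seed = 9)
  expect_equal(kabsch_rmsd(s, s2), kabsch_rmsd(s2, s), tolerance = 1e-12)
  expect_equal(kabsch_rmsd(rigid_move(s), s2), kabsch_rmsd(s, s2), tolerance = 1e-9)
  # residue-level mask expands to atoms
  mask <- rep(c(TRUE, FALSE), length.out = n_res(s))
  expect_silent(kabsch_rmsd(s, s2, atom_mask = mask))
  expect_error(kabsch_rmsd(s, s2, atom_mask = c(TRUE, FALSE)), "mask")
  expect_error(kabsch_rmsd(s, fix_helix(20)), "different")
})

test_that("kabsch_rmsd matches a brute-force rotation-grid oracle on a 4-point toy", {
  P <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0.4, 0.4, 0.8), 4, 3, byrow = TRUE)
  set.seed(11)
  Q <- P %*% random_rotation() + matrix(rnorm(3), 4, 3, byrow = TRUE)
  Q <- Q + matrix(rnorm(12, sd = 0.05), 4, 3)  # distortions so RMSD > 0
  got <- kabsch_rmsd(P, Q)
  # oracle: grid search over Euler angles after centering
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rot <- function(a, b, c) {
    Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rz2
  }
  # zooming grid search over Euler angles
  ctr <- c(pi, pi / 2, pi); width <- c(pi, pi / 2, pi); best <- Inf
  for (round in 1:6) {
    ga <- seq(ctr[1] - width[1], ctr[1] + width[1], length.out = 13)
    gb <- seq(max(ctr[2] - width[2], 0), min(ctr[2] + width[2], pi), length.out = 13)
    gc <- seq(ctr[3] - width[3], ctr[3] + width[3], length.out = 13)
    for (a in ga) for (b in gb) for (cc in gc) {
      r <- sqrt(mean(rowSums((Pc - Qc %*% t(rot(a, b, cc)))^2)))
      if (r < best) { best <- r; ctr <- c(a, b, cc) }
    }
    width <- width / 5
  }
  expect_lt(got, best + 1e-9)  # optimal is at least as good as any grid point
  expect_equal(got, best, tolerance = 1e-4)
  # cross-check against bio3d's fitted RMSD (Angstrom world, rounded to 1e-3 A)
  b3 <- bio3d::rmsd(as.vector(t(P * 10)), as.vector(t(Q * 10)), fit = TRUE)
  expect_lt(abs(got * 10 - b3), 6e-4)
})

test_that("backbone dihedrals recover builder inputs and match bio3d", {
  s <- build_from_dihedrals(rep("A", 8), rep(-57, 8), rep(-47, 8))
  dh <- backbone_dihedrals(s)
  expect_true(is.na(dh$phi[1]) && is.na(dh$psi[8]))
  expect_lt(max(abs(dh$phi[-1] + 57)), 1e-6)
  expect_lt(max(abs(dh$psi[-8] + 47)), 1e-6)
  # independent torsion check on raw coordinates (first phi)
  xyz <- c(t(rbind(s$coords[1, 3, ], s$coords[2, 1, ], s$coords[2, 2, ], s$coords[2, 3, ])))
  expect_equal(dh$phi[2], bio3d::torsion.xyz(xyz), tolerance = 1e-9,
               ignore_attr = TRUE)
  # planar zigzag: all atoms in a plane gives psi = +-180
  z <- build_from_dihedrals(rep("G", 6), rep(180, 6), rep(180, 6))
  dz <- backbone_dihedrals(z)
  expect_lt(max(abs(abs(dz$psi[-6]) - 180)), 1e-6)
})

test_that("O/H reconstruction obeys ideal geometry and flags undefined sites", {
  pr <- make_protein(list(segment_spec("helix", 4),
                          segment_spec("strand", 3, sequence = c("P", "A", "A"))),
                     seed = 1)
  e <- reconstruct_O_H(pr$structure)
  n <- n_res(e)
  # C=O bond lengths exactly 0.123 nm where defined
  for (i in which(e$o_defined))
    expect_equal(vnorm(e$O[i, ] - e$coords[i, 3, ]), 0.123, tolerance = 1e-6)
  for (i in which(e$h_defined))
    expect_equal(vnorm(e$H[i, ] - e$coords[i, 1, ]), 0.100, tolerance = 1e-6)
  # trans-peptide O-C-N(i+1) angle near 123 degrees
  i <- 2
  u <- e$O[i, ] - e$coords[i, 3, ]; v <- e$coords[i + 1, 1, ] - e$coords[i, 3, ]
  ang <- acos(sum(u * v) / (vnorm(u) * vnorm(v))) * 180 / pi
  expect_equal(ang, 123, tolerance = 2)
  # flags: last O, first H, proline H (residue 5) undefined
  expect_false(e$o_defined[n])
  expect_false(e$h_defined[1])
  expect_false(e$h_defined[5])
  expect_error(reconstruct_O_H(backbone("A", array(0, c(1, 3, 3)))), "2 residues")
})

test_that("O/H reconstruction is equivariant under rigid motions", {
  s <- fix_helix(8)
  e <- reconstruct_O_H(s)
  set.seed(5)
  R <- random_rotation(); tr <- rnorm(3)
  e2 <- reconstruct_O_H(rigid_move(s, R, tr))
  O_moved <- sweep(e$O %*% R, 2, tr, "+")
  H_moved <- sweep(e$H %*% R, 2, tr, "+")
  expect_lt(max(abs(e2$O - O_moved), na.rm = TRUE), 1e-9)
  expect_lt(max(abs(e2$H - H_moved), na.rm = TRUE), 1e-9)
})

test_that("chain-continuity validation warns on broken chains", {
  s <- fix_helix(6)
  bad <- s$coords
  bad[4, , ] <- bad[4, , ] + 5  # translate one residue far away
  expect_warning(backbone(s$sequence, bad, validate = TRUE), "0.20")
  expect_silent(backbone(s$sequence, s$coords, validate = TRUE))
})
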