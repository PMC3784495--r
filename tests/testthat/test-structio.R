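test_that("multi-model PDB round trip preserves frame and atom counts", {
  frames <- lapply(1:3, function(m) matrix(rnorm(15, sd = 5), 5, 3))
  path <- write_mm_pdb(frames)
  traj <- read_trajectory(path, "pdb_multimodel", dt = 2)
  expect_equal(n_frames(traj), 3)
  expect_equal(n_atoms(traj), 5)
  expect_equal(traj$dt, 2)
  # coordinates survive the fixed-width format to 1e-3
  expect_equal(traj$xyz[2, ], as.vector(t(frames[[2]])),
               tolerance = 1e-3, ignore_attr = TRUE)
  # writer round trip
  out <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(traj, out, scores = rep(1500, 5))  # clipped B
  traj2 <- read_trajectory(out, "pdb_multimodel", dt = 2)
  expect_equal(traj2$xyz, traj$xyz, tolerance = 1e-6)
})

test_that("table trajectories read with 3 columns per atom", {
  xyz <- matrix(rnorm(600), 100, 6)
  path <- tempfile(fileext = ".tsv")
  tr0 <- trajectory_ensemble(xyz, dt = 1)
  write_trajectory_table(tr0, path)
  traj <- read_trajectory(path, "table", dt = 1)
  expect_equal(n_frames(traj), 100)
  expect_equal(n_atoms(traj), 2)
  expect_equal(traj$xyz, xyz, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("degenerate PDB inputs raise shape/parse errors", {
  frames <- list(matrix(rnorm(15), 5, 3), matrix(rnorm(12), 4, 3))
  expect_error(read_trajectory(write_mm_pdb(frames), "pdb_multimodel"),
               "inconsistent atom counts")
  p <- tempfile(fileext = ".pdb")
  writeLines(c("MODEL 1", "ATOM      1  CA", "ENDMDL"), p)
  expect_error(read_trajectory(p, "pdb_multimodel"), "line 2")
})

test_that("superposition removes rigid motion and is idempotent", {
  set.seed(7)
  ref_coords <- matrix(rnorm(30, sd = 6), 10, 3)
  ref <- structure_model(as.vector(t(ref_coords)))
  frames <- lapply(1:4, function(i)
    ref_coords %*% t(random_rotation()) +
      matrix(rnorm(3, sd = 4), 10, 3, byrow = TRUE))
  traj <- traj_from_frames(frames)
  fit <- superpose(traj, ref)
  expect_lt(max(attr(fit, "rmsd")$after), 1e-9)
  # already aligned: unchanged
  again <- superpose(fit, ref)
  expect_equal(again$xyz, fit$xyz, tolerance = 1e-9)
  # per-frame RMSD never increases
  noisy <- traj_from_frames(lapply(frames, function(f)
    f + matrix(rnorm(30, sd = 0.3), 10, 3)))
  fit2 <- superpose(noisy, ref)
  expect_true(all(attr(fit2, "rmsd")$after <=
                    attr(fit2, "rmsd")$before + 1e-12))
  # collinear selection is underdetermined
  line <- structure_model(as.vector(t(cbind(1:5, 0, 0))))
  ltraj <- traj_from_frames(list(cbind(1:5, 0, 0)))
  expect_error(superpose(ltraj, line), "collinear")
})

test_that("superposed RMSD matches a rotation-search oracle", {
  set.seed(11)
  ref_coords <- matrix(rnorm(30, sd = 5), 10, 3)
  frame <- matrix(rnorm(30, sd = 5), 10, 3)
  traj <- traj_from_frames(list(frame))
  fit <- superpose(traj, structure_model(as.vector(t(ref_coords))))
  kabsch_rmsd <- attr(fit, "rmsd")$after
  # oracle: center both, minimize RMSD over Euler angles numerically
  a <- scale(frame, scale = FALSE)
  b <- scale(ref_coords, scale = FALSE)
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  }
  f <- function(ang) sqrt(mean(rowSums((a %*% t(rot(ang)) - b)^2)))
  grid <- as.matrix(expand.grid(a1 = seq(0, 2 * pi, length.out = 7),
                                a2 = seq(0, pi, length.out = 4),
                                a3 = seq(0, 2 * pi, length.out = 7)))
  vals <- apply(grid, 1, f)
  best <- optim(grid[which.min(vals), ], f)$value
  expect_equal(kabsch_rmsd, best, tolerance = 1e-3)
})

test_that("torsion angles follow the IUPAC convention", {
  # planar cis: 0 degrees
  cis <- matrix(c(1, 1, 0, 0, 0, 0, 1, 0, 0, 2, 1, 0), 4, 3, byrow = TRUE)
  # planar trans: 180 degrees
  trans <- matrix(c(1, 1, 0, 0, 0, 0, 1, 0, 0, 2, -1, 0), 4, 3,
                  byrow = TRUE)
  # right-handed quarter twist: +90
  twist <- matrix(c(1, 1, 0, 0, 0, 0, 1, 0, 0, 2, 0, 1), 4, 3,
                  byrow = TRUE)
  traj <- traj_from_frames(list(cis, trans, twist, cis))
  ang <- dihedral_series(traj, 1:4)$angles
  expect_equal(ang[1], 0, tolerance = 1e-9)
  expect_equal(ang[2], 180, tolerance = 1e-9)
  expect_equal(ang[3], 90, tolerance = 1e-9)
  # invariance under rigid motion of all frames
  set.seed(3)
  R <- random_rotation(); tvec <- rnorm(3)
  moved <- traj_from_frames(lapply(list(cis, trans, twist, cis),
    function(f) f %*% t(R) + matrix(tvec, 4, 3, byrow = TRUE)))
  expect_equal(dihedral_series(moved, 1:4)$angles, ang,
               tolerance = 1e-9)
  # collinear triple is a geometry error naming the frame
  bad <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0, 3, 1, 0), 4, 3,
                byrow = TRUE)
  expect_error(dihedral_series(traj_from_frames(list(cis, bad, cis, cis)),
                               1:4), "frame 2")
})

test_that("distance series match per-frame norms and survive fitting", {
  frames <- list(matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE),
                 matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE),
                 matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE),
                 matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE))
  traj <- traj_from_frames(frames)
  expect_equal(distance_series(traj, c(1, 2))$values, rep(1, 4))
  expect_equal(distance_series(traj, c(1, 1))$values, rep(0, 4))
  set.seed(2)
  rnd <- lapply(1:5, function(i) matrix(rnorm(12), 4, 3))
  rtraj <- traj_from_frames(rnd)
  d <- distance_series(rtraj, c(2, 4))$values
  oracle <- vapply(rnd, function(f) sqrt(sum((f[2, ] - f[4, ])^2)), 0)
  expect_equal(d, oracle, tolerance = 1e-12)
  # invariant under superposition
  ref <- structure_model(as.vector(t(rnd[[1]])))
  fit <- superpose(rtraj, ref)
  expect_equal(distance_series(fit, c(2, 4))$values, d,
               tolerance = 1e-9)
})

test_that("polar pair detection honors cutoff, occupancy and exclusions", {
  lab <- data.frame(chain = "A", resno = c(1, 5), resid = "SER",
                    elety = c("OG", "OG"), stringsAsFactors = FALSE)
  at <- function(dists) traj_from_frames(lapply(dists, function(d)
    matrix(c(0, 0, 0, d, 0, 0), 2, 3, byrow = TRUE)), labels = lab)
  close4 <- at(rep(2.8, 4))
  expect_equal(nrow(polar_pairs(close4)), 1)
  far4 <- at(rep(5.0, 4))
  expect_equal(nrow(polar_pairs(far4)), 0)
  # 40% occupancy below the 0.5 threshold
  mixed <- at(c(2.8, 2.8, 5, 5, 5))
  expect_equal(nrow(polar_pairs(mixed)), 0)
  # backbone N-O of adjacent residues excluded (peptide bond)
  lab2 <- data.frame(chain = "A", resno = c(1, 2), resid = "ALA",
                     elety = c("O", "N"), stringsAsFactors = FALSE)
  pep <- traj_from_frames(lapply(1:4, function(i)
    matrix(c(0, 0, 0, 2.9, 0, 0), 2, 3, byrow = TRUE)), labels = lab2)
  expect_equal(nrow(polar_pairs(pep)), 0)
  # no polar atoms -> warning and empty result
  lab3 <- data.frame(chain = "A", resno = 1:2, resid = "ALA",
                     elety = c("CA", "CB"), stringsAsFactors = FALSE)
  apolar <- traj_from_frames(list(matrix(rnorm(6), 2, 3)), labels = lab3)
  expect_warning(pp <- polar_pairs(apolar), "no polar")
  expect_equal(nrow(pp), 0)
})

test_that("displacement fields are exact and antisymmetric", {
  set.seed(4)
  base <- matrix(rnorm(12, sd = 5), 4, 3)
  A <- structure_model(as.vector(t(base)))
  expect_equal(displacement_field(A, A)$magnitudes, rep(0, 4))
  # shift one atom by 2 A, align on the others
  shifted <- base; shifted[2, ] <- shifted[2, ] + c(2, 0, 0)
  B <- structure_model(as.vector(t(shifted)))
  df <- displacement_field(A, B, align_selection = c(1, 3, 4))
  expect_equal(df$magnitudes[2], 2, tolerance = 1e-9)
  expect_lt(max(df$magnitudes[c(1, 3, 4)]), 1e-9)
  # a pure translation is removed by the superposition
  C <- structure_model(as.vector(t(base +
    matrix(c(1, 0, 0), 4, 3, byrow = TRUE))))
  expect_lt(max(displacement_field(A, C)$magnitudes), 1e-9)
  # antisymmetry
  fwd <- displacement_field(A, B, align_selection = c(1, 3, 4))
  rev <- displacement_field(B, A, align_selection = c(1, 3, 4))
  expect_equal(fwd$vectors, -rev$vectors, tolerance = 1e-8)
  expect_equal(fwd$magnitudes, rev$magnitudes, tolerance = 1e-8)
  expect_error(displacement_field(list(), A), "empty")
})
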