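test_that("trajectory PCA recovers directions and conserves variance", {
  set.seed(41)
  t_ <- rnorm(200)
  X <- cbind(t_, t_)  # points on the diagonal
  p <- traj_pca(X)
  expect_equal(abs(p$vectors[, 1]), c(1, 1) / sqrt(2), tolerance = 1e-9)
  expect_equal(p$values[2], 0, tolerance = 1e-9)
  # trace identity on random data
  Y <- matrix(rnorm(300), 50, 6)
  py <- traj_pca(Y)
  expect_equal(sum(py$values), sum(apply(Y, 2, var)), tolerance = 1e-9)
  expect_equal(crossprod(py$vectors), diag(6), tolerance = 1e-9,
               ignore_attr = TRUE)
  # isotropic noise: leading eigenvalues comparable
  Z <- matrix(rnorm(4000), 2000, 2)
  pz <- traj_pca(Z)
  expect_lt(pz$values[1] / pz$values[2], 1.3)
  # deterministic sign: largest-magnitude loading positive
  expect_true(all(apply(py$vectors, 2, function(v)
    v[which.max(abs(v))] > 0)))
})

test_that("subspace projection filters exactly what the eigenvalues say", {
  set.seed(43)
  X <- matrix(rnorm(600), 100, 6)
  p <- traj_pca(X)
  # full-dimension projection is the identity
  expect_equal(project_reconstruct(X, p, 6), X, tolerance = 1e-9,
               ignore_attr = TRUE)
  # rank-1 data recovered exactly with m = 1
  t_ <- rnorm(100)
  R1 <- outer(t_, c(1, 2, 3))
  expect_equal(project_reconstruct(R1, traj_pca(R1), 1), R1,
               tolerance = 1e-9, ignore_attr = TRUE)
  # residual sum of squares equals the discarded eigenvalue mass
  Xh <- project_reconstruct(X, p, 2)
  expect_equal(sum((X - Xh)^2), sum(p$values[3:6]) * (100 - 1),
               tolerance = 1e-6)
  expect_error(project_reconstruct(X, p, 7), "out of range")
})

test_that("in-phase summaries turn reconstructions into displacements", {
  n <- 400; k <- 10; phi0 <- 0.9
  tt <- 0:(n - 1)
  base <- cos(2 * pi * k * tt / n + phi0)
  # 2 atoms, shared phase, planted per-coordinate amplitudes
  alpha <- c(0.5, 1, 0, 2, 0.3, 1.2)
  recon <- outer(base, alpha)
  s <- inphase_summary(recon, k, forcing_phase = phi0)
  expect_equal(s$R,
               2 * sqrt(c(sum(alpha[1:3]^2), sum(alpha[4:6]^2))),
               tolerance = 1e-9)
  expect_equal(s$explained, 1, tolerance = 1e-9)
  expect_equal(s$phase, 0, tolerance = 1e-9)
  # amplitudes are invariant to the global sign of the eigenvector
  s2 <- inphase_summary(-recon, k, forcing_phase = phi0)
  expect_equal(s2$R, s$R, tolerance = 1e-9)
  # anti-phase equal-amplitude atoms: opposite-sign loadings, rank 1
  anti <- cbind(base, 0, 0, -base, 0, 0)
  sa <- inphase_summary(anti, k, forcing_phase = phi0)
  expect_equal(sa$explained, 1, tolerance = 1e-9)
  expect_equal(sa$p[1] * sa$p[4], -0.5, tolerance = 1e-9)
  # mixed phases: explained fraction from the 2x2 closed form
  mix <- cbind(base, 0, 0,
               cos(2 * pi * k * tt / n + phi0 + pi / 4), 0, 0)
  sm <- inphase_summary(mix, k, forcing_phase = phi0)
  expect_lt(sm$explained, 1)
  expect_equal(sm$explained, (1 + cos(pi / 4)) / 2, tolerance = 1e-9)
  expect_error(inphase_summary(matrix(0, 10, 6), k), "all-zero")
})

test_that("overlap and correlation behave as geometric similarity", {
  set.seed(47)
  d <- matrix(rnorm(30), 10, 3)
  df <- structure(list(vectors = d, magnitudes = sqrt(rowSums(d^2)),
                       selection = 1:10), class = "displacement_field")
  v <- as.vector(t(d))
  expect_equal(overlap(df, 2 * v), 1, tolerance = 1e-12)
  expect_equal(overlap(df, -v), 1, tolerance = 1e-12)  # absolute cosine
  # orthogonal direction
  w <- rnorm(30); w <- w - sum(w * v) / sum(v * v) * v
  expect_equal(overlap(df, w), 0, tolerance = 1e-9)
  # 45-degree construction
  u <- v / sqrt(sum(v^2)) + w / sqrt(sum(w^2))
  expect_equal(overlap(df, u), 1 / sqrt(2), tolerance = 1e-9)
  expect_error(overlap(structure(list(vectors = d * 0,
                                      magnitudes = rep(0, 10),
                                      selection = 1:10),
                                 class = "displacement_field"), v),
               "zero-norm")
  # subspace overlap: in-span 1, orthogonal 0, m = 1 consistency
  Q <- qr.Q(qr(matrix(rnorm(30 * 3), 30, 3)))
  inside <- as.numeric(Q %*% c(1, 2, -1))
  expect_equal(subspace_overlap(inside, Q), 1, tolerance = 1e-9)
  out <- rnorm(30); out <- out - Q %*% (t(Q) %*% out)
  expect_equal(subspace_overlap(as.numeric(out), Q), 0, tolerance = 1e-9)
  expect_equal(subspace_overlap(v, Q[, 1, drop = FALSE]),
               overlap(df, Q[, 1]), tolerance = 1e-12)
  # non-decreasing in m
  o <- vapply(1:3, function(m)
    subspace_overlap(v, Q[, 1:m, drop = FALSE]), 0)
  expect_true(all(diff(o) >= -1e-12))
  # correlation: scale invariance and reflection
  D <- runif(10, 0.1, 2)
  expect_equal(displacement_correlation(2 * D, D), 1)
  expect_equal(displacement_correlation(3 - D, D), -1)
  expect_error(displacement_correlation(rep(1, 10), D), "variance")
})

test_that("planted collective displacements are recovered from noise", {
  # 12 atoms, planted unit displacement direction u; each coordinate is
  # C u_j cos(w t + phi0) plus unit-MSF 1/f noise, with C set so the
  # mean per-coordinate planted power at f_b is 10x the noise share
  n <- 2048; k_b <- 32; na <- 12; phi0 <- 0.3
  share <- (1 / k_b) / sum(1 / seq_len(n / 2 - 1))
  C <- sqrt(2 * 10 * share * 3 * na)
  ovl <- vapply(1:20, function(s) {
    set.seed(s)
    u <- rnorm(3 * na); u <- u / sqrt(sum(u^2))
    recon <- matrix(NA_real_, n, 3 * na)
    for (j in seq_len(3 * na)) {
      pn <- pink_noise(n, msf = 1, seed = 10000 + 100 * s + j,
                       planted = list(k = k_b,
                                      amplitude = C * abs(u[j]),
                                      phase = phi0 + (u[j] < 0) * pi))
      recon[, j] <- band_reconstruct(pn, k_b)$series
    }
    summ <- inphase_summary(recon, k_b, forcing_phase = phi0)
    overlap(u, summ$p)
  }, 0)
  expect_true(all(ovl >= 0.95))
})
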