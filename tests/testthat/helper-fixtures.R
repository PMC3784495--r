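# in-code fixtures shared across test files

# write a multi-model PDB text file; coords is a list of A x 3 matrices
write_mm_pdb <- function(coords, path = tempfile(fileext = ".pdb"),
                         elety = NULL, resno = NULL) {
  na <- nrow(coords[[1]])
  elety <- elety %||% rep("CA", na)
  resno <- resno %||% seq_len(na)
  lines <- character(0)
  for (m in seq_along(coords)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    X <- coords[[m]]
    for (a in seq_len(nrow(X))) {
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
        a, substr(elety[a], 1, 4), "", "ALA", "A", resno[a], "",
        X[a, 1], X[a, 2], X[a, 3], 1.00, 0.00))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random rigid rotation matrix (via QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# trajectory from a list of A x 3 frames
traj_from_frames <- function(frames, dt = 1, labels = NULL) {
  trajectory_ensemble(do.call(rbind, lapply(frames, function(f)
    as.vector(t(f)))), dt = dt, labels = labels)
}

# spectral density object with prescribed component powers (for detect
# unit tests that need exact analytic spectra)
make_density <- function(P, dt = 40, id = "synthetic",
                         kind = "coordinate") {
  n <- 2 * (length(P) + 1)
  structure(list(frequencies = seq_along(P) / (n * dt) * 1000,
                 msf_contrib = P, total_msf = sum(P),
                 n_components = length(P), nyquist = FALSE,
                 n = n, dt = dt, id = id, kind = kind),
            class = "spectral_density")
}

# on-bin cosine series
cosine_series <- function(n, k, A = 1, phase = 0, dt = 1, id = "cos") {
  scalar_series(A * cos(2 * pi * k * (0:(n - 1)) / n + phase), dt, id)
}
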