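# Collective in-phase displacement analysis.
#
# PCA of the band-reconstructed coordinate matrix condenses the forced
# motion into a single eigenvector p; the score along p is an on-bin
# sinusoid whose peak-to-peak amplitude, distributed over atoms by the
# loadings of p, predicts the per-atom displacement between the two end
# conformations. Predictions are compared against an experimental
# displacement field by overlap (direction) and Pearson correlation
# (amplitude pattern).

#' PCA of a trajectory matrix
#'
#' Eigen-decomposition of the covariance matrix of the mean-centered
#' frames-by-variables matrix. Eigenvector signs follow a deterministic
#' convention (largest-magnitude loading positive); a warning is issued
#' when the two leading eigenvalues are nearly degenerate.
#'
#' @param X numeric matrix, frames x variables (>= 2 frames).
#' @return object of class \code{pca_result}: \code{mean},
#'   \code{vectors} (orthonormal columns), \code{values} (descending,
#'   >= 0), \code{dim}.
#' @export
traj_pca <- function(X) {
  X <- as.matrix(X)
  stopifnot_finite(X, "trajectory matrix")
  if (nrow(X) < 2) stop("need at least 2 frames", call. = FALSE)
  mu <- colMeans(X)
  C <- stats::cov(X)
  eig <- eigen(C, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  if (length(vals) > 1 && vals[1] > 0 &&
      (vals[1] - vals[2]) / vals[1] < 1e-6)
    warning("leading eigenvalues are nearly degenerate; ",
            "the first eigenvector is not uniquely determined")
  structure(list(mean = mu, vectors = vecs, values = vals,
                 dim = ncol(X)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  expl <- if (sum(x$values) > 0) x$values[1] / sum(x$values) else NA
  cat(sprintf("pca_result: dim %d, lambda1 = %.4g (%.1f%% of variance)\n",
              x$dim, x$values[1], 100 * expl))
  invisible(x)
}

#' Project onto a PC subspace and reconstruct
#'
#' \eqn{\hat X = \bar x + (\tilde X P_m) P_m^T}: projecting the
#' mean-centered matrix on the leading m eigenvectors and mapping back
#' acts as a filter that removes all variance orthogonal to the subspace.
#'
#' @param X frames x variables matrix.
#' @param pca a \code{\link{traj_pca}} result for \code{X}.
#' @param m subspace size, 1 <= m <= dim.
#' @return the filtered matrix, same shape as \code{X}.
#' @export
project_reconstruct <- function(X, pca, m) {
  if (m < 1 || m > pca$dim) stop("m out of range", call. = FALSE)
  Xc <- sweep(as.matrix(X), 2, pca$mean)
  Pm <- pca$vectors[, seq_len(m), drop = FALSE]
  sweep(Xc %*% Pm %*% t(Pm), 2, pca$mean, `+`)
}

#' Collective in-phase displacement summary
#'
#' Input is the band-reconstructed coordinate matrix (every column an
#' on-bin sinusoid at the same component k, e.g. the x/y/z series of all
#' atoms). The first eigenvector p and the fitted score sinusoid
#' \eqn{a_s \cos(\omega t + \phi)} summarize the collective motion; the
#' per-atom predicted displacement is peak-to-peak,
#' \eqn{R_i = 2 a_s \|p_i\|}, matching the full open-to-closed
#' displacement between the two end conformations. The sign of p is
#' chosen so the collective motion is in-phase with the forcing
#' (wrapped phase difference within [-pi/2, pi/2]).
#'
#' @param recon frames x (3 atoms) matrix of band-reconstructed series,
#'   or a list of \code{\link{band_reconstruct}} results in x,y,z order.
#' @param k the shared component index.
#' @param forcing_phase forcing fundamental phase in radians.
#' @return object of class \code{inphase_summary}: \code{p} (unit
#'   3N-vector), \code{amplitude} (score amplitude a_s, Angstrom),
#'   \code{R} (per-atom peak-to-peak amplitudes), \code{phase} (rad,
#'   relative to forcing, in [-pi/2, pi/2]), \code{explained}
#'   (lambda1 / sum lambda), \code{k}.
#' @export
inphase_summary <- function(recon, k, forcing_phase = 0) {
  if (is.list(recon) && !is.matrix(recon))
    recon <- vapply(recon, `[[`, numeric(recon[[1]]$n), "series")
  recon <- as.matrix(recon)
  if (ncol(recon) %% 3 != 0)
    stop("reconstructed matrix must have 3 columns per atom",
         call. = FALSE)
  if (all(recon == 0))
    stop("all-zero reconstruction; no collective motion to summarize",
         call. = FALSE)
  n <- nrow(recon)
  pca <- traj_pca(recon)
  p <- pca$vectors[, 1]
  score <- sweep(recon, 2, pca$mean) %*% p
  Yk <- fft(as.numeric(score))[k + 1]
  a_s <- 2 * Mod(Yk) / n
  phi <- Arg(Yk)
  dphi <- wrap_pi(phi - forcing_phase)
  if (abs(dphi) > pi / 2) {   # flip p so the motion is in-phase
    p <- -p
    dphi <- wrap_pi(dphi + pi)
  }
  na <- ncol(recon) / 3
  pn <- sqrt(rowSums(matrix(p^2, ncol = 3, byrow = TRUE)))
  expl <- if (sum(pca$values) > 0) pca$values[1] / sum(pca$values) else 0
  structure(list(p = p, amplitude = a_s, R = 2 * a_s * pn,
                 phase = dphi, explained = expl, k = k, n_atoms = na),
            class = "inphase_summary")
}

#' @export
print.inphase_summary <- function(x, ...) {
  cat(sprintf(paste0("inphase_summary: %d atoms, score amplitude %.4g A, ",
                     "phase %+.3f rad, %.1f%% explained\n"),
              x$n_atoms, x$amplitude, x$phase, 100 * x$explained))
  invisible(x)
}

as_flat_displacement <- function(d) {
  if (inherits(d, "displacement_field")) as.vector(t(d$vectors))
  else as.numeric(d)
}

#' Overlap of a displacement field with a direction
#'
#' Absolute cosine between the flattened experimental displacement vector
#' and a (3N) direction, in [0, 1].
#'
#' @param d a \code{\link{displacement_field}} or flat numeric vector.
#' @param v a 3N direction (need not be normalized).
#' @return dimensionless overlap in [0, 1].
#' @export
overlap <- function(d, v) {
  dv <- as_flat_displacement(d)
  if (length(dv) != length(v))
    stop("displacement and direction dimensions differ", call. = FALSE)
  nd <- vec_norm(dv); nv <- vec_norm(v)
  if (nd == 0) stop("zero-norm displacement", call. = FALSE)
  if (nv == 0) stop("zero-norm direction", call. = FALSE)
  abs(sum(dv * v)) / (nd * nv)
}

#' Overlap of a displacement with a PC subspace
#'
#' Norm fraction of the displacement captured by its projection on the
#' span of the leading eigenvectors: the overlap of the best linear
#' combination, \eqn{\|P_m P_m^T d\| / \|d\|}.
#'
#' @param d a \code{\link{displacement_field}} or flat numeric vector.
#' @param P_m matrix with m orthonormal columns.
#' @return dimensionless overlap in [0, 1]; non-decreasing in m.
#' @export
subspace_overlap <- function(d, P_m) {
  dv <- as_flat_displacement(d)
  P_m <- as.matrix(P_m)
  nd <- vec_norm(dv)
  if (nd == 0) stop("zero-norm displacement", call. = FALSE)
  vec_norm(as.numeric(P_m %*% (t(P_m) %*% dv))) / nd
}

#' Correlation of predicted and experimental displacement amplitudes
#'
#' Pearson correlation of the per-atom predicted peak-to-peak amplitudes
#' R_i with the experimental displacement magnitudes D_i.
#'
#' @param R per-atom predicted amplitudes (Angstrom).
#' @param D per-atom experimental magnitudes (Angstrom), same length.
#' @return correlation in [-1, 1].
#' @export
displacement_correlation <- function(R, D) {
  if (length(R) != length(D) || length(R) < 3)
    stop("R and D must have equal length >= 3", call. = FALSE)
  if (sd(R) == 0 || sd(D) == 0)
    stop("zero variance in displacement amplitudes", call. = FALSE)
  cor(R, D)
}

#' Write the collective summary (per-atom TSV + JSON)
#'
#' @param summary an \code{\link{inphase_summary}}.
#' @param path_tsv per-atom table output path.
#' @param path_json summary JSON output path.
#' @param D optional experimental magnitudes for comparison columns.
#' @param d optional \code{\link{displacement_field}} for overlap.
#' @export
write_collective <- function(summary, path_tsv, path_json,
                             D = NULL, d = NULL) {
  pn <- sqrt(rowSums(matrix(summary$p^2, ncol = 3, byrow = TRUE)))
  tab <- data.frame(atom = seq_len(summary$n_atoms),
                    R = summary$R, loading_norm = pn)
  if (!is.null(D)) tab$D <- D
  write_tsv(tab, path_tsv)
  js <- list(amplitude = summary$amplitude, phase = summary$phase,
             explained = summary$explained, k = summary$k)
  if (!is.null(d)) js$overlap <- overlap(d, summary$p)
  if (!is.null(D)) js$correlation <- displacement_correlation(summary$R, D)
  jsonlite::write_json(js, path_json, auto_unbox = TRUE, digits = NA)
  invisible(js)
}
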