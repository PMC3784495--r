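# Phase-angle extraction and clustering of perturbed variables.
#
# A phase difference of pi between two dihedral-like variables cannot be
# distinguished from a sign convention, so raw phases are folded to
# [0, pi) and embedded on the doubled-angle plane (cos 2*theta,
# sin 2*theta), where one turn corresponds to a phase difference of pi
# and anti-phase variables coincide.

#' Fold a phase angle to [0, pi)
#'
#' @param phi phase in radians (any real value).
#' @return \code{phi} modulo pi, in [0, pi).
#' @export
fold_phase <- function(phi) {
  stopifnot_finite(phi, "phase")
  out <- phi %% pi
  out[out >= pi] <- 0  # guard the boundary against rounding
  out
}

#' Separation of two folded phases
#'
#' Circular distance on the folded (period-pi) circle:
#' \code{min(|d|, pi - |d|)}, in [0, pi/2].
#'
#' @param theta1,theta2 folded phases in [0, pi).
#' @return separation in radians.
#' @export
phase_separation <- function(theta1, theta2) {
  if (any(theta1 < 0 | theta1 >= pi | theta2 < 0 | theta2 >= pi))
    stop("folded phases must lie in [0, pi)", call. = FALSE)
  d <- abs(theta1 - theta2)
  pmin(d, pi - d)
}

#' Single phase for a multi-component variable
#'
#' A variable with several band-reconstructed components (the x/y/z
#' coordinates of one atom, or the cos/sin branches of a dihedral) is
#' summarized by the first principal direction of the stacked component
#' series; the projected score is again a single on-bin sinusoid whose
#' phase, relative to the forcing fundamental, is folded to [0, pi).
#'
#' @param recon_components list of \code{\link{band_reconstruct}} results
#'   for one variable (all at the same component k), or a single one.
#' @param forcing_phase phase of the forcing fundamental in radians (the
#'   reference against which variable phases are measured).
#' @param id identifier; defaults to the first component's.
#' @return one-row data.frame of class \code{phase_assignment}: \code{id},
#'   \code{kind}, \code{theta} (rad in [0, pi)), \code{cos2t},
#'   \code{sin2t}, \code{amplitude}.
#' @export
variable_phase <- function(recon_components, forcing_phase = 0, id = NULL) {
  if (inherits(recon_components, "reconstructed_signal"))
    recon_components <- list(recon_components)
  if (!length(recon_components)) stop("no components given", call. = FALSE)
  k <- recon_components[[1]]$k
  n <- recon_components[[1]]$n
  for (rc in recon_components)
    if (rc$k != k || rc$n != n)
      stop("all components must share k and N", call. = FALSE)
  amps <- vapply(recon_components, `[[`, 0, "amplitude")
  if (all(amps == 0))
    stop("all component amplitudes are zero; phase undefined",
         call. = FALSE)
  M <- vapply(recon_components, `[[`, numeric(n), "series")
  M <- as.matrix(M)
  score <- if (ncol(M) == 1) M[, 1] else {
    sv <- svd(M, nu = 0, nv = 1)
    as.numeric(M %*% sv$v[, 1])
  }
  Yk <- fft(score)[k + 1]
  a <- 2 * Mod(Yk) / n
  theta <- fold_phase(Arg(Yk) - forcing_phase)
  out <- data.frame(id = id %||% recon_components[[1]]$id,
                    kind = recon_components[[1]]$kind %||% "coordinate",
                    theta = theta, cos2t = cos(2 * theta),
                    sin2t = sin(2 * theta), amplitude = a,
                    stringsAsFactors = FALSE)
  class(out) <- c("phase_assignment", class(out))
  out
}

#' Assemble a phase table for many variables
#'
#' @param assignments list of \code{\link{variable_phase}} rows.
#' @return data.frame with one row per variable.
#' @export
phase_table <- function(assignments) {
  out <- do.call(rbind, lapply(assignments, as.data.frame))
  rownames(out) <- NULL
  out
}

check_clusterable <- function(tab, include_distances) {
  if (!include_distances && "kind" %in% names(tab) &&
      any(tab$kind == "distance"))
    stop(paste("distance variables are excluded from phase clustering by",
               "default: the phase of a difference of two nearly",
               "equal-amplitude in-phase signals is not the phase of the",
               "constituents (set include_distances = TRUE to override)"),
         call. = FALSE)
  invisible(TRUE)
}

#' Quadrant clustering of folded phases
#'
#' Bins theta into four half-open intervals of width pi/4:
#' cluster j for theta in [(j-1) pi/4, j pi/4).
#'
#' @param tab a \code{\link{phase_table}} data.frame.
#' @param include_distances allow distance variables (default FALSE; see
#'   Details in \code{\link{variable_phase}}).
#' @return the table with a \code{cluster} column (1..4).
#' @export
quadrant_cluster <- function(tab, include_distances = FALSE) {
  check_clusterable(tab, include_distances)
  tab$cluster <- pmin(floor(tab$theta / (pi / 4)), 3) + 1L
  tab
}

# circular mean of folded phases via the doubled-angle embedding
folded_circular_mean <- function(theta) {
  fold_phase(atan2(mean(sin(2 * theta)), mean(cos(2 * theta))) / 2)
}

#' K-means clustering on the doubled-angle plane
#'
#' Runs k-means on the (cos 2 theta, sin 2 theta) embedding with a fixed
#' seed, then relabels clusters by ascending circular-mean theta so the
#' numbering is deterministic.
#'
#' @param tab a \code{\link{phase_table}} data.frame.
#' @param k number of clusters (1 <= k <= number of variables).
#' @param seed RNG seed for the k-means starts.
#' @param include_distances see \code{\link{quadrant_cluster}}.
#' @return the table with a \code{cluster} column (1..k).
#' @export
kmeans_cluster <- function(tab, k, seed = 1, include_distances = FALSE) {
  check_clusterable(tab, include_distances)
  if (k < 1 || k > nrow(tab))
    stop("k must be between 1 and the number of variables", call. = FALSE)
  emb <- cbind(tab$cos2t, tab$sin2t)
  km <- with_seed(seed, kmeans(emb, centers = k, nstart = 25,
                               iter.max = 100))
  means <- vapply(seq_len(k), function(j)
    folded_circular_mean(tab$theta[km$cluster == j]), 0)
  relabel <- match(seq_len(k), order(means))
  tab$cluster <- relabel[km$cluster]
  tab
}

#' Write a phase table as TSV
#'
#' @param tab a clustered phase table.
#' @param path output file.
#' @export
write_phase_table <- function(tab, path) {
  tab$theta_deg <- tab$theta * 180 / pi
  write_tsv(tab, path)
}
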