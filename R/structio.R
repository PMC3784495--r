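# Trajectory / structure IO and atomic-variable extraction.
#
# Coordinates are stored in the field-standard flat xyz layout
# (x1, y1, z1, x2, ...), one row per frame, as used by bio3d. All
# lengths are in Angstrom, the sampling interval dt in ps.

## ---- constructors -----------------------------------------------------

#' Trajectory ensemble
#'
#' Container for a multi-frame coordinate trajectory: an F x 3A coordinate
#' matrix (flat xyz layout), per-atom labels, and the sampling interval.
#'
#' @param xyz numeric matrix, frames x (3 * atoms), columns in
#'   (x1, y1, z1, x2, ...) order. A single frame may be given as a vector.
#' @param dt sampling interval in ps (> 0).
#' @param labels data.frame with one row per atom and columns
#'   \code{chain}, \code{resno}, \code{resid}, \code{elety}. Synthetic
#'   labels are generated when omitted.
#' @param source free-text provenance string.
#' @return object of class \code{trajectory_ensemble}.
#' @export
trajectory_ensemble <- function(xyz, dt, labels = NULL, source = "") {
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) %% 3 != 0)
    stop("xyz must have 3 columns per atom", call. = FALSE)
  stopifnot_finite(xyz, "coordinates")
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("dt must be a single positive number (ps)", call. = FALSE)
  na <- ncol(xyz) / 3
  if (is.null(labels)) labels <- synthetic_labels(na)
  if (nrow(labels) != na)
    stop("labels must have one row per atom (", na, ")", call. = FALSE)
  structure(list(xyz = xyz, dt = dt, labels = labels, source = source),
            class = "trajectory_ensemble")
}

synthetic_labels <- function(n) {
  data.frame(chain = "A", resno = seq_len(n), resid = "ALA",
             elety = "CA", stringsAsFactors = FALSE)
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("trajectory_ensemble: %d frames x %d atoms, dt = %g ps\n",
              n_frames(x), n_atoms(x), x$dt))
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' @rdname trajectory_ensemble
#' @param traj a \code{trajectory_ensemble}.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' @rdname trajectory_ensemble
#' @export
n_atoms <- function(traj) ncol(traj$xyz) / 3

#' Single-model structure
#'
#' @param xyz numeric vector of length 3A (flat xyz layout).
#' @param labels per-atom label data.frame (see
#'   \code{\link{trajectory_ensemble}}).
#' @return object of class \code{structure_model}.
#' @export
structure_model <- function(xyz, labels = NULL) {
  xyz <- as.numeric(xyz)
  stopifnot_finite(xyz, "coordinates")
  if (length(xyz) %% 3 != 0) stop("xyz length must be divisible by 3")
  if (is.null(labels)) labels <- synthetic_labels(length(xyz) / 3)
  structure(list(xyz = xyz, labels = labels), class = "structure_model")
}

#' Scalar variable series
#'
#' A sampled scalar atomic variable (a Cartesian coordinate or an
#' interatomic distance, in Angstrom).
#'
#' @param values numeric vector, length >= 4.
#' @param dt sampling interval in ps.
#' @param id variable identifier.
#' @param kind \code{"coordinate"} or \code{"distance"}.
#' @return object of class \code{scalar_series}.
#' @export
scalar_series <- function(values, dt, id = "x", kind = "coordinate") {
  values <- as.numeric(values)
  if (length(values) < 4) stop("series needs at least 4 samples")
  stopifnot_finite(values)
  kind <- match.arg(kind, c("coordinate", "distance"))
  structure(list(values = values, dt = dt, id = id, kind = kind),
            class = "scalar_series")
}

#' Circular variable series
#'
#' A sampled dihedral-like angle series in degrees on (-180, 180].
#'
#' @param angles numeric vector of angles in degrees.
#' @param dt sampling interval in ps.
#' @param id variable identifier.
#' @param kind \code{"backbone_dihedral"} or \code{"sidechain_dihedral"}.
#' @return object of class \code{circular_series}.
#' @export
circular_series <- function(angles, dt, id = "chi",
                            kind = "sidechain_dihedral") {
  angles <- as.numeric(angles)
  stopifnot_finite(angles, "angles")
  if (any(angles <= -180 | angles > 180))
    stop("angles must lie in (-180, 180] degrees", call. = FALSE)
  kind <- match.arg(kind, c("backbone_dihedral", "sidechain_dihedral"))
  structure(list(angles = angles, dt = dt, id = id, kind = kind),
            class = "circular_series")
}

## ---- reading ----------------------------------------------------------

#' Read a coordinate trajectory
#'
#' Reads either a multi-model PDB (MODEL/ENDMDL delimited, ATOM records)
#' or a plain tab-separated table with one frame per row and a header of
#' \code{atomid:axis} column names (three columns, x/y/z, per atom).
#'
#' @param path file path.
#' @param format \code{"pdb_multimodel"} or \code{"table"}.
#' @param dt sampling interval in ps.
#' @return a \code{\link{trajectory_ensemble}}.
#' @export
read_trajectory <- function(path, format = c("pdb_multimodel", "table"),
                            dt = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "table") read_trajectory_table(path, dt)
  else read_trajectory_pdb(path, dt)
}

read_trajectory_table <- function(path, dt) {
  tab <- read.delim(path, check.names = FALSE)
  if (ncol(tab) %% 3 != 0)
    stop("trajectory table must have 3 columns (x,y,z) per atom; got ",
         ncol(tab), call. = FALSE)
  xyz <- as.matrix(tab)
  if (!is.numeric(xyz))
    stop("non-numeric entries in trajectory table", call. = FALSE)
  trajectory_ensemble(xyz, dt = dt, source = path)
}

read_trajectory_pdb <- function(path, dt) {
  validate_multimodel_pdb(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sel <- which(pdb$atom$type == "ATOM")
  if (length(sel) == 0) stop("no ATOM records in ", path, call. = FALSE)
  cols <- as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel))
  xyz <- pdb$xyz[, cols, drop = FALSE]
  labels <- data.frame(chain = pdb$atom$chain[sel] %||% "A",
                       resno = pdb$atom$resno[sel],
                       resid = pdb$atom$resid[sel],
                       elety = pdb$atom$elety[sel],
                       stringsAsFactors = FALSE)
  labels$chain[is.na(labels$chain)] <- "A"
  trajectory_ensemble(xyz, dt = dt, labels = labels, source = path)
}

# light pre-scan: consistent per-model ATOM counts, well-formed records
validate_multimodel_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  atom <- grepl("^ATOM", lines)
  bad <- which(atom & nchar(lines) < 54)
  if (length(bad))
    stop("malformed ATOM record at line ", bad[1], " of ", path,
         call. = FALSE)
  models <- grepl("^MODEL", lines)
  if (any(models)) {
    grp <- cumsum(models)
    counts <- table(grp[atom & grp > 0])
    if (length(unique(as.integer(counts))) > 1)
      stop("inconsistent atom counts across models in ", path, ": ",
           paste(as.integer(counts), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a single-model PDB structure
#'
#' @param path file path.
#' @return a \code{\link{structure_model}}.
#' @export
read_structure <- function(path) {
  traj <- read_trajectory(path, "pdb_multimodel", dt = 1)
  structure_model(traj$xyz[1, ], traj$labels)
}

#' Read a list of structures from a text file of paths
#'
#' One path per line; relative paths are resolved against the directory of
#' the list file.
#'
#' @param path path to the list file.
#' @return list of \code{\link{structure_model}} objects.
#' @export
read_structure_set <- function(path) {
  paths <- trimws(readLines(path, warn = FALSE))
  paths <- paths[nzchar(paths)]
  if (!length(paths)) stop("empty structure list: ", path, call. = FALSE)
  base <- dirname(path)
  lapply(paths, function(p) {
    if (!file.exists(p) && file.exists(file.path(base, p)))
      p <- file.path(base, p)
    read_structure(p)
  })
}

## ---- writing ----------------------------------------------------------

#' Write a trajectory as a multi-model PDB
#'
#' Optionally places per-atom scores in the B-factor column (clipped to
#' [0, 999.99], two decimals) so cluster ids or flags can be visualized in
#' any molecular viewer.
#'
#' @param traj a \code{\link{trajectory_ensemble}}.
#' @param path output file.
#' @param scores optional per-atom numeric scores for the B column.
#' @export
write_trajectory_pdb <- function(traj, path, scores = NULL) {
  b <- rep(0, n_atoms(traj))
  if (!is.null(scores)) {
    if (length(scores) != n_atoms(traj))
      stop("scores must have one value per atom", call. = FALSE)
    b <- round(pmin(pmax(scores, 0), 999.99), 2)
  }
  bio3d::write.pdb(file = path, xyz = traj$xyz,
                   resno = traj$labels$resno, resid = traj$labels$resid,
                   chain = traj$labels$chain, elety = traj$labels$elety,
                   b = b)
  invisible(path)
}

#' Write a trajectory as a tab-separated table
#'
#' One frame per row; header names are \code{atomid:axis}.
#'
#' @param traj a \code{\link{trajectory_ensemble}}.
#' @param path output file.
#' @export
write_trajectory_table <- function(traj, path) {
  ids <- paste0("A", seq_len(n_atoms(traj)))
  hdr <- as.vector(t(outer(ids, c("x", "y", "z"), paste, sep = ":")))
  df <- as.data.frame(traj$xyz)
  names(df) <- hdr
  write_tsv(df, path)
}

## ---- superposition ----------------------------------------------------

# selection indices -> flat xyz column indices
xyz_cols <- function(atoms) as.vector(rbind(3 * atoms - 2,
                                            3 * atoms - 1,
                                            3 * atoms))

check_selection_rank <- function(coords3) {
  # coords3: n x 3; need >= 3 atoms spanning at least a plane-less line
  if (nrow(coords3) < 3)
    stop("superposition needs at least 3 selected atoms", call. = FALSE)
  s <- svd(scale(coords3, scale = FALSE))$d
  if (s[2] < 1e-8 * max(s[1], 1))
    stop("selected atoms are collinear; superposition is underdetermined",
         call. = FALSE)
  invisible(TRUE)
}

#' Rigid-body least-squares superposition
#'
#' Superposes every frame onto a reference structure by minimizing the
#' RMSD of a selection (Kabsch algorithm via \code{bio3d::fit.xyz};
#' rotations only, reflections excluded).
#'
#' @param traj a \code{\link{trajectory_ensemble}}.
#' @param reference a \code{\link{structure_model}}; defaults to the first
#'   frame of \code{traj}.
#' @param selection atom indices used for the fit; defaults to all atoms.
#' @return the superposed \code{trajectory_ensemble}; per-frame selection
#'   RMSDs before/after are attached as attribute \code{"rmsd"}.
#' @export
superpose <- function(traj, reference = NULL, selection = NULL) {
  if (is.null(reference))
    reference <- structure_model(traj$xyz[1, ], traj$labels)
  if (is.null(selection)) selection <- seq_len(n_atoms(traj))
  if (!length(selection)) stop("empty selection", call. = FALSE)
  if (max(selection) > n_atoms(traj) ||
      max(selection) > length(reference$xyz) / 3)
    stop("selection atoms missing from trajectory or reference",
         call. = FALSE)
  cols <- xyz_cols(selection)
  check_selection_rank(matrix(reference$xyz[cols], ncol = 3, byrow = TRUE))
  before <- frame_rmsd(traj$xyz[, cols, drop = FALSE], reference$xyz[cols])
  fitted <- bio3d::fit.xyz(fixed = reference$xyz, mobile = traj$xyz,
                           fixed.inds = cols, mobile.inds = cols)
  fitted <- matrix(fitted, nrow = n_frames(traj))
  after <- frame_rmsd(fitted[, cols, drop = FALSE], reference$xyz[cols])
  out <- trajectory_ensemble(fitted, traj$dt, traj$labels, traj$source)
  attr(out, "rmsd") <- data.frame(before = before, after = after)
  out
}

frame_rmsd <- function(xyz, ref) {
  sqrt(rowMeans((sweep(xyz, 2, ref))^2) * 3)
}

## ---- derived variable series ------------------------------------------

#' Cartesian coordinate series of one atom
#'
#' @param traj a \code{\link{trajectory_ensemble}}.
#' @param atom atom index.
#' @param axis \code{"x"}, \code{"y"} or \code{"z"}.
#' @return a \code{\link{scalar_series}}.
#' @export
coordinate_series <- function(traj, atom, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  off <- match(axis, c("x", "y", "z"))
  scalar_series(traj$xyz[, 3 * (atom - 1) + off], traj$dt,
                id = sprintf("atom%d.%s", atom, axis), kind = "coordinate")
}

#' Torsion-angle series for an atom quadruple
#'
#' Computes the IUPAC-convention torsion angle (cis = 0, right-handed
#' positive, degrees on (-180, 180]) for four atoms across all frames.
#'
#' @param traj a \code{\link{trajectory_ensemble}}.
#' @param quadruple four atom indices.
#' @param id variable identifier.
#' @param kind dihedral kind label.
#' @return a \code{\link{circular_series}}.
#' @export
dihedral_series <- function(traj, quadruple, id = NULL,
                            kind = "sidechain_dihedral") {
  if (length(quadruple) != 4) stop("quadruple must name 4 atoms")
  if (max(quadruple) > n_atoms(traj))
    stop("quadruple atoms missing from trajectory", call. = FALSE)
  p <- lapply(quadruple, function(a)
    traj$xyz[, (3 * (a - 1) + 1):(3 * a), drop = FALSE])
  b1 <- p[[2]] - p[[1]]; b2 <- p[[3]] - p[[2]]; b3 <- p[[4]] - p[[3]]
  n1 <- rowcross(b1, b2); n2 <- rowcross(b2, b3)
  ln1 <- sqrt(rowSums(n1^2)); ln2 <- sqrt(rowSums(n2^2))
  lb <- sqrt(rowSums(b2^2))
  bad <- which(ln1 < 1e-9 | ln2 < 1e-9 | lb < 1e-9)
  if (length(bad))
    stop("collinear or coincident atoms in frame ", bad[1], call. = FALSE)
  m1 <- rowcross(n1, b2 / lb)
  x <- rowSums(n1 * n2); y <- rowSums(m1 * n2)
  ang <- wrap_deg(-atan2(y, x) * 180 / pi)  # IUPAC sign (cis = 0)
  circular_series(ang, traj$dt,
                  id = id %||% paste0("dih", paste(quadruple, collapse = "-")),
                  kind = kind)
}

rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Interatomic distance series
#'
#' @param traj a \code{\link{trajectory_ensemble}}.
#' @param pair two atom indices.
#' @param id variable identifier.
#' @return a \code{\link{scalar_series}} of Euclidean distances (Angstrom).
#' @export
distance_series <- function(traj, pair, id = NULL) {
  if (length(pair) != 2) stop("pair must name 2 atoms")
  if (max(pair) > n_atoms(traj))
    stop("pair atoms missing from trajectory", call. = FALSE)
  a <- traj$xyz[, (3 * (pair[1] - 1) + 1):(3 * pair[1]), drop = FALSE]
  b <- traj$xyz[, (3 * (pair[2] - 1) + 1):(3 * pair[2]), drop = FALSE]
  d <- sqrt(rowSums((a - b)^2))
  scalar_series(d, traj$dt,
                id = id %||% paste0("dist", pair[1], "-", pair[2]),
                kind = "distance")
}

#' Identify polar-contact atom pairs
#'
#' Enumerates N/O heavy-atom pairs from distinct residues whose distance
#' stays within \code{cutoff} in at least \code{min_occupancy} of frames.
#' Backbone N-O pairs of peptide-bond neighbors (adjacent residues on the
#' same chain) are excluded, as are pairs within one residue.
#'
#' @param traj a \code{\link{trajectory_ensemble}} with informative atom
#'   names in \code{labels$elety}.
#' @param cutoff distance cutoff in Angstrom.
#' @param min_occupancy minimum fraction of frames within the cutoff.
#' @return two-column matrix of atom index pairs (ascending order); empty
#'   (with a warning) when no polar atoms are present.
#' @export
polar_pairs <- function(traj, cutoff = 3.5, min_occupancy = 0.5) {
  el <- substr(trimws(traj$labels$elety), 1, 1)
  polar <- which(el %in% c("N", "O"))
  if (length(polar) < 2) {
    warning("no polar (N/O) atoms found")
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("i", "j"))))
  }
  lb <- traj$labels
  keep <- list()
  for (u in seq_along(polar)) {
    for (v in seq_len(u - 1L)) {
      i <- polar[v]; j <- polar[u]   # i < j by construction
      same_res <- lb$chain[i] == lb$chain[j] && lb$resno[i] == lb$resno[j]
      if (same_res) next
      bb_no <- lb$chain[i] == lb$chain[j] &&
        abs(lb$resno[i] - lb$resno[j]) == 1 &&
        all(trimws(c(lb$elety[i], lb$elety[j])) %in% c("N", "O")) &&
        trimws(lb$elety[i]) != trimws(lb$elety[j])
      if (bb_no) next
      d <- distance_series(traj, c(i, j))$values
      if (mean(d <= cutoff) >= min_occupancy)
        keep[[length(keep) + 1L]] <- c(i, j)
    }
  }
  out <- if (length(keep)) do.call(rbind, keep)
         else matrix(integer(0), ncol = 2)
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  colnames(out) <- c("i", "j")
  out
}

## ---- displacement fields ----------------------------------------------

#' Displacement field between two structure ensembles
#'
#' All structures are superposed onto the first structure of \code{setA}
#' using \code{align_selection}; the per-atom displacement is the
#' difference of the set means over \code{report_selection}.
#'
#' @param setA,setB lists of \code{\link{structure_model}} objects (a
#'   single model is also accepted).
#' @param align_selection atom indices used for superposition (default all).
#' @param report_selection atom indices reported (default all).
#' @return object of class \code{displacement_field} with fields
#'   \code{vectors} (n x 3), \code{magnitudes}, \code{selection}.
#' @export
displacement_field <- function(setA, setB, align_selection = NULL,
                               report_selection = NULL) {
  as_set <- function(s) if (inherits(s, "structure_model")) list(s) else s
  setA <- as_set(setA); setB <- as_set(setB)
  if (!length(setA) || !length(setB))
    stop("empty structure set", call. = FALSE)
  na <- length(setA[[1]]$xyz) / 3
  align_selection <- align_selection %||% seq_len(na)
  report_selection <- report_selection %||% seq_len(na)
  ref <- setA[[1]]
  fit1 <- function(m) {
    tr <- trajectory_ensemble(m$xyz, dt = 1, labels = m$labels)
    superpose(tr, ref, align_selection)$xyz[1, ]
  }
  mean_xyz <- function(set)
    colMeans(do.call(rbind, lapply(set, fit1)))
  cols <- xyz_cols(report_selection)
  d <- mean_xyz(setB)[cols] - mean_xyz(setA)[cols]
  vec <- matrix(d, ncol = 3, byrow = TRUE)
  structure(list(vectors = vec, magnitudes = sqrt(rowSums(vec^2)),
                 selection = report_selection),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("displacement_field: %d atoms, |d| mean %.3f A, max %.3f A\n",
              nrow(x$vectors), mean(x$magnitudes), max(x$magnitudes)))
  invisible(x)
}
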