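#' @title Coordinate featurization
#' @name featurize
#' @description Turns trajectory coordinates into the analysis features of
#'   the pipeline: the 44 selectivity-filter dihedrals (backbone phi/psi of
#'   the five filter residues on each of the four P-loops, plus one
#'   threonine chi1 per loop), their sin/cos expansion, filter-backbone
#'   RMSD after Kabsch superposition, axial (pore-axis) coordinates, and
#'   in-plane (xy) distances from the pore axis.
NULL

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Vectorised dihedral over stacked quadruples (n x 3 matrices per atom).
# IUPAC convention: cis = 0, clockwise looking p2 -> p3 positive;
# range (-180, 180], ties at 180 mapped to +180.
dihedral_rows <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(rowSums(b2^2))
  if (any(nb2 < 1e-12) || any(sqrt(rowSums(n1^2)) < 1e-12) ||
      any(sqrt(rowSums(n2^2)) < 1e-12))
    stop("undefined dihedral: coincident or collinear consecutive points",
         call. = FALSE)
  y <- nb2 * rowSums(b1 * n2)
  x <- rowSums(n1 * n2)
  wrap_deg(rad2deg(atan2(y, x)))
}

#' Dihedral angle of four points
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees in `(-180, 180]`; 0 is cis, 180 trans.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  unname(dihedral_rows(rbind(p1), rbind(p2), rbind(p3), rbind(p4))[1])
}

#' Define the selectivity-filter selection
#'
#' One entry per P-loop: the chain id, the residue index of the first
#' residue of the five-residue filter motif, and the threonine residue
#' whose chi1 is included (by default the first motif residue).
#'
#' @param chain_id Character vector of 4 chain ids.
#' @param first_res Integer vector of 4 first-residue indices.
#' @param thr_res Integer vector of threonine indices (default `first_res`).
#' @return A `data.frame` of class `pf_sfsel`.
#' @export
sf_selection <- function(chain_id, first_res, thr_res = first_res) {
  if (length(chain_id) != 4 || length(first_res) != 4)
    stop("the filter selection must list exactly 4 P-loops", call. = FALSE)
  df <- data.frame(chain_id = as.character(chain_id),
                   first_res = as.integer(first_res),
                   last_res = as.integer(first_res) + 4L,
                   thr_res = as.integer(thr_res),
                   stringsAsFactors = FALSE)
  class(df) <- c("pf_sfsel", "data.frame")
  df
}

# Row index of one atom in the atom table; error names the address.
atom_index <- function(atoms, chain, resid, name) {
  i <- which(atoms$chain_id == chain & atoms$residue_index == resid &
               atoms$atom_name == name)
  if (length(i) != 1)
    stop("missing atom: chain ", chain, " residue ", resid, " atom ", name,
         call. = FALSE)
  i
}

# The canonical 44-column dihedral plan: chain-major, residues N->C, phi
# then psi per residue, chi1 last per chain. Returns a data.frame with one
# row per column and the four atom indices of each dihedral.
sf_dihedral_plan <- function(atoms, sel) {
  rows <- list()
  for (p in seq_len(nrow(sel))) {
    ch <- sel$chain_id[p]
    for (r in sel$first_res[p]:sel$last_res[p]) {
      rows[[length(rows) + 1]] <- data.frame(
        label = paste0(ch, r, "_phi"), chain = ch, residue = r, kind = "phi",
        i1 = atom_index(atoms, ch, r - 1, "C"),
        i2 = atom_index(atoms, ch, r, "N"),
        i3 = atom_index(atoms, ch, r, "CA"),
        i4 = atom_index(atoms, ch, r, "C"), stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        label = paste0(ch, r, "_psi"), chain = ch, residue = r, kind = "psi",
        i1 = atom_index(atoms, ch, r, "N"),
        i2 = atom_index(atoms, ch, r, "CA"),
        i3 = atom_index(atoms, ch, r, "C"),
        i4 = atom_index(atoms, ch, r + 1, "N"), stringsAsFactors = FALSE)
    }
    tr <- sel$thr_res[p]
    rows[[length(rows) + 1]] <- data.frame(
      label = paste0(ch, tr, "_chi1"), chain = ch, residue = tr,
      kind = "chi1",
      i1 = atom_index(atoms, ch, tr, "N"),
      i2 = atom_index(atoms, ch, tr, "CA"),
      i3 = atom_index(atoms, ch, tr, "CB"),
      i4 = atom_index(atoms, ch, tr, "OG1"), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Extract the 44 selectivity-filter dihedrals
#'
#' Computes phi and psi for the five filter residues of each P-loop plus
#' the threonine chi1, in a fixed documented order (chain-major, residues
#' N to C, phi before psi, chi1 last per chain): 4 x (5 x 2 + 1) = 44
#' columns. Phi of the first filter residue uses the preceding residue's
#' carbonyl carbon, which must be present; any missing atom is an error.
#'
#' @param traj A `pf_traj`.
#' @param sel A [sf_selection()].
#' @return Numeric matrix `n_frames x 44` in degrees, with column labels
#'   `<chain><residue>_<phi|psi|chi1>`.
#' @export
extract_sf_dihedrals <- function(traj, sel) {
  if (!inherits(sel, "pf_sfsel") || nrow(sel) != 4)
    stop("the filter selection must list exactly 4 P-loops", call. = FALSE)
  plan <- sf_dihedral_plan(traj$atoms, sel)
  nf <- n_frames(traj)
  out <- matrix(NA_real_, nrow = nf, ncol = nrow(plan),
                dimnames = list(NULL, plan$label))
  at <- function(i) matrix(traj$coords[, i, ], ncol = 3)
  for (k in seq_len(nrow(plan))) {
    out[, k] <- dihedral_rows(at(plan$i1[k]), at(plan$i2[k]),
                              at(plan$i3[k]), at(plan$i4[k]))
  }
  out
}

#' Sin/cos expansion of a dihedral matrix
#'
#' @param m Matrix of angles in degrees (`n x d`).
#' @return `n x 2d` matrix with columns `sin(a1), cos(a1), sin(a2), ...`.
#' @export
sincos_expand <- function(m) {
  m <- as.matrix(m)
  rad <- deg2rad(m)
  out <- matrix(NA_real_, nrow = nrow(m), ncol = 2 * ncol(m))
  out[, seq(1, 2 * ncol(m), by = 2)] <- sin(rad)
  out[, seq(2, 2 * ncol(m), by = 2)] <- cos(rad)
  lbl <- colnames(m)
  if (is.null(lbl)) lbl <- paste0("a", seq_len(ncol(m)))
  colnames(out) <- as.vector(rbind(paste0("sin_", lbl), paste0("cos_", lbl)))
  out
}

# Atom-table row indices of the SF backbone (N, CA, C, O of the filter
# residues, chain-major).
sf_backbone_indices <- function(atoms, sel) {
  idx <- integer(0)
  for (p in seq_len(nrow(sel))) {
    for (r in sel$first_res[p]:sel$last_res[p]) {
      for (nm in c("N", "CA", "C", "O"))
        idx <- c(idx, atom_index(atoms, sel$chain_id[p], r, nm))
    }
  }
  idx
}

#' Filter-backbone RMSD series
#'
#' Per-frame root-mean-square deviation of the filter backbone atoms
#' (N, CA, C, O of the five motif residues on all four P-loops) from a
#' reference frame, after optimal rigid-body superposition (Kabsch) on the
#' same selection.
#'
#' @param traj A `pf_traj`.
#' @param sel A [sf_selection()].
#' @param reference Reference frame index (default 1, the initial filter
#'   structure of the run).
#' @param fit Superpose before measuring (default `TRUE`). `fit = FALSE`
#'   measures raw deviations in the laboratory frame.
#' @return Numeric vector of per-frame RMSD values (Angstrom).
#' @export
sf_backbone_rmsd <- function(traj, sel, reference = 1, fit = TRUE) {
  idx <- sf_backbone_indices(traj$atoms, sel)
  nf <- n_frames(traj)
  ref <- traj$coords[reference, idx, ]
  refv <- as.vector(t(ref))
  out <- numeric(nf)
  for (f in seq_len(nf)) {
    mob <- as.vector(t(traj$coords[f, idx, ]))
    if (fit) {
      out[f] <- bio3d::rmsd(refv, mob, fit = TRUE)
    } else {
      out[f] <- sqrt(mean(colSums(matrix((mob - refv)^2, nrow = 3))))
    }
  }
  out
}

# Per-frame SF backbone centroid (the pore-axis origin).
sf_origin <- function(traj, sel) {
  idx <- sf_backbone_indices(traj$atoms, sel)
  sub <- traj$coords[, idx, , drop = FALSE]
  apply(sub, c(1, 3), mean)
}

#' Axial (pore-axis) coordinate series
#'
#' The pore axis is the laboratory z axis after centering each frame on
#' the filter-backbone centroid; positive z points extracellular. The
#' value is therefore invariant under rigid translations of the whole
#' system.
#'
#' @param traj A `pf_traj`.
#' @param atom_rows Integer row indices into `traj$atoms` (e.g. ion or
#'   water oxygen atoms).
#' @param sel A [sf_selection()] defining the axis origin.
#' @return Numeric matrix `n_frames x length(atom_rows)` of z values (Angstrom).
#' @export
axial_coordinate <- function(traj, atom_rows, sel) {
  org <- sf_origin(traj, sel)                # n_frames x 3
  z <- matrix(traj$coords[, atom_rows, 3], nrow = n_frames(traj))
  sweep(z, 1, org[, 3])
}

#' In-plane (xy) distance from the pore axis
#'
#' Distance of each selected atom from the pore axis projected on the
#' membrane (xy) plane, per frame.
#'
#' @inheritParams axial_coordinate
#' @return Numeric matrix `n_frames x length(atom_rows)` (Angstrom).
#' @export
xy_distance <- function(traj, atom_rows, sel) {
  org <- sf_origin(traj, sel)
  x <- matrix(traj$coords[, atom_rows, 1], nrow = n_frames(traj))
  y <- matrix(traj$coords[, atom_rows, 2], nrow = n_frames(traj))
  sqrt(sweep(x, 1, org[, 1])^2 + sweep(y, 1, org[, 2])^2)
}
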