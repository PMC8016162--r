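#' @title TM2-TM4 gating and lipid cavity penetration
#' @name gating_lipids
#' @description Distances between the TM2 and TM4 helices of opposite
#'   subunits (reference C-alpha atoms), up/down state classification with
#'   the 8 Angstrom threshold and strict >50% prevalence rule, debounced
#'   transition counting, distance-distribution modes, and lipid
#'   cavity-penetration flags with the 10 Angstrom / >50% rule.
NULL

#' TM2-TM4 interface distances
#'
#' Plain euclidean distance per frame between the two reference atoms of
#' each interface (conventionally the C-alpha of the TM2 proline of one
#' subunit and of the TM4 isoleucine of the other).
#'
#' @param traj A `pf_traj`.
#' @param refs Data frame with one row per interface and columns
#'   `interface`, `chain1`, `res1`, `atom1`, `chain2`, `res2`, `atom2`.
#' @return A data frame of per-frame distances, one column per interface.
#' @export
interface_distances <- function(traj, refs) {
  nf <- n_frames(traj)
  out <- list()
  for (k in seq_len(nrow(refs))) {
    i1 <- atom_index(traj$atoms, refs$chain1[k], refs$res1[k], refs$atom1[k])
    i2 <- atom_index(traj$atoms, refs$chain2[k], refs$res2[k], refs$atom2[k])
    p1 <- matrix(traj$coords[, i1, ], ncol = 3)
    p2 <- matrix(traj$coords[, i2, ], ncol = 3)
    out[[as.character(refs$interface[k])]] <- sqrt(rowSums((p1 - p2)^2))
  }
  as.data.frame(out, check.names = FALSE)
}

#' Classify up/down gating states
#'
#' A frame is `down` when the distance is strictly above the threshold
#' (exactly 8 Angstrom is `up`). A state is prevalent in a run only if it
#' holds strictly more than 50% of the frames; otherwise the prevalent
#' state is `"none"`.
#'
#' @param distance Numeric per-frame distance series (Angstrom).
#' @param threshold Up/down threshold (Angstrom, default 8).
#' @param prevalence Strict prevalence fraction (default 0.5).
#' @return List of class `pf_gating`: `states` (character per frame),
#'   `down_fraction`, `prevalent`.
#' @export
classify_updown <- function(distance, threshold = 8, prevalence = 0.5) {
  if (inherits(distance, "data.frame")) distance <- distance[[
    setdiff(names(distance), "time_ns")[1]]]
  stopifnot(all(distance > 0))
  states <- ifelse(distance > threshold, "down", "up")
  fd <- mean(states == "down")
  prevalent <- if (fd > prevalence) "down" else
    if (1 - fd > prevalence) "up" else "none"
  structure(list(states = states, down_fraction = fd,
                 prevalent = prevalent),
            class = "pf_gating")
}

#' Joint gating label of the two interfaces
#'
#' @param gating_a,gating_b `pf_gating` results for the A-side and B-side
#'   interfaces.
#' @return A string such as `"up/up"` or `"up/down"` (A-side first).
#' @export
joint_gating_label <- function(gating_a, gating_b) {
  paste(gating_a$prevalent, gating_b$prevalent, sep = "/")
}

#' Count debounced state transitions
#'
#' A transition is a state change that persists at least `min_dwell`
#' frames; shorter blips are ignored. Counts are reported by direction.
#'
#' @param states Character vector of per-frame states (`"up"`/`"down"`).
#' @param min_dwell Minimum persistence (frames, default 1 = no
#'   debounce).
#' @return Named integer vector `c(up_down = ..., down_up = ...)`.
#' @export
count_transitions <- function(states, min_dwell = 1) {
  rl <- rle(states)
  up_down <- 0L
  down_up <- 0L
  current <- states[1]
  for (k in seq_along(rl$values)) {
    if (rl$lengths[k] < min_dwell) next
    v <- rl$values[k]
    if (v != current) {
      if (current == "up" && v == "down") up_down <- up_down + 1L
      if (current == "down" && v == "up") down_up <- down_up + 1L
      current <- v
    }
  }
  c(up_down = up_down, down_up = down_up)
}

#' Modes of a distance distribution
#'
#' Gaussian-kernel density estimate evaluated on a 0.05 Angstrom grid;
#' returns all local maxima above 10% of the global peak, ordered by
#' height (global mode first).
#'
#' @param x Numeric distance sample (Angstrom).
#' @param bandwidth KDE bandwidth (Angstrom); default Silverman's rule.
#' @return Numeric vector of mode locations (Angstrom).
#' @export
distribution_mode <- function(x, bandwidth = NULL) {
  x <- x[is.finite(x)]
  if (length(unique(x)) == 1) return(x[1])
  bw <- if (is.null(bandwidth)) stats::bw.nrd0(x) else bandwidth
  lo <- min(x) - 3 * bw
  hi <- max(x) + 3 * bw
  grid_n <- ceiling((hi - lo) / 0.05) + 1
  den <- stats::density(x, bw = bw, from = lo, to = hi, n = grid_n)
  y <- den$y
  k <- length(y)
  is_max <- c(y[1] > y[2], y[2:(k - 1)] > y[1:(k - 2)] &
                y[2:(k - 1)] >= y[3:k], y[k] > y[k - 1])
  peaks <- which(is_max & y > 0.1 * max(y))
  peaks <- peaks[order(-y[peaks])]
  den$x[peaks]
}

#' Lipid cavity-penetration flag
#'
#' A lipid is inside the cavity when its headgroup spends strictly more
#' than `fraction_rule` of the frames at an in-plane distance strictly
#' below `cutoff` (exact boundary values on either rule do not flag).
#'
#' @param distance Per-frame headgroup in-plane distance (Angstrom), or a
#'   feature table with one distance column.
#' @param cutoff Cavity boundary (Angstrom, default 10).
#' @param fraction_rule Time-fraction rule (default 0.5).
#' @param lipid_id Optional identifier carried through.
#' @return List of class `pf_lipid`: `lipid_id`, `fraction`,
#'   `in_cavity`.
#' @export
lipid_cavity_flag <- function(distance, cutoff = 10, fraction_rule = 0.5,
                              lipid_id = NA) {
  if (inherits(distance, "data.frame")) distance <- distance[[
    setdiff(names(distance), "time_ns")[1]]]
  frac <- mean(distance < cutoff)
  structure(list(lipid_id = lipid_id, fraction = frac,
                 in_cavity = frac > fraction_rule),
            class = "pf_lipid")
}

#' Default lipid reference atoms
#'
#' The headgroup phosphorus, the glycerol-ester carbons of both chains
#' and the terminal methyl carbons of both acyl chains of a
#' phosphatidylcholine, the atoms whose in-plane distance profiles track
#' lipid penetration depth.
#'
#' @return Character vector of atom names.
#' @export
lipid_reference_atoms <- function() c("P", "C21", "C36", "C218", "C316")

#' Per-atom in-plane distance profiles of one lipid
#'
#' @param traj A `pf_traj` including the lipid.
#' @param lipid_chain,lipid_res Chain id and residue index of the lipid.
#' @param atom_names Atom names to profile (default
#'   [lipid_reference_atoms()]); an absent atom is an error naming it.
#' @param sel A [sf_selection()] defining the pore axis.
#' @param bin_width Histogram bin width (Angstrom, default 0.5).
#' @return List of class `pf_lipidprofile`: `series` (data frame of
#'   per-atom distances), `histograms` (named list of `hist` objects).
#' @export
lipid_atom_profile <- function(traj, lipid_chain, lipid_res,
                               atom_names = lipid_reference_atoms(), sel,
                               bin_width = 0.5) {
  rows <- vapply(atom_names, function(nm)
    atom_index(traj$atoms, lipid_chain, lipid_res, nm), integer(1))
  d <- xy_distance(traj, rows, sel)
  colnames(d) <- atom_names
  breaks <- seq(0, max(d) + bin_width, by = bin_width)
  hists <- lapply(atom_names, function(nm)
    graphics::hist(d[, nm], breaks = breaks, plot = FALSE))
  names(hists) <- atom_names
  structure(list(series = as.data.frame(d), histograms = hists),
            class = "pf_lipidprofile")
}
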