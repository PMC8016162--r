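#' @title Conformational-state classification
#' @name states
#' @description DBSCAN clustering of the low-dimensional map, geometric
#'   carbonyl-flip classification of filter conformations, mapping of
#'   clusters to the recurrent-state vocabulary (I, II, II', III-VII,
#'   other) and relative-population tables.
NULL

BOUNDARIES <- c("S4-S3", "S3-S2", "S2-S1", "S1-S0")

#' DBSCAN clustering
#'
#' Standard sequential DBSCAN (a core point has at least `min_points`
#' neighbors within `eps`, counting itself; border points join the first
#' cluster that discovers them; remaining points are noise). Points
#' outside the optional analysis window are labeled noise before
#' clustering. The implementation bins points on an `eps` grid for the
#' region queries, so it scales to large maps.
#'
#' @param points Numeric matrix `n x 2` (low-d coordinates).
#' @param eps Neighborhood radius (map units).
#' @param min_points Minimum neighborhood size for a core point
#'   (including the point itself).
#' @param window Optional analysis box `c(xmin, xmax, ymin, ymax)`
#'   (e.g. `c(-60, 60, -60, 60)`); points outside it get label -1.
#' @return Integer vector of cluster ids (1, 2, ...); -1 marks noise or
#'   out-of-window points.
#' @export
dbscan_cluster <- function(points, eps, min_points = 3, window = NULL) {
  points <- as.matrix(points)
  stopifnot(eps > 0, min_points >= 1, ncol(points) == 2,
            all(is.finite(points)))
  n <- nrow(points)
  labels <- rep(-1L, n)
  active <- rep(TRUE, n)
  if (!is.null(window)) {
    stopifnot(length(window) == 4)
    active <- points[, 1] >= window[1] & points[, 1] <= window[2] &
      points[, 2] >= window[3] & points[, 2] <= window[4]
  }
  idx <- which(active)
  if (length(idx) == 0) return(labels)
  px <- points[idx, 1]
  py <- points[idx, 2]
  m <- length(idx)
  # eps-grid bins; region query scans the 3x3 neighborhood of a bin
  bx <- floor(px / eps)
  by <- floor(py / eps)
  bkey <- paste(bx, by)
  bins <- split(seq_len(m), bkey)
  binkeys <- names(bins)
  nbin <- length(bins)
  bid <- match(bkey, binkeys)             # bin id per point
  # ids of the occupied bins in each bin's 3x3 neighborhood, precomputed
  kx <- vapply(strsplit(binkeys, " ", fixed = TRUE),
               function(v) as.numeric(v[1]), numeric(1))
  ky <- vapply(strsplit(binkeys, " ", fixed = TRUE),
               function(v) as.numeric(v[2]), numeric(1))
  nbr_bins <- lapply(seq_len(nbin), function(b) {
    hit <- match(as.vector(outer(kx[b] + (-1:1), ky[b] + (-1:1), paste)),
                 binkeys)
    hit[!is.na(hit)]
  })
  query <- function(i) {
    cand <- unlist(bins[nbr_bins[[bid[i]]]], use.names = FALSE)
    cand[(px[cand] - px[i])^2 + (py[cand] - py[i])^2 <= eps^2]
  }
  lab <- rep(0L, m)                       # 0 unclassified, -1 noise
  visited <- rep(FALSE, m)
  queued <- rep(FALSE, m)                 # each point enters a queue once
  queue <- integer(m)
  # a point is "settled" once it is labeled > 0 and queued or visited;
  # when every point in a bin block is settled, popping a point there
  # cannot claim or enqueue anything, so its region query can be skipped
  settled <- rep(FALSE, m)
  bin_total <- tabulate(bid, nbin)
  bin_settled <- integer(nbin)
  settle <- function(pts) {
    new <- pts[!settled[pts] & lab[pts] > 0L &
                 (queued[pts] | visited[pts])]
    if (length(new) > 0) {
      settled[new] <<- TRUE
      bin_settled <<- bin_settled + tabulate(bid[new], nbin)
    }
  }
  cl <- 0L
  for (i in seq_len(m)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- query(i)
    if (length(nb) < min_points) {
      lab[i] <- -1L
      next
    }
    cl <- cl + 1L
    lab[i] <- cl
    lab[nb[lab[nb] <= 0]] <- cl
    add <- nb[!visited[nb] & !queued[nb]]
    queued[add] <- TRUE
    settle(nb)
    qhead <- 1L
    qtail <- length(add)
    queue[seq_len(qtail)] <- add
    while (qhead <= qtail) {
      j <- queue[qhead]
      qhead <- qhead + 1L
      if (visited[j]) next
      visited[j] <- TRUE
      nbj <- nbr_bins[[bid[j]]]
      if (all(bin_settled[nbj] == bin_total[nbj])) next
      nbj <- query(j)
      if (length(nbj) >= min_points) {
        newpts <- nbj[lab[nbj] <= 0]
        lab[newpts] <- cl
        add <- nbj[!visited[nbj] & !queued[nbj]]
        if (length(add) > 0) {
          queued[add] <- TRUE
          queue[qtail + seq_along(add)] <- add
          qtail <- qtail + length(add)
        }
        settle(nbj)
      }
    }
  }
  labels[idx] <- lab
  labels
}

#' Canonical flip-signature string
#'
#' A flip signature is a set of (chain, boundary) pairs; its canonical
#' string is the sorted `chain|boundary` entries joined with `+`, the
#' empty signature being `""` (the native filter).
#'
#' @param chain Character vector of chain ids (may be empty).
#' @param boundary Matching boundary labels from
#'   `c("S4-S3", "S3-S2", "S2-S1", "S1-S0")`.
#' @return A single canonical string.
#' @export
signature_string <- function(chain = character(), boundary = character()) {
  stopifnot(length(chain) == length(boundary))
  if (length(chain) == 0) return("")
  if (!all(boundary %in% BOUNDARIES))
    stop("unknown boundary label; expected one of ",
         paste(BOUNDARIES, collapse = ", "), call. = FALSE)
  paste(sort(paste(chain, boundary, sep = "|")), collapse = "+")
}

#' Default residue-position to site-boundary map
#'
#' Maps motif positions 1-4 to the coordination-site boundary their
#' carbonyl forms, in the KcsA-like assignment: the threonine carbonyl to
#' S4-S3, position 2 to S3-S2, position 3 to S2-S1 and position 4 to
#' S1-S0. Position 5's carbonyl points extracellular and is not
#' flip-capable. Configurable because structure-specific assignments
#' differ.
#'
#' @return Named character vector (names are motif positions).
#' @export
default_boundary_map <- function() {
  c(`1` = "S4-S3", `2` = "S3-S2", `3` = "S2-S1", `4` = "S1-S0")
}

#' Classify carbonyl flips geometrically
#'
#' A motif residue's carbonyl is flipped when the inward radial cosine --
#' the cosine between the in-plane component of the C->O vector and the
#' in-plane unit vector from C toward the pore axis -- is strictly
#' negative. A carbonyl exactly tangential (cosine 0) is not flipped.
#'
#' @param traj A `pf_traj`.
#' @param sel A [sf_selection()].
#' @param boundary_map Position-to-boundary table
#'   (default [default_boundary_map()]).
#' @return Character vector of canonical signature strings, one per
#'   frame.
#' @export
classify_flips <- function(traj, sel, boundary_map = default_boundary_map()) {
  nf <- n_frames(traj)
  org <- sf_origin(traj, sel)
  positions <- as.integer(names(boundary_map))
  per_res <- list()
  for (p in seq_len(nrow(sel))) {
    ch <- sel$chain_id[p]
    for (pos in positions) {
      r <- sel$first_res[p] + pos - 1L
      iC <- atom_index(traj$atoms, ch, r, "C")
      iO <- atom_index(traj$atoms, ch, r, "O")
      Cxy <- matrix(traj$coords[, iC, 1:2], nrow = nf)
      Oxy <- matrix(traj$coords[, iO, 1:2], nrow = nf)
      v <- Oxy - Cxy
      nv <- sqrt(rowSums(v^2))
      if (any(nv < 1e-9))
        stop("degenerate C->O vector at chain ", ch, " residue ", r,
             call. = FALSE)
      u <- org[, 1:2, drop = FALSE] - Cxy
      nu <- sqrt(rowSums(u^2))
      cosr <- rowSums(v * u) / (nv * pmax(nu, 1e-12))
      per_res[[paste(ch, pos)]] <- list(
        flipped = cosr < 0, chain = ch,
        boundary = boundary_map[[as.character(pos)]])
    }
  }
  vapply(seq_len(nf), function(f) {
    fl <- Filter(function(e) e$flipped[f], per_res)
    signature_string(vapply(fl, `[[`, "", "chain"),
                     vapply(fl, `[[`, "", "boundary"))
  }, character(1))
}

# number of flips encoded in a canonical signature string
signature_size <- function(sig) {
  ifelse(sig == "", 0L, lengths(strsplit(sig, "+", fixed = TRUE)))
}

# boundary multiset (sorted distinct boundaries) of a signature string
signature_boundaries <- function(sig) {
  if (sig == "") return(character(0))
  parts <- strsplit(sig, "+", fixed = TRUE)[[1]]
  sort(unique(vapply(strsplit(parts, "|", fixed = TRUE), `[`, "", 2)))
}

# map one canonical signature to the recurrent-state vocabulary
state_from_signature <- function(sig, chain_a = "A") {
  if (sig == "") return("I")
  parts <- strsplit(sig, "+", fixed = TRUE)[[1]]
  chains <- vapply(strsplit(parts, "|", fixed = TRUE), `[`, "", 1)
  bset <- signature_boundaries(sig)
  nb <- length(parts)
  if (nb == 1 && identical(bset, "S4-S3"))
    return(if (chains[1] == chain_a) "II" else "II'")
  if (nb == 1 && identical(bset, "S3-S2")) return("III")
  if (nb == 1 && identical(bset, "S2-S1")) return("IV")
  if (setequal(bset, c("S4-S3", "S3-S2")) && nb == 2) return("V")
  if (setequal(bset, c("S3-S2", "S1-S0"))) return("VI")
  if (setequal(bset, c("S3-S2", "S2-S1", "S1-S0"))) return("VII")
  "other"
}

STATE_LEVELS <- c("I", "II", "II'", "III", "IV", "V", "VI", "VII", "other")

#' Label clustered frames with the recurrent-state vocabulary
#'
#' Each cluster is labeled by the modal flip signature of its member
#' frames (ties broken toward the signature with fewer flips, i.e. toward
#' the native state), mapped to the state vocabulary: I (no flips), II /
#' II' (single S4-S3 flip on chain A / another chain), III (single
#' S3-S2), IV (single S2-S1), V (S4-S3 + S3-S2), VI (S3-S2 + S1-S0),
#' VII (S3-S2 + S2-S1 + S1-S0). Unmatched signatures and noise frames map
#' to `"other"`.
#'
#' @param cluster_ids Integer labels from [dbscan_cluster()] (-1 noise).
#' @param signatures Per-frame canonical signature strings.
#' @param chain_a Chain id distinguishing II from II'.
#' @return List of class `pf_statetrace`: `state` (per-frame factor),
#'   `cluster` (input ids), `cluster_states` (named map cluster -> state).
#' @export
label_states <- function(cluster_ids, signatures, chain_a = "A") {
  stopifnot(length(cluster_ids) == length(signatures))
  states <- rep("other", length(cluster_ids))
  cl_ids <- sort(unique(cluster_ids[cluster_ids > 0]))
  cluster_states <- character(0)
  for (cl in cl_ids) {
    member <- signatures[cluster_ids == cl]
    tab <- table(member)
    top <- names(tab)[tab == max(tab)]
    modal <- top[order(signature_size(top), top)][1]
    st <- state_from_signature(modal, chain_a)
    cluster_states[as.character(cl)] <- st
    states[cluster_ids == cl] <- st
  }
  structure(list(state = factor(states, levels = STATE_LEVELS),
                 cluster = cluster_ids, cluster_states = cluster_states),
            class = "pf_statetrace")
}

#' Relative-population table across conditions
#'
#' Percentages are taken over all frames of each condition, noise frames
#' contributing to `"other"`, so rows sum to 100.
#'
#' @param traces Named list of `pf_statetrace` objects (or per-frame state
#'   factors/characters), one per condition.
#' @return Matrix `conditions x states` of percentages.
#' @export
population_table <- function(traces) {
  rows <- lapply(traces, function(tr) {
    st <- if (inherits(tr, "pf_statetrace")) tr$state else
      factor(as.character(tr), levels = STATE_LEVELS)
    100 * as.vector(table(st)) / length(st)
  })
  out <- do.call(rbind, rows)
  dimnames(out) <- list(names(traces), STATE_LEVELS)
  out
}

#' Sum named state populations for one condition
#'
#' @param table Matrix from [population_table()], or any matrix with
#'   state columns and condition rows.
#' @param states Character vector of state names to sum (may be empty).
#' @param condition Row name (or index).
#' @return The summed percentage.
#' @export
sum_states <- function(table, states, condition) {
  if (length(states) == 0) return(0)
  sum(table[condition, states])
}
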