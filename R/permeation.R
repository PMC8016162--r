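#' @title Permeation events and conductance
#' @name permeation
#' @description Detects complete ion crossings of the selectivity filter
#'   from axial traces with a three-region state machine, gates events on
#'   water exit from the filter, and estimates single-channel conductance
#'   from event counts with replica statistics. Frames are 1-based
#'   throughout.
NULL

#' Filter axial bounds
#'
#' @param z_low Entry (S4) plane, Angstrom.
#' @param z_high Exit (S0) plane, Angstrom.
#' @param radial_cut In-plane cutoff for site occupancy (Angstrom).
#' @return A list of class `pf_bounds`.
#' @export
filter_bounds <- function(z_low = -6, z_high = 6, radial_cut = 4) {
  stopifnot(z_low < z_high, radial_cut > 0)
  structure(list(z_low = z_low, z_high = z_high, radial_cut = radial_cut),
            class = "pf_bounds")
}

# region code per frame: 1 below, 2 inside, 3 above
region_code <- function(z, bounds) {
  r <- rep(2L, length(z))
  r[z < bounds$z_low] <- 1L
  r[z > bounds$z_high] <- 3L
  r
}

# event detection on one ion's z series
detect_events_one <- function(z, bounds, count_initial_inside) {
  reg <- region_code(z, bounds)
  rl <- rle(reg)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  events <- list()
  # pending direction: +1 armed upward (entered from below or jump
  # below->above), -1 armed downward, 0 unarmed
  armed <- 0L
  entry <- NA_integer_
  prev <- rl$values[1]
  if (rl$values[1] == 2L && count_initial_inside) {
    armed <- 1L                         # part of the single file: first
    entry <- 1L                         # exit above counts
  }
  if (length(rl$values) > 1) {
    for (k in 2:length(rl$values)) {
      cur <- rl$values[k]
      fr <- starts[k]
      if (cur == 2L) {
        armed <- if (prev == 1L) 1L else -1L
        entry <- fr
      } else if (cur == 3L) {
        if (prev == 1L || armed == 1L) {      # full traversal upward
          events[[length(events) + 1]] <- data.frame(
            entry_frame = if (prev == 1L && armed != 1L) fr - 1L else entry,
            completion_frame = fr, direction = 1L)
        }
        armed <- 0L
        entry <- NA_integer_
      } else {                                # cur == 1L
        if (prev == 3L || armed == -1L) {     # full traversal downward
          events[[length(events) + 1]] <- data.frame(
            entry_frame = if (prev == 3L && armed != -1L) fr - 1L else entry,
            completion_frame = fr, direction = -1L)
        }
        armed <- 0L
        entry <- NA_integer_
      }
      prev <- cur
    }
  }
  if (length(events) == 0)
    return(data.frame(entry_frame = integer(), completion_frame = integer(),
                      direction = integer()))
  do.call(rbind, events)
}

#' Detect complete permeation events
#'
#' Three-region state machine (below / inside / above the filter) per
#' ion: an outward event is counted at the first frame the ion is above
#' `z_high` having entered the filter from below; excursions that return
#' without full traversal count nothing; inward events are mirrored with
#' direction -1. A below-to-above jump within one frame interval also
#' counts (the ion passed through). Ions that start inside the filter are
#' treated as part of the single file: with
#' `count_initial_inside = TRUE` (default) their first exit above counts.
#'
#' @param z Feature table or numeric matrix of per-ion axial series
#'   (Angstrom); a bare numeric vector is one ion.
#' @param bounds A [filter_bounds()].
#' @param count_initial_inside Count the first outward exit of ions that
#'   begin inside the filter.
#' @return Data frame with `ion`, `entry_frame`, `completion_frame`,
#'   `direction` (1-based frames; `entry_frame < completion_frame`).
#' @export
detect_events <- function(z, bounds, count_initial_inside = TRUE) {
  if (inherits(z, "data.frame")) {
    z <- as.matrix(z[, setdiff(names(z), "time_ns"), drop = FALSE])
  } else if (is.null(dim(z))) {
    z <- matrix(z, ncol = 1)
  }
  if (!all(is.finite(z))) stop("non-finite z values", call. = FALSE)
  out <- lapply(seq_len(ncol(z)), function(i) {
    ev <- detect_events_one(z[, i], bounds, count_initial_inside)
    if (nrow(ev) > 0) cbind(ion = i, ev) else
      cbind(ion = integer(0), ev)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Water occupancy of the filter
#'
#' Counts water oxygens inside the filter per frame (axially within the
#' bounds and, when in-plane distances are given, within `radial_cut` of
#' the axis).
#'
#' @param z Per-water axial series (feature table, matrix or vector).
#' @param bounds A [filter_bounds()].
#' @param xy Optional matching in-plane distance series.
#' @return List with `occupancy` (integer per frame) and
#'   `first_exit_frame` (first frame with zero occupancy, or `NA` if the
#'   filter never empties).
#' @export
water_occupancy <- function(z, bounds, xy = NULL) {
  if (inherits(z, "data.frame"))
    z <- as.matrix(z[, setdiff(names(z), "time_ns"), drop = FALSE])
  if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  inside <- z >= bounds$z_low & z <= bounds$z_high
  if (!is.null(xy)) {
    if (inherits(xy, "data.frame"))
      xy <- as.matrix(xy[, setdiff(names(xy), "time_ns"), drop = FALSE])
    if (is.null(dim(xy))) xy <- matrix(xy, ncol = 1)
    inside <- inside & xy <= bounds$radial_cut
  }
  occ <- as.integer(rowSums(inside))
  empty <- which(occ == 0)
  list(occupancy = occ,
       first_exit_frame = if (length(empty) > 0) empty[1] else NA_integer_)
}

#' Keep events occurring after water exit
#'
#' Events complete only after the filter has emptied of water; if it
#' never empties no event is countable.
#'
#' @param events Data frame from [detect_events()].
#' @param first_exit_frame Frame of first zero water occupancy (`NA` if
#'   none).
#' @return The filtered events data frame.
#' @export
filter_events_after_water_exit <- function(events, first_exit_frame) {
  if (is.na(first_exit_frame)) return(events[0, , drop = FALSE])
  events[events$completion_frame >= first_exit_frame, , drop = FALSE]
}

ELEMENTARY_CHARGE <- 1.602176634e-19    # C

#' Single-replica conductance from an event count
#'
#' `G[pS] = N e / (T V)` with `N` the number of conduction events, `T`
#' the duration and `V` the membrane potential.
#'
#' @param n_events Number of conduction events.
#' @param duration_us Replica duration in microseconds.
#' @param voltage_mV Membrane potential in millivolts (non-zero).
#' @return Conductance in picosiemens.
#' @export
replica_conductance <- function(n_events, duration_us, voltage_mV) {
  stopifnot(n_events >= 0, duration_us > 0)
  if (voltage_mV == 0)
    stop("conductance is undefined at 0 mV", call. = FALSE)
  n_events * ELEMENTARY_CHARGE /
    (duration_us * 1e-6 * voltage_mV * 1e-3) * 1e12
}

#' Replica-averaged conductance
#'
#' Per-replica conductances via [replica_conductance()]; the mean and
#' sample standard deviation (n - 1 denominator) over replicas, zero
#' event counts contributing 0 pS (not dropped).
#'
#' @param counts Integer event counts, one per replica.
#' @param durations_us Durations (microseconds), recycled if scalar.
#' @param voltage_mV Membrane potential (millivolts).
#' @return List of class `pf_conductance`: `per_replica` (pS), `mean`,
#'   `sd`, `n_replicas`.
#' @export
aggregate_conductance <- function(counts, durations_us, voltage_mV) {
  if (length(durations_us) == 1)
    durations_us <- rep(durations_us, length(counts))
  stopifnot(length(durations_us) == length(counts))
  g <- mapply(replica_conductance, counts, durations_us,
              MoreArgs = list(voltage_mV = voltage_mV))
  structure(list(per_replica = g, mean = mean(g),
                 sd = if (length(g) > 1) stats::sd(g) else NA_real_,
                 n_replicas = length(g)),
            class = "pf_conductance")
}

#' @export
print.pf_conductance <- function(x, ...) {
  cat(sprintf("conductance: %.1f +/- %.1f pS (n = %d)\n",
              round_half_up(x$mean, 1), round_half_up(x$sd, 1),
              x$n_replicas))
  invisible(x)
}

#' Constant electric field for a transmembrane potential
#'
#' The applied field along z is the potential divided by the full box
#' length, `E_z = dV / L_z`.
#'
#' @param voltage_mV Transmembrane potential (millivolts).
#' @param box_length_z Box length along z (Angstrom).
#' @return Field in mV/Angstrom (sign follows the voltage).
#' @export
constant_field <- function(voltage_mV, box_length_z) {
  stopifnot(box_length_z > 0)
  voltage_mV / box_length_z
}
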