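#' Shipped study bookkeeping tables
#'
#' The package ships the printed per-run summary of the force-field
#' comparison study (32 one-microsecond replicas: force field, initial
#' filter ion configuration, membrane potential, prevalent gating state,
#' lipid cavity flag, observed conduction events) and the printed
#' relative-population table of the recurrent filter states. They drive
#' the conductance and population bookkeeping without requiring the
#' (undeposited) raw trajectories.
#'
#' @return `study_registry()`: the replica registry data frame (see
#'   [load_replica_registry()]). `study_populations()`: a matrix of
#'   relative populations (%) with conditions as columns, plus a
#'   `boundaries` attribute.
#' @export
study_registry <- function() {
  load_replica_registry(system.file("extdata", "table1_registry.yaml",
                                    package = "poreflow"))
}

#' @rdname study_registry
#' @export
study_populations <- function() {
  df <- utils::read.csv(system.file("extdata", "table2_populations.csv",
                                    package = "poreflow"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:2)])
  rownames(m) <- df$state
  attr(m, "boundaries") <- stats::setNames(df$boundaries, df$state)
  m
}

#' Conductance line for one study condition
#'
#' Recomputes a printed "conductance" line of the study summary from the
#' registry's event counts: per-replica conductances via
#' [replica_conductance()], averaged with sample SD.
#'
#' @param registry A registry data frame with an `events` column.
#' @param force_field,init_config,voltage_mV Condition selectors.
#' @return A `pf_conductance` (see [aggregate_conductance()]).
#' @export
condition_conductance <- function(registry, force_field, init_config,
                                  voltage_mV) {
  rows <- registry[registry$force_field == force_field &
                     registry$init_config == init_config &
                     registry$voltage_mV == voltage_mV, ]
  if (nrow(rows) == 0) stop("no replicas match that condition",
                            call. = FALSE)
  aggregate_conductance(rows$events, rows$duration_us, voltage_mV)
}
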