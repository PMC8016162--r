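#' @title Pipeline orchestration
#' @name pipeline
#' @description Runs the full analysis over a registry of replicas from a
#'   single YAML configuration: featurization input, sketch-map
#'   embedding and DBSCAN clustering per condition, state labeling and
#'   population tables, permeation detection with conductance
#'   aggregation, gating classification and lipid flags. Reports are
#'   machine-readable JSON embedding the seed, a config fingerprint and
#'   the package version, so identical inputs give identical reports.
NULL

#' Write a synthetic replica directory
#'
#' Emits the CSV inputs [run_pipeline()] consumes for one replica:
#' `dihedrals.csv`, `signatures.csv`, `ions.csv`, `gating.csv`,
#' `lipid.csv` and a `truth.json` ground-truth sidecar.
#'
#' @param dir Output directory (created).
#' @param kinetics A [state_kinetics_spec()].
#' @param ion_spec An [ion_trace_spec()].
#' @param n_frames Frames per series.
#' @param frame_interval Frame spacing (ns).
#' @param seed RNG seed.
#' @param gating Named list of [simulate_gating_trace()] arguments.
#' @param lipid Named list of [simulate_lipid_trace()] arguments.
#' @return The ground-truth list, invisibly.
#' @export
write_synthetic_replica <- function(dir, kinetics, ion_spec,
                                    n_frames = 5000, frame_interval = 0.1,
                                    seed = 1, gating = list(),
                                    lipid = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(kinetics$signatures))
    stop("the kinetics spec must carry per-state flip signatures",
         call. = FALSE)
  dih <- simulate_dihedral_series(kinetics, n_frames, frame_interval,
                                  seed = seed)
  ions <- simulate_ion_traces(ion_spec, n_frames, frame_interval,
                              seed = seed + 1)
  gat <- do.call(simulate_gating_trace,
                 c(list(n_frames = n_frames,
                        frame_interval = frame_interval, seed = seed + 2),
                   gating))
  lip <- do.call(simulate_lipid_trace,
                 c(list(n_frames = n_frames,
                        frame_interval = frame_interval, seed = seed + 3),
                   lipid))
  write_feature_table(
    feature_table(dih$times, as.data.frame(dih$angles)),
    file.path(dir, "dihedrals.csv"))
  utils::write.csv(
    data.frame(time_ns = dih$times, signature = dih$signatures,
               state = dih$states, stringsAsFactors = FALSE),
    file.path(dir, "signatures.csv"), row.names = FALSE)
  write_feature_table(ions$features, file.path(dir, "ions.csv"))
  names(gat$features)[2] <- "d_AB"
  gat$features$d_BA <- gat$features$d_AB     # single-interface surrogate
  write_feature_table(gat$features, file.path(dir, "gating.csv"))
  write_feature_table(lip$features, file.path(dir, "lipid.csv"))
  truth <- list(n_events = nrow(ions$events),
                events = ions$events,
                state_occupancy = as.list(table(dih$states) / n_frames),
                down_fraction = gat$down_fraction,
                lipid_fraction = lip$fraction)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(truth)
}

default_config <- function() {
  list(
    embedding = list(method = "sketchmap", sigma = 60, A = 12, B = 12,
                     a = 1, b = 2, n_landmarks = 150, metric = "periodic"),
    dbscan = list(eps = 15, min_points = 3, window = NULL),
    permeation = list(z_low = -6, z_high = 6, radial_cut = 4,
                      count_initial_inside = TRUE),
    gating = list(threshold = 8, prevalence = 0.5, min_dwell = 1),
    lipids = list(cutoff = 10, fraction_rule = 0.5),
    seed = 1
  )
}

# resolve a path against the config base directory; absolute paths pass
# through unchanged
resolve_path <- function(base, p) {
  ifelse(startsWith(p, "/"), p, file.path(base, p))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Validate a pipeline configuration
#'
#' Loads a YAML config (or takes a list), fills defaults, and collects
#' every validation error rather than failing at the first.
#'
#' @param config Path to a YAML config file, or a config list.
#' @param base_dir Directory against which relative paths resolve.
#' @return List with `config` (defaults merged) and `errors` (character
#'   vector; empty when valid).
#' @export
validate_config <- function(config, base_dir = ".") {
  if (is.character(config)) {
    if (!file.exists(config))
      return(list(config = NULL,
                  errors = paste("config file not found:", config)))
    base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_config(), config)
  cfg$base_dir <- base_dir
  errors <- character(0)
  add <- function(msg) errors <<- c(errors, msg)
  if (is.null(cfg$registry)) add("missing key: registry")
  else {
    reg_path <- resolve_path(base_dir, cfg$registry)
    if (!file.exists(reg_path)) add(paste("registry not found:", reg_path))
    else {
      reg <- tryCatch(load_replica_registry(reg_path),
                      error = function(e) conditionMessage(e))
      if (is.character(reg)) add(paste("registry:", reg))
      else if (is.null(reg$voltage_mV)) add("registry: missing voltage_mV")
    }
  }
  if (is.null(cfg$output_dir)) add("missing key: output_dir")
  if (cfg$dbscan$eps <= 0) add("dbscan.eps must be > 0")
  if (cfg$dbscan$min_points < 1) add("dbscan.min_points must be >= 1")
  if (!is.null(cfg$dbscan$window) && length(cfg$dbscan$window) != 4)
    add("dbscan.window must be c(xmin, xmax, ymin, ymax)")
  if (cfg$embedding$sigma <= 0) add("embedding.sigma must be > 0")
  if (!cfg$embedding$metric %in% c("euclidean", "periodic"))
    add("embedding.metric must be euclidean or periodic")
  if (cfg$permeation$z_low >= cfg$permeation$z_high)
    add("permeation.z_low must be below z_high")
  if (is.null(cfg$seed)) add("missing key: seed")
  list(config = cfg, errors = errors)
}

config_fingerprint <- function(cfg) {
  cfg$base_dir <- NULL
  fnv1a_hash(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA))
}

#' Run the full analysis pipeline
#'
#' Per condition (force field x initial configuration): pools the
#' replicas' dihedral features, embeds them with sketch-map, clusters the
#' map with DBSCAN and labels states from the per-frame flip signatures.
#' Per replica: permeation events (gated on water exit when a water trace
#' is present), gating classification of both interfaces and the lipid
#' cavity flag. Conductance is aggregated per condition and voltage over
#' its replicas. Writes one JSON report per replica plus an aggregate
#' report; every report embeds the seed, config fingerprint and package
#' version.
#'
#' @param config Path to a YAML config or a config list (see
#'   [validate_config()]). Registry runs must carry a `path` field
#'   pointing at a replica directory written by
#'   [write_synthetic_replica()] (or with the same layout).
#' @return The aggregate report list, invisibly. Reports are written
#'   under `output_dir`.
#' @export
run_pipeline <- function(config) {
  val <- validate_config(config)
  if (length(val$errors) > 0)
    stop("invalid configuration:\n  ", paste(val$errors, collapse = "\n  "),
         call. = FALSE)
  cfg <- val$config
  out_dir <- resolve_path(cfg$base_dir, cfg$output_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  registry <- load_replica_registry(resolve_path(cfg$base_dir,
                                                 cfg$registry))
  if (is.null(registry$path))
    stop("stage core_io failed: registry runs need a 'path' field",
         call. = FALSE)
  fingerprint <- config_fingerprint(cfg)
  meta <- list(seed = cfg$seed, config_hash = fingerprint,
               package_version = as.character(utils::packageVersion("poreflow")))

  registry$condition <- paste(registry$force_field, registry$init_config,
                              sep = "-")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
  }

  # ---- per-condition embedding, clustering, populations -----------------
  populations <- list()
  per_frame <- list()
  for (cond in unique(registry$condition)) {
    runs <- registry[registry$condition == cond, ]
    dih <- list()
    sigs <- list()
    for (r in seq_len(nrow(runs))) {
      rep_dir <- resolve_path(cfg$base_dir, runs$path[r])
      ft <- stage("featurize",
                  read_feature_table(file.path(rep_dir, "dihedrals.csv")))
      sg <- stage("featurize",
                  utils::read.csv(file.path(rep_dir, "signatures.csv"),
                                  stringsAsFactors = FALSE))
      dih[[r]] <- as.matrix(ft[, -1, drop = FALSE])
      sigs[[r]] <- as.character(sg$signature)
    }
    x <- do.call(rbind, dih)
    sig <- unlist(sigs)
    emb <- stage("embed", sketchmap_embed(
      x, sketchmap_params(sigma = cfg$embedding$sigma, A = cfg$embedding$A,
                          B = cfg$embedding$B, a = cfg$embedding$a,
                          b = cfg$embedding$b,
                          n_landmarks = min(cfg$embedding$n_landmarks,
                                            nrow(x))),
      seed = cfg$seed, metric = cfg$embedding$metric))
    cl <- stage("states", dbscan_cluster(
      emb$coords, eps = cfg$dbscan$eps, min_points = cfg$dbscan$min_points,
      window = cfg$dbscan$window))
    trace <- stage("states", label_states(cl, sig))
    per_frame[[cond]] <- trace
    populations[[cond]] <- trace
  }
  pop <- population_table(populations)

  # ---- per-replica permeation, gating, lipids ---------------------------
  replica_reports <- list()
  cond_counts <- list()
  for (r in seq_len(nrow(registry))) {
    run <- registry[r, ]
    rep_dir <- resolve_path(cfg$base_dir, run$path)
    ions <- stage("permeation",
                  read_feature_table(file.path(rep_dir, "ions.csv")))
    bounds <- filter_bounds(cfg$permeation$z_low, cfg$permeation$z_high,
                            cfg$permeation$radial_cut)
    events <- stage("permeation", detect_events(
      ions, bounds,
      count_initial_inside = cfg$permeation$count_initial_inside))
    water_path <- file.path(rep_dir, "water.csv")
    if (file.exists(water_path)) {
      wz <- read_feature_table(water_path)
      occ <- water_occupancy(wz, bounds)
      events <- filter_events_after_water_exit(events, occ$first_exit_frame)
    }
    gat <- stage("gating",
                 read_feature_table(file.path(rep_dir, "gating.csv")))
    ga <- classify_updown(gat$d_AB, threshold = cfg$gating$threshold,
                          prevalence = cfg$gating$prevalence)
    gb <- classify_updown(gat$d_BA, threshold = cfg$gating$threshold,
                          prevalence = cfg$gating$prevalence)
    lip <- stage("lipids",
                 read_feature_table(file.path(rep_dir, "lipid.csv")))
    flag <- lipid_cavity_flag(lip, cutoff = cfg$lipids$cutoff,
                              fraction_rule = cfg$lipids$fraction_rule,
                              lipid_id = run$path)
    n_outward <- sum(events$direction == 1)   # conduction = outward crossings
    key <- paste(run$condition, run$voltage_mV, sep = "@")
    cond_counts[[key]] <- rbind(
      cond_counts[[key]],
      data.frame(replica = run$replica, n_events = n_outward,
                 duration_us = run$duration_us))
    rep_report <- c(meta, list(
      replica = run$replica, condition = run$condition,
      voltage_mV = run$voltage_mV, duration_us = run$duration_us,
      n_events = n_outward,
      prevalent_state = joint_gating_label(ga, gb),
      down_fraction = c(A = ga$down_fraction, B = gb$down_fraction),
      lipid_in_cavity = flag$in_cavity,
      lipid_cavity_fraction = flag$fraction))
    replica_reports[[r]] <- rep_report
    jsonlite::write_json(
      rep_report,
      file.path(out_dir, sprintf("replica_%s_%s_%d.json", run$condition,
                                 run$voltage_mV, run$replica)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  conductance <- list()
  for (key in names(cond_counts)) {
    cc <- cond_counts[[key]]
    voltage <- as.numeric(sub(".*@", "", key))
    conductance[[key]] <- if (voltage == 0) {
      list(events = cc$n_events, mean_pS = NA, sd_pS = NA)
    } else {
      agg <- aggregate_conductance(cc$n_events, cc$duration_us, voltage)
      list(events = cc$n_events, mean_pS = agg$mean, sd_pS = agg$sd)
    }
  }

  aggregate <- c(meta, list(
    populations = as.data.frame(pop),
    conductance = conductance,
    replicas = lapply(replica_reports, function(x)
      x[c("condition", "voltage_mV", "replica", "n_events",
          "prevalent_state", "lipid_in_cavity")])))
  jsonlite::write_json(aggregate, file.path(out_dir, "aggregate.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(aggregate)
}

#' Check a pipeline report against the shipped schema
#'
#' Structural validation: required keys present with the expected types,
#' per the JSON schema in `inst/extdata/report-schema.json`.
#'
#' @param report Parsed report list (from `jsonlite::read_json`) or a
#'   path to a report file.
#' @return `TRUE` if valid, otherwise a character vector of problems.
#' @export
check_report_schema <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(system.file("extdata",
                                            "report-schema.json",
                                            package = "poreflow"))
  problems <- character(0)
  for (key in names(schema$required)) {
    if (is.null(report[[key]]))
      problems <- c(problems, paste("missing key:", key))
  }
  if (length(problems) == 0) TRUE else problems
}
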