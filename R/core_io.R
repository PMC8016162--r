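#' @title Structure, trajectory and feature-table input/output
#' @name core_io
#' @description Readers and writers for the plain formats the pipeline
#'   consumes: PDB structures (ATOM/HETATM subset), CHARMM-style DCD
#'   trajectories, CSV feature tables, and the YAML run registry that
#'   mirrors the simulation bookkeeping (force field, initial filter
#'   configuration, voltage, replica, duration).
#'
#'   Units are fixed package-wide: coordinates and distances in Angstrom,
#'   times in nanoseconds internally, run durations in microseconds in the
#'   registry (converted by [us_to_ns()]). Residue numbering always follows
#'   the input file's author numbering.
NULL

#' Construct an atom table
#'
#' @param atom_name,residue_name,chain_id character vectors.
#' @param residue_index integer vector (author numbering).
#' @param x,y,z numeric coordinates in Angstrom.
#' @return A `data.frame` of class `pf_atoms` with one row per atom.
#' @export
atom_table <- function(atom_name, residue_name, residue_index, chain_id,
                       x, y, z) {
  df <- data.frame(
    atom_name = as.character(atom_name),
    residue_name = as.character(residue_name),
    residue_index = as.integer(residue_index),
    chain_id = as.character(chain_id),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    stringsAsFactors = FALSE
  )
  validate_atom_table(df)
  class(df) <- c("pf_atoms", "data.frame")
  df
}

validate_atom_table <- function(df) {
  if (nrow(df) == 0) stop("empty structure: no atoms", call. = FALSE)
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)) || !all(is.finite(df$z)))
    stop("non-finite atom coordinates", call. = FALSE)
  key <- paste(df$chain_id, df$residue_index, df$atom_name, sep = "/")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate atom record (chain/residue/atom): ", dup, call. = FALSE)
  }
  invisible(df)
}

#' Read a PDB structure into an atom table
#'
#' Parses ATOM/HETATM records (via `bio3d::read.pdb`) preserving file
#' order, chain ids and author residue numbering. Structures with
#' insertion codes are rejected: the pipeline's residue addressing is
#' (chain, residue number) only.
#'
#' @param path Path to a PDB file.
#' @return An atom table (see [atom_table()]).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("empty structure: no ATOM/HETATM records in ", path,
                      call. = FALSE)
  # pre-scan for malformed coordinate fields so errors carry line numbers
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed PDB record at line ", i, ": too short", call. = FALSE)
    coords <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))))
    if (any(is.na(coords)))
      stop("malformed PDB record at line ", i, ": bad coordinate field",
           call. = FALSE)
    if (substr(ln, 27, 27) != " ")
      stop("insertion code at line ", i,
           " not supported (residue addressing is chain + number)",
           call. = FALSE)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  atom_table(
    atom_name = a$elety, residue_name = a$resid,
    residue_index = a$resno, chain_id = ifelse(is.na(a$chain), "", a$chain),
    x = a$x, y = a$y, z = a$z
  )
}

#' Write an atom table as a PDB file
#'
#' @param atoms An atom table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path) {
  validate_atom_table(atoms)
  name4 <- ifelse(nchar(atoms$atom_name) < 4,
                  sprintf(" %-3s", atoms$atom_name),
                  substr(atoms$atom_name, 1, 4))
  lines <- sprintf(
    "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
    seq_len(nrow(atoms)), name4, atoms$residue_name,
    substr(paste0(atoms$chain_id, " "), 1, 1), atoms$residue_index,
    atoms$x, atoms$y, atoms$z, 1, 0
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Construct a trajectory object
#'
#' @param atoms Atom table defining the (fixed) atom order.
#' @param coords Numeric array `n_frames x n_atoms x 3` in Angstrom, or an
#'   `n_atoms x 3` matrix for a single frame.
#' @param frame_interval Time between stored frames in ns.
#' @param box Optional per-frame box lengths, `n_frames x 3` in Angstrom.
#' @return An object of class `pf_traj`.
#' @export
trajectory <- function(atoms, coords, frame_interval = 1, box = NULL) {
  validate_atom_table(atoms)
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, dim(coords)))
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (dim(coords)[1] < 1) stop("trajectory must have at least one frame",
                               call. = FALSE)
  if (dim(coords)[2] != nrow(atoms))
    stop("coordinate array has ", dim(coords)[2], " atoms but atom table has ",
         nrow(atoms), call. = FALSE)
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0 (ns)", call. = FALSE)
  if (!is.null(box)) {
    box <- matrix(box, ncol = 3)
    stopifnot(nrow(box) == dim(coords)[1])
  }
  structure(list(atoms = atoms, coords = coords,
                 frame_interval = frame_interval, box = box),
            class = "pf_traj")
}

#' @export
print.pf_traj <- function(x, ...) {
  cat("pf_traj:", dim(x$coords)[1], "frames x", dim(x$coords)[2], "atoms,",
      "frame interval", x$frame_interval, "ns\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]

#' Number of frames in a trajectory
#' @param traj A `pf_traj`.
#' @return Integer frame count.
#' @export
traj_n_frames <- function(traj) n_frames(traj)

#' Frame times of a trajectory (ns)
#' @param traj A `pf_traj`.
#' @return Numeric vector, first frame at time 0.
#' @export
traj_times <- function(traj) (seq_len(n_frames(traj)) - 1) * traj$frame_interval

# ---- DCD ------------------------------------------------------------------

# Minimal CHARMM-DCD writer (bio3d reads but does not write DCD). Record
# structure: Fortran unformatted records with 4-byte length markers; header
# block "CORD" + 20 control ints (slot 10 holds the timestep as a float,
# slot 11 the unit-cell flag, slot 20 the CHARMM version), title block,
# atom-count block, then per frame an optional 6-double cell record and one
# float record per coordinate axis.
write_dcd <- function(coords, path, cell = NULL, delta_ns = 1) {
  nf <- dim(coords)[1]
  na <- dim(coords)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wdbl <- function(x) writeBin(as.numeric(x), con, size = 8, endian = "little")
  has_cell <- !is.null(cell)
  wint(84)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  wint(c(nf, 1, 1, nf, 0, 0, 0, 0, 0))     # icntrl 1..9
  wflt(delta_ns)                           # icntrl 10: timestep
  wint(c(if (has_cell) 1 else 0, rep(0, 8), 24))  # icntrl 11..20
  wint(84)
  title <- formatC("Synthetic trajectory written by poreflow", width = -80)
  wint(4 + 80)
  wint(1)
  writeChar(title, con, nchars = 80, eos = NULL)
  wint(4 + 80)
  wint(4); wint(na); wint(4)
  for (f in seq_len(nf)) {
    if (has_cell) {
      b <- cell[f, ]
      wint(48)
      wdbl(c(b[1], 0, b[2], 0, 0, b[3]))   # a, cos(g), b, cos(b), cos(a), c
      wint(48)
    }
    for (ax in 1:3) {
      wint(4 * na); wflt(coords[f, , ax]); wint(4 * na)
    }
  }
  invisible(path)
}

# Read the DCD header enough to know frame layout; used to detect
# truncation before delegating the actual read to bio3d.
dcd_layout <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rint <- function(n = 1) readBin(con, "integer", n = n, size = 4,
                                  endian = "little")
  m1 <- rint()
  if (!identical(m1, 84L)) stop("not a DCD file (bad header record): ", path,
                                call. = FALSE)
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "CORD")) stop("not a DCD file (no CORD tag): ", path,
                                      call. = FALSE)
  icntrl <- rint(20)
  rint()                                    # closing marker
  tlen <- rint()
  seek(con, where = tlen, origin = "current")
  rint()
  rint(); natom <- rint(); rint()
  header_bytes <- seek(con, where = NA)
  nframes <- icntrl[1]
  has_cell <- icntrl[11] == 1
  frame_bytes <- 3 * (8 + 4 * natom) + if (has_cell) (8 + 48) else 0
  list(natom = natom, nframes = nframes, has_cell = has_cell,
       header_bytes = header_bytes, frame_bytes = frame_bytes,
       file_bytes = file.size(path))
}

#' Read a trajectory file against a known structure
#'
#' Reads a DCD trajectory (via `bio3d::read.dcd`), checks the atom count
#' against `atoms`, and returns coordinates in Angstrom. Truncated files
#' are rejected rather than silently short-read. XTC input is not
#' supported; convert to DCD first.
#'
#' @param atoms Atom table matching the trajectory's atom order.
#' @param path Path to a `.dcd` file.
#' @param frame_interval Time between stored frames in ns.
#' @return A `pf_traj`.
#' @export
read_trajectory <- function(atoms, path, frame_interval = 1) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.xtc$", path, ignore.case = TRUE))
    stop("XTC input is not supported; convert the trajectory to DCD",
         call. = FALSE)
  lay <- dcd_layout(path)
  if (lay$natom != nrow(atoms))
    stop("atom-count mismatch: trajectory has ", lay$natom,
         " atoms but structure has ", nrow(atoms), call. = FALSE)
  expected <- lay$header_bytes + lay$nframes * lay$frame_bytes
  if (lay$file_bytes < expected)
    stop("truncated DCD: expected ", expected, " bytes for ", lay$nframes,
         " frames, file has ", lay$file_bytes, call. = FALSE)
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  nf <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nf, lay$natom, 3))
  for (ax in 1:3) coords[, , ax] <- xyz[, seq(ax, ncol(xyz), by = 3)]
  trajectory(atoms, coords, frame_interval = frame_interval)
}

#' Write a trajectory as a DCD file
#'
#' @param traj A `pf_traj`.
#' @param path Output path (`.dcd`).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write_dcd(traj$coords, path, cell = traj$box,
            delta_ns = traj$frame_interval)
  invisible(path)
}

# ---- Feature tables -------------------------------------------------------

#' Construct a feature table
#'
#' A feature table is a data frame whose first column `time_ns` is a
#' strictly increasing time axis and whose remaining columns are numeric
#' per-frame series (angles in degrees, distances in Angstrom, occupancies
#' as counts).
#'
#' @param time_ns Strictly increasing numeric times.
#' @param ... Named numeric series, each the length of `time_ns`.
#' @return A `data.frame` of class `pf_features`.
#' @export
feature_table <- function(time_ns, ...) {
  series <- list(...)
  if (length(series) == 1 && is.list(series[[1]]) && is.null(names(series)[1]))
    series <- series[[1]]
  df <- data.frame(time_ns = as.numeric(time_ns), series, check.names = FALSE)
  validate_feature_table(df)
  class(df) <- c("pf_features", "data.frame")
  df
}

validate_feature_table <- function(df) {
  if (names(df)[1] != "time_ns")
    stop("feature table must have 'time_ns' as its first column",
         call. = FALSE)
  t <- df$time_ns
  if (any(diff(t) <= 0)) stop("times must be strictly increasing",
                              call. = FALSE)
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("all feature-table columns must be numeric", call. = FALSE)
  invisible(df)
}

#' Write / read a feature table as CSV
#'
#' CSV dialect: comma separator, `.` decimal, UTF-8, mandatory header.
#' Round-trips are lossless to at least 6 significant digits (values are
#' written with 15 digits).
#'
#' @param table A feature table.
#' @param path CSV path.
#' @return `path` invisibly (write); a `pf_features` data frame (read).
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  validate_feature_table(df)
  class(df) <- c("pf_features", "data.frame")
  df
}

# ---- Replica registry -----------------------------------------------------

#' Load a replica registry
#'
#' The registry is a YAML file with a top-level `runs:` list; each run
#' carries `force_field`, `init_config` (KK or KWK), `voltage_mV`,
#' `replica` and `duration_us`, plus any extra fields (observed event
#' counts, prevalent gating state, lipid flags, data paths) which are kept
#' as-is.
#'
#' @param path Path to the YAML registry.
#' @return A `data.frame` with one row per run.
#' @export
load_replica_registry <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  runs <- doc$runs
  if (is.null(runs)) runs <- list()
  required <- c("force_field", "init_config", "voltage_mV", "replica",
                "duration_us")
  rows <- lapply(seq_along(runs), function(i) {
    run <- runs[[i]]
    missing <- setdiff(required, names(run))
    if (length(missing) > 0)
      stop("registry run ", i, " is missing field(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    if (!run$init_config %in% c("KK", "KWK"))
      stop("registry run ", i, ": init_config must be KK or KWK",
           call. = FALSE)
    if (run$duration_us <= 0)
      stop("registry run ", i, ": duration_us must be > 0", call. = FALSE)
    as.data.frame(run[!vapply(run, is.null, logical(1))],
                  stringsAsFactors = FALSE)
  })
  if (length(rows) == 0)
    return(data.frame(force_field = character(), init_config = character(),
                      voltage_mV = numeric(), replica = integer(),
                      duration_us = numeric()))
  out <- do.call(rbind, lapply(rows, function(r) {
    cols <- unique(unlist(lapply(rows, names)))
    for (c in setdiff(cols, names(r))) r[[c]] <- NA
    r[cols]
  }))
  rownames(out) <- NULL
  out
}

#' Total simulation time of a registry
#' @param registry Data frame from [load_replica_registry()].
#' @return Total duration in microseconds.
#' @export
registry_total_time <- function(registry) {
  if (nrow(registry) == 0) return(0)
  sum(registry$duration_us)
}

#' Convert microseconds to nanoseconds
#' @param us Duration(s) in microseconds.
#' @return Duration(s) in nanoseconds.
#' @export
us_to_ns <- function(us) us * 1000
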