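#' @title Synthetic trajectory generators
#' @name synthetic_data
#' @description Generates every input the analysis pipeline consumes, with
#'   exact ground truth: a four-fold symmetric selectivity-filter geometry
#'   with controllable carbonyl flips, Markov-switching 44-dimensional
#'   dihedral time series with von Mises angular noise, K+ axial traces
#'   with an exact number of planted filter crossings, telegraph-process
#'   helix-distance (gating) traces, and lipid headgroup in-plane-distance
#'   traces with cavity excursions. All generators are pure functions of
#'   their spec and seed.
NULL

# NeRF atom placement: new atom bonded to C at distance r, bond angle
# theta (B-C-new, degrees), torsion phi (A-B-C-new, degrees).
place_atom <- function(A, B, C, r, theta, phi) {
  th <- deg2rad(theta)
  ph <- deg2rad(phi)
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-r * cos(th), r * sin(th) * cos(ph), r * sin(th) * sin(ph))
  C + d[1] * bc + d[2] * m + d[3] * n
}

rot_z <- function(deg) {
  t <- deg2rad(deg)
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

#' Selectivity-filter geometry spec
#'
#' @param n_chains Number of P-loops (4).
#' @param residues_per_chain Filter motif length (5).
#' @param pore_radius Radial distance of the filter backbone from the pore
#'   axis (Angstrom).
#' @param rise_per_residue Nominal axial spacing between coordination
#'   planes, used to lay out ion-site z positions (Angstrom).
#' @param flip_signature List of `c(chain, position)` pairs (1-based; the
#'   position is within the 5-residue motif) whose carbonyl points away
#'   from the axis.
#' @param angular_noise Von Mises jitter (degrees, roughly a standard
#'   deviation) applied to backbone/chi1 torsions and carbonyl directions;
#'   0 gives exact geometry.
#' @param phi,psi,chi1 Backbone and side-chain torsions (degrees) used to
#'   build each chain; constant along the chain.
#' @return A list of class `pf_sfgeom`.
#' @export
sf_geometry_spec <- function(n_chains = 4, residues_per_chain = 5,
                             pore_radius = 3, rise_per_residue = 3,
                             flip_signature = list(), angular_noise = 0,
                             phi = -120, psi = 130, chi1 = -60) {
  stopifnot(n_chains >= 1, residues_per_chain >= 1, pore_radius > 0,
            angular_noise >= 0)
  for (fl in flip_signature) {
    if (length(fl) != 2 || fl[1] < 1 || fl[1] > n_chains ||
        fl[2] < 1 || fl[2] > residues_per_chain)
      stop("flip_signature entries must be c(chain, position) within range",
           call. = FALSE)
  }
  structure(list(n_chains = n_chains,
                 residues_per_chain = residues_per_chain,
                 pore_radius = pore_radius,
                 rise_per_residue = rise_per_residue,
                 flip_signature = flip_signature,
                 angular_noise = angular_noise,
                 phi = phi, psi = psi, chi1 = chi1),
            class = "pf_sfgeom")
}

#' Filter selection matching the synthetic geometry
#'
#' @param spec A [sf_geometry_spec()].
#' @param first_res Residue index of the first motif residue (author-style
#'   numbering; default 129 as in the reference structure).
#' @return A [sf_selection()].
#' @export
synthetic_sf_selection <- function(spec, first_res = 129) {
  sf_selection(chain_id = LETTERS[seq_len(spec$n_chains)],
               first_res = rep(first_res, spec$n_chains))
}

# kappa giving roughly sd_deg of circular spread
noise_kappa <- function(sd_deg) if (sd_deg <= 0) Inf else 1 / deg2rad(sd_deg)^2

vm_jitter <- function(n, sd_deg) {
  if (sd_deg <= 0) return(rep(0, n))
  rvonmises_deg(n, 0, noise_kappa(sd_deg))
}

#' Build a single-frame synthetic selectivity filter
#'
#' Places `n_chains` copies of a torsion-defined backbone (prev residue +
#' 5-residue motif + next residue; atoms N, CA, C, plus O on the motif
#' residues and CB/OG1 on the bottom threonine) symmetrically around the
#' z axis at radius `pore_radius`. Carbonyl oxygens of motif residues
#' point toward the axis unless the residue is listed in
#' `spec$flip_signature`, in which case they point away. With
#' `angular_noise = 0` the construction is exact and identical across
#' chains (up to rotation about z).
#'
#' @param spec A [sf_geometry_spec()].
#' @param seed Seed for the angular jitter (ignored at zero noise).
#' @param first_res First motif residue index (default 129).
#' @return A single-frame `pf_traj`.
#' @export
build_filter_coordinates <- function(spec, seed = NULL, first_res = 129) {
  stopifnot(inherits(spec, "pf_sfgeom"))
  with_seed(seed, {
    nres <- spec$residues_per_chain + 2L       # prev + motif + next
    rows <- list()
    for (k in seq_len(spec$n_chains)) {
      phi_k <- spec$phi + vm_jitter(nres, spec$angular_noise)
      psi_k <- spec$psi + vm_jitter(nres, spec$angular_noise)
      chi_k <- spec$chi1 + vm_jitter(1, spec$angular_noise)
      # seed atoms of the chain template
      N <- matrix(NA_real_, nres, 3)
      CA <- matrix(NA_real_, nres, 3)
      Cc <- matrix(NA_real_, nres, 3)
      N[1, ] <- c(0, 0, 0)
      CA[1, ] <- c(1.46, 0, 0)
      Cc[1, ] <- CA[1, ] + 1.52 * c(cos(deg2rad(69)), sin(deg2rad(69)), 0)
      for (j in seq_len(nres - 1)) {
        N[j + 1, ] <- place_atom(N[j, ], CA[j, ], Cc[j, ], 1.33, 117,
                                 psi_k[j])
        CA[j + 1, ] <- place_atom(CA[j, ], Cc[j, ], N[j + 1, ], 1.46, 121,
                                  180)
        Cc[j + 1, ] <- place_atom(Cc[j, ], N[j + 1, ], CA[j + 1, ], 1.52,
                                  111, phi_k[j + 1])
      }
      # align the motif CA axis with +z and put the centroid at the pore
      # radius on azimuth 0, then rotate into the chain's sector
      motif <- 2:(nres - 1)
      v <- CA[nres - 1, ] - CA[2, ]
      v <- v / sqrt(sum(v^2))
      # rotation taking v -> e_z (Rodrigues)
      ez <- c(0, 0, 1)
      ax <- c(v[2] * ez[3] - v[3] * ez[2],
              v[3] * ez[1] - v[1] * ez[3],
              v[1] * ez[2] - v[2] * ez[1])
      s <- sqrt(sum(ax^2))
      if (s < 1e-12) {
        R <- diag(3) * sign(sum(v * ez))
      } else {
        ax <- ax / s
        ang <- acos(max(-1, min(1, sum(v * ez))))
        K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0),
                    3, 3)
        R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
      }
      xyz <- rbind(N, CA, Cc) %*% t(R)
      N <- xyz[seq_len(nres), ]
      CA <- xyz[nres + seq_len(nres), ]
      Cc <- xyz[2 * nres + seq_len(nres), ]
      cen <- colMeans(CA[motif, , drop = FALSE])
      shift <- c(spec$pore_radius, 0, 0) - cen
      N <- sweep(N, 2, -shift)
      CA <- sweep(CA, 2, -shift)
      Cc <- sweep(Cc, 2, -shift)
      Rk <- rot_z(360 / spec$n_chains * (k - 1))
      N <- N %*% t(Rk)
      CA <- CA %*% t(Rk)
      Cc <- Cc %*% t(Rk)
      # carbonyl oxygens on the motif residues: radial in the xy plane,
      # inward unless flipped, with optional angular jitter about z
      flips <- vapply(spec$flip_signature,
                      function(fl) fl[1] == k, logical(1))
      flip_pos <- vapply(spec$flip_signature[flips],
                         function(fl) fl[2], numeric(1))
      chain_rows <- list()
      for (j in seq_len(nres)) {
        resi <- first_res - 2L + j             # j = 1 is the prev residue
        chain_rows[[length(chain_rows) + 1]] <- data.frame(
          atom_name = c("N", "CA", "C"),
          residue_name = if (j == 2) "THR" else "GLY",
          residue_index = resi, chain_id = LETTERS[k],
          x = c(N[j, 1], CA[j, 1], Cc[j, 1]),
          y = c(N[j, 2], CA[j, 2], Cc[j, 2]),
          z = c(N[j, 3], CA[j, 3], Cc[j, 3]), stringsAsFactors = FALSE)
        if (j >= 2 && j <= nres - 1) {
          pos <- j - 1L                        # motif position 1..5
          inward <- -Cc[j, 1:2]
          inward <- inward / sqrt(sum(inward^2))
          if (pos %in% flip_pos) inward <- -inward
          eta <- vm_jitter(1, spec$angular_noise)
          dir2 <- rot_z(eta)[1:2, 1:2] %*% inward
          O <- c(Cc[j, 1:2] + 1.23 * as.vector(dir2), Cc[j, 3])
          chain_rows[[length(chain_rows) + 1]] <- data.frame(
            atom_name = "O", residue_name = if (pos == 1) "THR" else "GLY",
            residue_index = resi, chain_id = LETTERS[k],
            x = O[1], y = O[2], z = O[3], stringsAsFactors = FALSE)
          if (pos == 1) {                      # bottom threonine side chain
            CB <- place_atom(Cc[j, ], N[j, ], CA[j, ], 1.53, 110, -122)
            OG1 <- place_atom(N[j, ], CA[j, ], CB, 1.42, 109, chi_k)
            chain_rows[[length(chain_rows) + 1]] <- data.frame(
              atom_name = c("CB", "OG1"), residue_name = "THR",
              residue_index = resi, chain_id = LETTERS[k],
              x = c(CB[1], OG1[1]), y = c(CB[2], OG1[2]),
              z = c(CB[3], OG1[3]), stringsAsFactors = FALSE)
          }
        }
      }
      rows[[k]] <- do.call(rbind, chain_rows)
    }
    df <- do.call(rbind, rows)
    atoms <- atom_table(df$atom_name, df$residue_name, df$residue_index,
                        df$chain_id, df$x, df$y, df$z)
    trajectory(atoms, as.matrix(df[, c("x", "y", "z")]), frame_interval = 1)
  })
}

#' State-kinetics spec for the dihedral generator
#'
#' @param labels Character state labels (e.g. `c("I", "II", "III")`).
#' @param rates `k x k` transition-rate matrix (per ns): off-diagonal
#'   entries are jump rates, rows sum to zero; must be irreducible.
#' @param means `k x 44` matrix of per-state mean dihedrals (degrees).
#' @param kappa Per-state von Mises concentration of the angular noise
#'   (scalar or length-k; `Inf` = no noise).
#' @param signatures Optional character vector of canonical flip-signature
#'   strings per state (see [signature_string()]), carried along as the
#'   ground truth consumed by [label_states()].
#' @return A list of class `pf_kinetics`.
#' @export
state_kinetics_spec <- function(labels, rates, means, kappa = 50,
                                signatures = NULL) {
  rates <- as.matrix(rates)
  means <- as.matrix(means)
  k <- length(labels)
  stopifnot(nrow(rates) == k, ncol(rates) == k, nrow(means) == k)
  if (any(rates[row(rates) != col(rates)] < 0))
    stop("off-diagonal rates must be >= 0", call. = FALSE)
  if (max(abs(rowSums(rates))) > 1e-8)
    stop("rate-matrix rows must sum to zero", call. = FALSE)
  if (!ctmc_is_irreducible(rates))
    stop("rate matrix is reducible: every state must be reachable",
         call. = FALSE)
  if (length(kappa) == 1) kappa <- rep(kappa, k)
  if (!is.null(signatures)) stopifnot(length(signatures) == k)
  structure(list(labels = labels, rates = rates, means = means,
                 kappa = kappa, signatures = signatures),
            class = "pf_kinetics")
}

#' Stationary distribution of a state-kinetics spec
#' @param spec A [state_kinetics_spec()].
#' @return Named numeric vector of stationary probabilities.
#' @export
stationary_distribution <- function(spec) {
  p <- ctmc_stationary(spec$rates)
  names(p) <- spec$labels
  p
}

#' Simulate a Markov-switching dihedral time series
#'
#' Samples a continuous-time Markov path, reads it out at the frame times,
#' and adds wrapped von Mises noise around the per-state mean dihedral
#' vectors.
#'
#' @param spec A [state_kinetics_spec()].
#' @param n_frames Number of frames.
#' @param frame_interval Time per frame (ns).
#' @param seed RNG seed.
#' @return List with `angles` (`n_frames x 44` degrees), `states`
#'   (ground-truth labels), `state_index`, `signatures` (per-frame, if the
#'   spec carries them) and `times` (ns).
#' @export
simulate_dihedral_series <- function(spec, n_frames, frame_interval = 0.1,
                                     seed = NULL) {
  stopifnot(inherits(spec, "pf_kinetics"), n_frames >= 1)
  with_seed(seed, {
    times <- (seq_len(n_frames) - 1) * frame_interval
    init <- sample.int(length(spec$labels), 1,
                       prob = ctmc_stationary(spec$rates))
    path <- ctmc_sample_path(spec$rates, init, times)
    d <- ncol(spec$means)
    angles <- matrix(NA_real_, n_frames, d,
                     dimnames = list(NULL, sprintf("d%02d", seq_len(d))))
    for (s in unique(path)) {
      rows <- which(path == s)
      if (is.infinite(spec$kappa[s])) {
        angles[rows, ] <- matrix(spec$means[s, ], length(rows), d,
                                 byrow = TRUE)
      } else {
        noise <- matrix(rvonmises_deg(length(rows) * d, 0, spec$kappa[s]),
                        length(rows), d)
        angles[rows, ] <- wrap_deg(
          matrix(spec$means[s, ], length(rows), d, byrow = TRUE) + noise)
      }
    }
    out <- list(angles = angles, states = spec$labels[path],
                state_index = path, times = times)
    if (!is.null(spec$signatures)) out$signatures <- spec$signatures[path]
    out
  })
}

#' Ion-trace spec
#'
#' @param n_ions Number of ions.
#' @param planted_events Total number of complete outward filter crossings
#'   to plant (distributed round-robin over ions).
#' @param z_low,z_high Axial bounds of the filter (Angstrom; entry and
#'   exit planes).
#' @param drift Baseline drift (Angstrom/ns), voltage-linked.
#' @param noise Step standard deviation of the baseline walk (Angstrom per
#'   frame).
#' @return A list of class `pf_ionspec`.
#' @export
ion_trace_spec <- function(n_ions = 1, planted_events = 0, z_low = -6,
                           z_high = 6, drift = 0, noise = 0.5) {
  stopifnot(z_low < z_high, planted_events >= 0, n_ions >= 1, noise >= 0)
  structure(list(n_ions = n_ions, planted_events = planted_events,
                 z_low = z_low, z_high = z_high, drift = drift,
                 noise = noise),
            class = "pf_ionspec")
}

#' Simulate ion axial traces with planted permeation events
#'
#' Between events each ion performs a reflected random walk strictly below
#' the filter entry plane; each planted event is a deterministic monotone
#' ramp from below `z_low` to above `z_high` superposed on the trace, so
#' the ground-truth crossing count is exact by construction.
#'
#' @param spec An [ion_trace_spec()].
#' @param n_frames Number of frames.
#' @param frame_interval Time per frame (ns).
#' @param seed RNG seed.
#' @return List with `features` (a [feature_table()] of per-ion z series,
#'   columns `ion_1`, ...) and `events` (data frame `ion`, `entry_frame`,
#'   `completion_frame`, `direction`; frames are 1-based).
#' @export
simulate_ion_traces <- function(spec, n_frames, frame_interval = 1,
                                seed = NULL) {
  stopifnot(inherits(spec, "pf_ionspec"), n_frames >= 2)
  width <- spec$z_high - spec$z_low
  step <- width / 5
  ramp <- seq(spec$z_low - 1, spec$z_high + 2, by = step)
  ramp_len <- length(ramp)
  per_ion <- table(factor(rep(seq_len(spec$n_ions),
                              length.out = spec$planted_events),
                          levels = seq_len(spec$n_ions)))
  if (any(per_ion * (ramp_len + 2) > n_frames))
    stop("n_frames too small to host ", spec$planted_events,
         " planted events (need > ", max(per_ion) * (ramp_len + 2),
         " frames)", call. = FALSE)
  with_seed(seed, {
    lower <- spec$z_low - 12
    upper <- spec$z_low - 1
    reflect <- function(z) {
      while (z > upper || z < lower) {
        if (z > upper) z <- 2 * upper - z
        if (z < lower) z <- 2 * lower - z
      }
      z
    }
    cols <- list()
    ev <- list()
    for (i in seq_len(spec$n_ions)) {
      steps <- stats::rnorm(n_frames, mean = spec$drift * frame_interval,
                            sd = spec$noise)
      z <- numeric(n_frames)
      z[1] <- (lower + upper) / 2
      for (t in 2:n_frames) z[t] <- reflect(z[t - 1] + steps[t])
      k <- per_ion[i]
      if (k > 0) {
        # one ramp per equal block, at a seeded offset inside the block
        block <- floor(n_frames / k)
        for (e in seq_len(k)) {
          lo <- (e - 1) * block + 1
          hi <- e * block - ramp_len
          start <- if (hi <= lo) lo else lo + floor(stats::runif(1) *
                                                      (hi - lo + 1))
          z[start:(start + ramp_len - 1)] <- ramp
          entry <- start + which(ramp >= spec$z_low)[1] - 1
          compl <- start + which(ramp > spec$z_high)[1] - 1
          ev[[length(ev) + 1]] <- data.frame(
            ion = i, entry_frame = entry, completion_frame = compl,
            direction = 1L)
        }
      }
      cols[[paste0("ion_", i)]] <- z
    }
    events <- if (length(ev) > 0) do.call(rbind, ev) else
      data.frame(ion = integer(), entry_frame = integer(),
                 completion_frame = integer(), direction = integer())
    events <- events[order(events$ion, events$completion_frame), ,
                     drop = FALSE]
    rownames(events) <- NULL
    list(features = feature_table((seq_len(n_frames) - 1) * frame_interval,
                                  cols),
         events = events)
  })
}

#' Simulate a telegraph gating (helix-distance) trace
#'
#' Two-state continuous-time telegraph process between an up mean and a
#' down mean with additive Gaussian noise.
#'
#' @param mean_up,mean_down State means (Angstrom); conventionally
#'   `mean_up < 8 < mean_down`.
#' @param rate_up_down,rate_down_up Switching rates (per ns).
#' @param noise_sd Gaussian noise SD (Angstrom).
#' @param n_frames Number of frames.
#' @param frame_interval Time per frame (ns).
#' @param seed RNG seed.
#' @param init Initial state, `"up"` or `"down"`.
#' @return List with `features` (feature table, column `distance`),
#'   `states` (ground-truth `"up"`/`"down"` per frame) and
#'   `down_fraction`.
#' @export
simulate_gating_trace <- function(mean_up = 4, mean_down = 9.5,
                                  rate_up_down = 0.01, rate_down_up = 0.01,
                                  noise_sd = 0.3, n_frames = 1000,
                                  frame_interval = 1, seed = NULL,
                                  init = c("up", "down")) {
  init <- match.arg(init)
  with_seed(seed, {
    times <- (seq_len(n_frames) - 1) * frame_interval
    if (rate_up_down <= 0 && rate_down_up <= 0) {
      path <- rep(if (init == "up") 1L else 2L, n_frames)
    } else {
      Q <- matrix(c(-rate_up_down, rate_up_down,
                    rate_down_up, -rate_down_up), 2, 2, byrow = TRUE)
      # a one-way chain (a rate of 0) is legal for a telegraph trace
      path <- ctmc_sample_path(Q, if (init == "up") 1L else 2L, times)
    }
    d <- ifelse(path == 1L, mean_up, mean_down) +
      stats::rnorm(n_frames, 0, noise_sd)
    list(features = feature_table(times, list(distance = d)),
         states = c("up", "down")[path],
         down_fraction = mean(path == 2L))
  })
}

#' Simulate a lipid headgroup in-plane-distance trace
#'
#' Produces a series spending an exact fraction of frames below the 10
#' Angstrom cavity boundary: `round(fraction_in_cavity * n_frames)` frames
#' take the cavity value and the rest the membrane baseline, with noise
#' clamped so no frame crosses the boundary spuriously.
#'
#' @param baseline Membrane-side distance (Angstrom, > 10).
#' @param cavity_value In-cavity distance (Angstrom, < 10).
#' @param fraction_in_cavity Target fraction of frames below 10 Angstrom.
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @param noise_sd Gaussian noise SD (Angstrom).
#' @param frame_interval Time per frame (ns).
#' @return List with `features` (feature table, column `distance`) and
#'   `fraction` (the exact realised fraction).
#' @export
simulate_lipid_trace <- function(baseline = 14, cavity_value = 6,
                                 fraction_in_cavity = 0, n_frames = 1000,
                                 seed = NULL, noise_sd = 0.5,
                                 frame_interval = 1) {
  stopifnot(cavity_value < 10, baseline > 10,
            fraction_in_cavity >= 0, fraction_in_cavity <= 1)
  with_seed(seed, {
    n_in <- round(fraction_in_cavity * n_frames)
    idx <- if (n_in > 0) sample.int(n_frames, n_in) else integer(0)
    d <- pmax(10.5, baseline + stats::rnorm(n_frames, 0, noise_sd))
    if (n_in > 0)
      d[idx] <- pmin(9.5, pmax(0.5, cavity_value +
                                 stats::rnorm(n_in, 0, noise_sd)))
    list(features = feature_table((seq_len(n_frames) - 1) * frame_interval,
                                  list(distance = d)),
         fraction = n_in / n_frames)
  })
}
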