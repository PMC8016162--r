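# Independent reference implementations ("oracles") used to check the
# package's algorithms, plus small shared fixtures. These are written as
# directly as possible from the textbook definitions so that agreement
# with the package code is meaningful.

# Dihedral angle from the two-vector atan2 formula (degrees, IUPAC sign).
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  n1 <- cr(b1, b2)
  n2 <- cr(b2, b3)
  y <- sqrt(sum(b2^2)) * sum(b1 * n2)
  x <- sum(n1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Naive DBSCAN from the original Ester et al. description: full distance
# matrix, region queries by scanning, recursive expansion via a plain
# to-visit vector. Core point counts itself. No analysis window.
oracle_dbscan <- function(pts, eps, min_points) {
  n <- nrow(pts)
  dm <- as.matrix(stats::dist(pts))
  neighbors <- lapply(seq_len(n), function(i) which(dm[i, ] <= eps))
  labels <- rep(0L, n)    # 0 = unclassified, -1 = noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    if (length(neighbors[[i]]) < min_points) {
      labels[i] <- -1L
      next
    }
    cl <- cl + 1L
    labels[i] <- cl
    seeds <- setdiff(neighbors[[i]], i)
    while (length(seeds) > 0) {
      j <- seeds[1]
      seeds <- seeds[-1]
      if (labels[j] == -1L) labels[j] <- cl
      if (labels[j] != 0L) next
      labels[j] <- cl
      if (length(neighbors[[j]]) >= min_points)
        seeds <- c(seeds, setdiff(neighbors[[j]], which(labels > 0L)))
    }
  }
  labels
}

# Relabel cluster ids canonically (by first occurrence) so two DBSCAN
# implementations can be compared independent of cluster numbering.
canonical_labels <- function(labels) {
  out <- labels
  ids <- unique(labels[labels > 0])
  for (k in seq_along(ids)) out[labels == ids[k]] <- k
  out
}

# PCA spectrum from the covariance eigendecomposition.
oracle_pca_var <- function(x) {
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  ev[ev < 0] <- 0
  ev
}

# Brute-force per-pair periodic distance.
oracle_periodic_dist <- function(u, v) {
  d <- abs(u - v) %% 360
  sqrt(sum(pmin(d, 360 - d)^2))
}

# A tiny but complete three-state kinetics spec shared by several tests.
toy_kinetics <- function(kappa = 60) {
  means <- matrix(0, 3, 44)
  means[2, 1:8] <- 120
  means[3, 21:28] <- -120
  state_kinetics_spec(
    labels = c("I", "II", "III"),
    rates = matrix(c(-0.6, 0.4, 0.2,
                     0.3, -0.4, 0.1,
                     0.3, 0.1, -0.4), 3, 3, byrow = TRUE),
    means = means, kappa = kappa,
    signatures = c("", "A|S4-S3", "A|S3-S2"))
}

# Write a minimal valid pipeline config list for tests.
toy_config <- function(dir) {
  reps <- file.path(dir, "reps")
  dir.create(reps, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(dir, "out")
  dir.create(out, showWarnings = FALSE)
  merge_config(default_config(), list(
    registry = file.path(dir, "registry.yaml"),
    output_dir = out, seed = 7))
}
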