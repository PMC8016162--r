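#' @title Dimensionality reduction: PCA and sketch-map
#' @name embed
#' @description PCA on sin/cos-expanded dihedrals and a complete
#'   sketch-map implementation: sigmoid distance transforms, farthest-point
#'   landmark selection, stress minimization of the landmark embedding and
#'   deterministic out-of-sample projection of the remaining frames.
#'
#'   Sketch-map matches sigmoid-transformed distances between the high-
#'   and low-dimensional spaces, so that distances near the characteristic
#'   length `sigma` are preserved while shorter ones are contracted and
#'   longer ones saturated. The stress is
#'   `sum_{i<j} (F(R_ij) - f(r_ij))^2` with `F`, `f` the high-/low-d
#'   sigmoids.
NULL

#' Sketch-map parameters
#'
#' @param sigma Characteristic length in feature-space distance units.
#' @param A,B High-dimensional sigmoid exponents.
#' @param a,b Low-dimensional sigmoid exponents.
#' @param n_landmarks Number of landmark points.
#' @param low_d Embedding dimensionality (2).
#' @return A list of class `pf_smparams`.
#' @export
sketchmap_params <- function(sigma = 2.5, A = 12, B = 12, a = 1, b = 2,
                             n_landmarks = 1000, low_d = 2) {
  stopifnot(sigma > 0, A > 0, B > 0, a > 0, b > 0,
            n_landmarks >= 2, low_d >= 1)
  structure(list(sigma = sigma, A = A, B = B, a = a, b = b,
                 n_landmarks = n_landmarks, low_d = low_d),
            class = "pf_smparams")
}

#' Sketch-map sigmoid
#'
#' `s(r) = 1 - (1 + (2^(p/q) - 1) (r/sigma)^p)^(-q/p)`: monotone, 0 at
#' r = 0, exactly 1/2 at r = sigma, approaching 1 as r grows.
#'
#' @param r Non-negative distance(s).
#' @param sigma Characteristic length.
#' @param p,q Exponents (> 0).
#' @return Values in `[0, 1)`.
#' @export
sm_sigmoid <- function(r, sigma, p, q) {
  if (any(r < 0)) stop("distances must be >= 0", call. = FALSE)
  c0 <- 2^(p / q) - 1
  1 - (1 + c0 * (r / sigma)^p)^(-q / p)
}

# derivative of sm_sigmoid wrt r; safe at r = 0 for p >= 1
sm_sigmoid_grad <- function(r, sigma, p, q) {
  c0 <- 2^(p / q) - 1
  t <- c0 * (r / sigma)^p
  out <- ifelse(r > 0, q * t * (1 + t)^(-q / p - 1) / r, 0)
  if (p == 1) out[r == 0] <- q * c0 / sigma
  out
}

# inverse: the r with sm_sigmoid(r) = v (used in tests and 2-point solves)
sm_sigmoid_inv <- function(v, sigma, p, q) {
  c0 <- 2^(p / q) - 1
  sigma * (((1 - v)^(-p / q) - 1) / c0)^(1 / p)
}

# per-coordinate wrapped absolute difference for degree-valued features:
# min(|d| mod 360, 360 - |d| mod 360) computed as |d - 360 round(d/360)|
wrap_absdiff <- function(d) {
  abs(d - 360 * round(d / 360))
}

#' Pairwise distance matrix
#'
#' @param x Numeric matrix (`n x d`).
#' @param metric `"euclidean"` or `"periodic"` (per-coordinate wrapped
#'   difference `min(|delta|, 360 - |delta|)` for angles in degrees).
#' @return Symmetric `n x n` matrix with zero diagonal.
#' @export
pairwise_distances <- function(x, metric = c("euclidean", "periodic")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  if (metric == "euclidean") return(as.matrix(stats::dist(x)))
  n <- nrow(x)
  d2 <- matrix(0, n, n)
  for (k in seq_len(ncol(x))) {
    dk <- wrap_absdiff(outer(x[, k], x[, k], "-"))
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

#' Distances from a set of points to a set of reference rows
#'
#' @param x Query matrix (`n x d`).
#' @param y Reference matrix (`m x d`).
#' @inheritParams pairwise_distances
#' @return `n x m` matrix of distances.
#' @export
cross_distances <- function(x, y, metric = c("euclidean", "periodic")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (metric == "euclidean") {
    d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * x %*% t(y)
    return(sqrt(pmax(d2, 0)))
  }
  n <- nrow(x)
  m <- nrow(y)
  d2 <- matrix(0, n, m)
  for (k in seq_len(ncol(x))) {
    dk <- wrap_absdiff(outer(x[, k], y[, k], "-"))
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

#' Farthest-point-sampling landmark selection
#'
#' The first landmark is a seeded random frame; each subsequent landmark
#' maximizes its minimum distance to the landmarks already chosen (ties
#' broken toward the lower index).
#'
#' @param x Feature matrix (`n x d`).
#' @param n_landmarks Number of landmarks (capped at `n`).
#' @param seed RNG seed for the first pick.
#' @inheritParams pairwise_distances
#' @return Integer vector of landmark row indices, in selection order.
#' @export
select_landmarks <- function(x, n_landmarks, seed = NULL,
                             metric = c("euclidean", "periodic")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  n <- nrow(x)
  n_landmarks <- min(n_landmarks, n)
  first <- with_seed(seed, sample.int(n, 1))
  chosen <- integer(n_landmarks)
  chosen[1] <- first
  mind <- as.vector(cross_distances(x, x[first, , drop = FALSE], metric))
  if (n_landmarks > 1) {
    for (k in 2:n_landmarks) {
      nxt <- which.max(mind)
      chosen[k] <- nxt
      d <- as.vector(cross_distances(x, x[nxt, , drop = FALSE], metric))
      mind <- pmin(mind, d)
    }
  }
  chosen
}

#' Sketch-map stress of a landmark configuration
#'
#' @param d_high Symmetric matrix of high-dimensional landmark distances.
#' @param y Low-dimensional coordinates (`n x low_d`).
#' @param params A [sketchmap_params()].
#' @return The stress `sum_{i<j} (F(R_ij) - f(r_ij))^2` (>= 0).
#' @export
sketchmap_stress <- function(d_high, y, params) {
  iu <- upper.tri(d_high)
  Fv <- sm_sigmoid(d_high[iu], params$sigma, params$A, params$B)
  r <- as.matrix(stats::dist(y))[iu]
  fv <- sm_sigmoid(r, params$sigma, params$a, params$b)
  sum((Fv - fv)^2)
}

# stress + gradient on flattened coordinates, for the optimiser
sm_stress_obj <- function(d_high, params) {
  n <- nrow(d_high)
  iu <- upper.tri(d_high)
  Fv <- sm_sigmoid(d_high[iu], params$sigma, params$A, params$B)
  ld <- params$low_d
  list(
    fn = function(yv) {
      y <- matrix(yv, n, ld)
      r <- as.matrix(stats::dist(y))[iu]
      fv <- sm_sigmoid(r, params$sigma, params$a, params$b)
      sum((Fv - fv)^2)
    },
    gr = function(yv) {
      y <- matrix(yv, n, ld)
      R <- as.matrix(stats::dist(y))
      Fm <- matrix(0, n, n)
      Fm[iu] <- Fv
      Fm <- Fm + t(Fm)
      fv <- sm_sigmoid(R, params$sigma, params$a, params$b)
      fg <- sm_sigmoid_grad(R, params$sigma, params$a, params$b)
      # dS/dy_i = sum_j 2 (f - F) f'(r) (y_i - y_j) / r
      w <- 2 * (fv - Fm) * fg / ifelse(R > 0, R, 1)
      diag(w) <- 0
      g <- matrix(0, n, ld)
      for (k in seq_len(ld)) {
        dy <- outer(y[, k], y[, k], "-")
        g[, k] <- rowSums(w * dy)
      }
      as.vector(g)
    }
  )
}

#' Optimize the landmark embedding
#'
#' Initializes from classical metric MDS (`cmdscale`) on the
#' sigmoid-transformed distances, then refines by quasi-Newton (BFGS)
#' minimization of the sketch-map stress with analytic gradients.
#' Additional restarts perturb the MDS solution with seeded Gaussian
#' jitter; the best final configuration is returned.
#'
#' @param d_high Symmetric landmark distance matrix (high-dimensional).
#' @param params A [sketchmap_params()].
#' @param seed RNG seed for the restarts.
#' @param restarts Number of optimizations (default 4).
#' @param maxit Iteration cap per restart.
#' @return List with `coords` (`n x low_d`), `stress`, and
#'   `stress_by_restart`.
#' @export
minimize_landmark_embedding <- function(d_high, params, seed = NULL,
                                        restarts = 4, maxit = 10000) {
  d_high <- as.matrix(d_high)
  n <- nrow(d_high)
  if (n < 2) stop("need at least 2 landmarks", call. = FALSE)
  Fmat <- sm_sigmoid(d_high, params$sigma, params$A, params$B)
  diag(Fmat) <- 0
  init <- suppressWarnings(
    stats::cmdscale(Fmat, k = min(params$low_d, n - 1), add = TRUE)$points)
  if (ncol(init) < params$low_d)
    init <- cbind(init, matrix(0, n, params$low_d - ncol(init)))
  # scale the MDS solution into the sigma regime of the low-d sigmoid
  spread <- max(stats::dist(init))
  if (spread > 0) init <- init * (params$sigma * 2 / spread)
  obj <- sm_stress_obj(d_high, params)
  best <- NULL
  stresses <- numeric(restarts)
  with_seed(seed, {
    for (rs in seq_len(restarts)) {
      y0 <- init
      if (rs > 1)
        y0 <- y0 + matrix(stats::rnorm(length(y0), 0, params$sigma / 2),
                          nrow = n)
      fit <- stats::optim(as.vector(y0), fn = obj$fn, gr = obj$gr,
                          method = "BFGS",
                          control = list(maxit = maxit, reltol = 1e-10))
      if (!is.finite(fit$value))
        stop("non-finite stress during optimization", call. = FALSE)
      stresses[rs] <- fit$value
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  })
  list(coords = matrix(best$par, n, params$low_d), stress = best$value,
       stress_by_restart = stresses)
}

# single-point stress pieces for out-of-sample projection
oos_objective <- function(Fp, landmark_y, params) {
  list(
    fn = function(y) {
      r <- sqrt(colSums((t(landmark_y) - y)^2))
      fv <- sm_sigmoid(r, params$sigma, params$a, params$b)
      sum((Fp - fv)^2)
    },
    gr = function(y) {
      dy <- t(t(landmark_y) - y)           # n_land x low_d, y_j - y
      r <- sqrt(rowSums(dy^2))
      fv <- sm_sigmoid(r, params$sigma, params$a, params$b)
      fg <- sm_sigmoid_grad(r, params$sigma, params$a, params$b)
      w <- 2 * (fv - Fp) * fg / ifelse(r > 0, r, 1)
      -colSums(w * dy)
    }
  )
}

#' Out-of-sample projection onto a landmark embedding
#'
#' Each point's low-dimensional position minimizes its single-point
#' stress against the fixed landmarks; points whose features exactly
#' duplicate a landmark take that landmark's coordinates directly.
#' Initialization scans a coarse grid
#' over the (slightly expanded) landmark bounding box, then refines the
#' best cell with damped Gauss-Newton (2-d embeddings, all points at
#' once) or BFGS. Deterministic given its inputs.
#'
#' @param x Feature matrix of points to project (`n x d`), or a single
#'   feature vector.
#' @param landmarks_x Landmark feature matrix (`m x d`).
#' @param landmark_y Landmark low-d coordinates (`m x low_d`).
#' @param params A [sketchmap_params()].
#' @inheritParams pairwise_distances
#' @param grid Grid resolution per axis for the initialization (default
#'   20).
#' @return `n x low_d` matrix of projected coordinates.
#' @export
project_out_of_sample <- function(x, landmarks_x, landmark_y, params,
                                  metric = c("euclidean", "periodic"),
                                  grid = 20) {
  metric <- match.arg(metric)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  landmark_y <- as.matrix(landmark_y)
  ld <- ncol(landmark_y)
  dmat <- cross_distances(x, landmarks_x, metric)
  # a point whose features duplicate a landmark (distance zero to
  # numerical precision on the sigma scale) is that landmark frame: map
  # it to the landmark's coordinates for a consistent embedding
  dup_land <- apply(dmat, 1, which.min)
  is_dup <- dmat[cbind(seq_len(nrow(x)), dup_land)] <= 1e-6 * params$sigma
  if (all(is_dup)) return(landmark_y[dup_land, , drop = FALSE])
  if (any(is_dup)) {
    out <- matrix(NA_real_, nrow(x), ld)
    out[is_dup, ] <- landmark_y[dup_land[is_dup], , drop = FALSE]
    out[!is_dup, ] <- project_out_of_sample(
      x[!is_dup, , drop = FALSE], landmarks_x, landmark_y, params,
      metric = metric, grid = grid)
    return(out)
  }
  Fmat <- sm_sigmoid(dmat, params$sigma, params$A, params$B)
  # grid nodes over the expanded landmark bounding box
  lo <- apply(landmark_y, 2, min)
  hi <- apply(landmark_y, 2, max)
  pad <- pmax(0.05 * (hi - lo), params$sigma / 10)
  axes <- lapply(seq_len(ld), function(k)
    seq(lo[k] - pad[k], hi[k] + pad[k], length.out = grid))
  # the landmark positions join the grid as candidate starts, so points
  # (near-)duplicating a landmark start at that landmark's coordinates
  nodes <- unname(rbind(as.matrix(expand.grid(axes)), landmark_y))
  # f-sigmoid of node-to-landmark distances, shared by all points
  rg <- cross_distances(nodes, landmark_y, "euclidean")
  fg <- sm_sigmoid(rg, params$sigma, params$a, params$b)
  # stress(point, node) = ||F_p||^2 - 2 F_p . f_node + ||f_node||^2
  cross <- Fmat %*% t(fg)
  sgrid <- rowSums(Fmat^2) - 2 * cross +
    matrix(rowSums(fg^2), nrow(x), nrow(nodes), byrow = TRUE)
  best_node <- max.col(-sgrid, ties.method = "first")
  y0 <- nodes[best_node, , drop = FALSE]
  if (ld == 2)
    return(refine_oos_lm(y0, Fmat, landmark_y, params))
  out <- matrix(NA_real_, nrow(x), ld)
  for (i in seq_len(nrow(x))) {
    obj <- oos_objective(Fmat[i, ], landmark_y, params)
    fit <- stats::optim(y0[i, ], fn = obj$fn, gr = obj$gr,
                        method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    out[i, ] <- fit$par
  }
  out
}

# Vectorized Levenberg-Marquardt refinement of every point's single-point
# stress at once (2-d embeddings): per-point damped Gauss-Newton steps
# with closed-form 2x2 solves, accept/reject per point. Converged points
# leave the active set, so the per-iteration cost shrinks as the bulk of
# the points settles.
refine_oos_lm <- function(y, Fmat, landmark_y, params,
                          max_iter = 200) {
  n <- nrow(y)
  stress_of <- function(yy, Fsub) {
    d1 <- outer(yy[, 1], landmark_y[, 1], "-")
    d2 <- outer(yy[, 2], landmark_y[, 2], "-")
    r <- sqrt(d1^2 + d2^2)
    res <- Fsub - sm_sigmoid(r, params$sigma, params$a, params$b)
    list(d1 = d1, d2 = d2, r = r, res = res, stress = rowSums(res^2))
  }
  cur <- stress_of(y, Fmat)
  lambda <- rep(1e-3, n)
  tol <- 1e-7 * params$sigma
  active <- seq_len(n)
  for (it in seq_len(max_iter)) {
    fp <- sm_sigmoid_grad(cur$r, params$sigma, params$a, params$b)
    inv_r <- ifelse(cur$r > 0, 1 / cur$r, 0)
    u1 <- cur$d1 * inv_r
    u2 <- cur$d2 * inv_r
    g1 <- -2 * rowSums(cur$res * fp * u1)
    g2 <- -2 * rowSums(cur$res * fp * u2)
    fp2 <- 2 * fp^2
    a11 <- rowSums(fp2 * u1^2) + lambda[active]
    a22 <- rowSums(fp2 * u2^2) + lambda[active]
    a12 <- rowSums(fp2 * u1 * u2)
    det <- a11 * a22 - a12^2
    det[det <= 0 | !is.finite(det)] <- NA
    s1 <- (-g1 * a22 + g2 * a12) / det
    s2 <- (-g2 * a11 + g1 * a12) / det
    bad <- !is.finite(s1) | !is.finite(s2)
    s1[bad] <- 0
    s2[bad] <- 0
    ytrial <- y[active, , drop = FALSE] + cbind(s1, s2)
    trial <- stress_of(ytrial, Fmat[active, , drop = FALSE])
    ok <- trial$stress < cur$stress & !bad
    idx_ok <- active[ok]
    if (length(idx_ok) > 0) {
      y[idx_ok, ] <- ytrial[ok, ]
      lambda[idx_ok] <- pmax(lambda[idx_ok] * 0.3, 1e-12)
    }
    idx_rej <- active[!ok]
    lambda[idx_rej] <- pmin(lambda[idx_rej] * 4, 1e12)
    # a point is done when its accepted step is below tol, or when the
    # damping has grown so large that no further progress is possible
    step <- pmax(abs(s1), abs(s2))
    done <- (ok & step < tol) | (!ok & lambda[active] >= 1e8)
    keep <- !done
    if (!any(keep)) break
    sub_new <- which(ok & keep)            # rows of `trial` to carry over
    keep_ok <- ok[keep]                    # within the surviving subset
    cur <- list(
      d1 = rbind_update(cur$d1[keep, , drop = FALSE],
                        trial$d1[sub_new, , drop = FALSE], keep_ok),
      d2 = rbind_update(cur$d2[keep, , drop = FALSE],
                        trial$d2[sub_new, , drop = FALSE], keep_ok),
      r = rbind_update(cur$r[keep, , drop = FALSE],
                       trial$r[sub_new, , drop = FALSE], keep_ok),
      res = rbind_update(cur$res[keep, , drop = FALSE],
                         trial$res[sub_new, , drop = FALSE], keep_ok),
      stress = {
        s <- cur$stress[keep]
        s[keep_ok] <- trial$stress[sub_new]
        s
      })
    active <- active[keep]
  }
  y
}

# overwrite the rows of `base` flagged by `mask` with the rows of `upd`
rbind_update <- function(base, upd, mask) {
  if (length(upd) > 0) base[mask, ] <- upd
  base
}

#' Embed a feature matrix with sketch-map
#'
#' Full pipeline: landmark selection (farthest-point sampling), landmark
#' stress minimization, and out-of-sample projection of all frames.
#' Landmark frames keep their optimized coordinates in the projection.
#'
#' @param x Feature matrix (`n x d`).
#' @param params A [sketchmap_params()].
#' @param seed RNG seed (landmark choice and optimizer restarts).
#' @inheritParams pairwise_distances
#' @param chunk Frames per projection block (memory control).
#' @return List of class `pf_embedding`: `landmark_idx`, `landmark_y`,
#'   `coords` (all frames), `params`, `stress`, `metric`.
#' @export
sketchmap_embed <- function(x, params = sketchmap_params(), seed = NULL,
                            metric = c("euclidean", "periodic"),
                            chunk = 2000) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  idx <- select_landmarks(x, params$n_landmarks, seed = seed,
                          metric = metric)
  dl <- pairwise_distances(x[idx, , drop = FALSE], metric)
  emb <- minimize_landmark_embedding(dl, params, seed = seed)
  n <- nrow(x)
  coords <- matrix(NA_real_, n, params$low_d)
  coords[idx, ] <- emb$coords
  rest <- setdiff(seq_len(n), idx)
  if (length(rest) > 0) {
    blocks <- split(rest, ceiling(seq_along(rest) / chunk))
    for (bl in blocks) {
      coords[bl, ] <- project_out_of_sample(
        x[bl, , drop = FALSE], x[idx, , drop = FALSE], emb$coords, params,
        metric = metric)
    }
  }
  structure(list(landmark_idx = idx, landmark_y = emb$coords,
                 coords = coords, params = params, stress = emb$stress,
                 metric = metric),
            class = "pf_embedding")
}

#' Principal component analysis (column-centered SVD)
#'
#' @param x Feature matrix (`n x d`).
#' @return List with `scores` (`n x k`), `loadings` (`d x k`),
#'   `sdev`, and `explained` (variance fractions summing to 1).
#' @export
pca <- function(x) {
  x <- as.matrix(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  k <- sum(sv$d > max(sv$d) * 1e-12)
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  var_comp <- sv$d^2 / (nrow(x) - 1)
  list(scores = scores, loadings = sv$v, sdev = sqrt(var_comp),
       explained = var_comp / sum(var_comp), rank = k)
}
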