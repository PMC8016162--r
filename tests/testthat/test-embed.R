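test_that("the sigmoid has the definitional limits and half-point", {
  expect_equal(sm_sigmoid(0, 2.5, 12, 12), 0)
  # half-point at sigma for many exponent settings, including the
  # (A, B) = (12, 12) and (a, b) = (1, 2) pairs
  for (pq in list(c(12, 12), c(1, 2), c(2, 7), c(0.5, 3), c(6, 1))) {
    expect_equal(sm_sigmoid(2.5, 2.5, pq[1], pq[2]), 0.5)
    expect_equal(sm_sigmoid(17, 17, pq[1], pq[2]), 0.5)
  }
  expect_lt(1 - sm_sigmoid(1e6, 2.5, 12, 12), 1e-6)
  expect_error(sm_sigmoid(-1, 2.5, 12, 12), ">= 0")
})

test_that("the sigmoid is monotone on a fine grid", {
  r <- seq(0, 12, length.out = 1000)
  s <- sm_sigmoid(r, 2.5, 12, 12)
  # non-decreasing everywhere; strictly increasing away from the ends,
  # where the steep (12, 12) variant is flat to double precision
  expect_true(all(diff(s) >= 0))
  expect_true(all(diff(s[r >= 1 & r <= 5]) > 0))
  s2 <- sm_sigmoid(r, 2.5, 1, 2)
  expect_true(all(diff(s2) > 0))
})

test_that("the sigmoid derivative matches a numeric gradient", {
  h <- 1e-6
  for (pq in list(c(12, 12), c(1, 2))) {
    r <- c(0.3, 1, 2.5, 4, 9)
    num <- (sm_sigmoid(r + h, 2.5, pq[1], pq[2]) -
              sm_sigmoid(r - h, 2.5, pq[1], pq[2])) / (2 * h)
    ana <- poreflow:::sm_sigmoid_grad(r, 2.5, pq[1], pq[2])
    expect_equal(ana, num, tolerance = 1e-5)
  }
})

test_that("pairwise distances: wrap definition and brute-force oracle", {
  d <- pairwise_distances(matrix(c(179, -179), 2, 1), "periodic")
  expect_equal(d[1, 2], 2)
  expect_equal(pairwise_distances(matrix(c(179, -179), 2, 1),
                                  "euclidean")[1, 2], 358)
  set.seed(31)
  x <- matrix(runif(15, -180, 180), 5, 3)
  dp <- pairwise_distances(x, "periodic")
  de <- pairwise_distances(x, "euclidean")
  for (i in 1:5) for (j in 1:5) {
    expect_equal(dp[i, j], oracle_periodic_dist(x[i, ], x[j, ]),
                 tolerance = 1e-12)
    expect_equal(de[i, j], sqrt(sum((x[i, ] - x[j, ])^2)),
                 tolerance = 1e-12)
  }
  expect_true(all(diag(dp) == 0))
  expect_equal(dp, t(dp))
})

test_that("farthest-point sampling picks endpoints of a collinear triple", {
  x <- matrix(c(0, 1, 10), 3, 1)
  # FPS from the endpoint at 0 must add the other endpoint next
  idx <- select_landmarks(x, 2, seed = 1)
  # whatever the seeded start, the two chosen points are 2 of the 3 and
  # include at least one endpoint at maximal spread
  expect_length(idx, 2)
  expect_length(unique(idx), 2)
  # with all three requested, all indices are returned
  expect_setequal(select_landmarks(x, 3, seed = 1), 1:3)
  # deterministic under a fixed seed
  set.seed(99)
  y <- matrix(rnorm(200), 100, 2)
  expect_identical(select_landmarks(y, 10, seed = 2),
                   select_landmarks(y, 10, seed = 2))
})

test_that("FPS maximizes the minimum distance at each step", {
  set.seed(32)
  x <- matrix(rnorm(60), 30, 2)
  idx <- select_landmarks(x, 5, seed = 3)
  d <- pairwise_distances(x, "euclidean")
  for (k in 2:5) {
    chosen <- idx[seq_len(k - 1)]
    gains <- unname(apply(d[, chosen, drop = FALSE], 1, min))
    expect_equal(gains[idx[k]], max(gains))
  }
})

test_that("stress is zero iff the transformed distances match, and is rigid-invariant", {
  p <- sketchmap_params(sigma = 2.5, A = 12, B = 12, a = 1, b = 2,
                        n_landmarks = 3)
  R <- matrix(c(0, 2.5, 2.5, 2.5, 0, 2.5, 2.5, 2.5, 0), 3, 3)
  # the r* with f(r*) = 0.5 = F(sigma)
  rstar <- poreflow:::sm_sigmoid_inv(0.5, 2.5, 1, 2)
  y <- rbind(c(0, 0), c(rstar, 0), c(rstar / 2, rstar * sqrt(3) / 2))
  expect_equal(sketchmap_stress(R, y, p), 0, tolerance = 1e-12)
  # two-landmark single-pair values
  R2 <- matrix(c(0, 2.5, 2.5, 0), 2, 2)
  y0 <- rbind(c(0, 0), c(0, 0))
  expect_equal(sketchmap_stress(R2, y0, p), 0.25)
  # rigid motion invariance
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  y2 <- y %*% rot + matrix(rep(c(3, -1), each = 3), 3, 2)
  expect_equal(sketchmap_stress(R, y2, p), sketchmap_stress(R, y, p),
               tolerance = 1e-12)
})

test_that("two landmarks embed exactly with zero stress", {
  p <- sketchmap_params(sigma = 2.5, A = 12, B = 12, a = 1, b = 2,
                        n_landmarks = 2)
  R <- matrix(c(0, 4, 4, 0), 2, 2)
  emb <- minimize_landmark_embedding(R, p, seed = 1)
  expect_equal(emb$stress, 0, tolerance = 1e-12)
  r_low <- sqrt(sum((emb$coords[1, ] - emb$coords[2, ])^2))
  expect_equal(r_low,
               poreflow:::sm_sigmoid_inv(sm_sigmoid(4, 2.5, 12, 12),
                                         2.5, 1, 2),
               tolerance = 1e-6)
})

test_that("three equidistant landmarks at R = sigma embed as the analytic triangle", {
  p <- sketchmap_params(sigma = 2.5, A = 12, B = 12, a = 1, b = 2,
                        n_landmarks = 3)
  R <- matrix(2.5, 3, 3) - diag(2.5, 3)
  emb <- minimize_landmark_embedding(R, p, seed = 1)
  expect_lt(emb$stress, 1e-12)
  rstar <- poreflow:::sm_sigmoid_inv(0.5, 2.5, 1, 2)
  sides <- as.vector(dist(emb$coords))
  expect_equal(sides, rep(rstar, 3), tolerance = 1e-4)
  # best stress across restarts is what is returned
  expect_equal(emb$stress, min(emb$stress_by_restart))
})

test_that("out-of-sample projection reproduces landmark coordinates", {
  # data whose pairwise distances straddle sigma, so the transformed
  # distances are informative and the landmark positions identifiable
  set.seed(33)
  x <- matrix(runif(40 * 2, 0, 150), 40, 2)
  p <- sketchmap_params(sigma = 60, A = 4, B = 4, a = 1, b = 2,
                        n_landmarks = 40)
  d <- pairwise_distances(x, "euclidean")
  emb <- minimize_landmark_embedding(d, p, seed = 4)
  proj <- project_out_of_sample(x, x, emb$coords, p, metric = "euclidean")
  err <- sqrt(rowSums((proj - emb$coords)^2))
  expect_lt(max(err), 1e-3)
})

test_that("a point equidistant from two symmetric landmarks projects onto the bisector", {
  p <- sketchmap_params(sigma = 2, A = 2, B = 2, a = 1, b = 2,
                        n_landmarks = 2)
  lx <- rbind(c(0, 0), c(4, 0))
  ly <- rbind(c(-1.3, 0), c(1.3, 0))
  q <- c(2, 1.7)                      # equidistant from both landmarks
  proj <- project_out_of_sample(rbind(q), lx, ly, p, metric = "euclidean")
  expect_equal(abs(proj[1, 1] - (-1.3)), abs(proj[1, 1] - 1.3),
               tolerance = 1e-6)
})

test_that("the full embedding keeps landmark coordinates fixed in the projection", {
  set.seed(34)
  x <- rbind(matrix(rnorm(25 * 4, 0, 2), 25, 4),
             matrix(rnorm(25 * 4, 40, 2), 25, 4))
  p <- sketchmap_params(sigma = 15, A = 12, B = 12, a = 1, b = 2,
                        n_landmarks = 10)
  emb <- sketchmap_embed(x, p, seed = 5, metric = "euclidean")
  expect_s3_class(emb, "pf_embedding")
  expect_identical(emb$coords[emb$landmark_idx, ], emb$landmark_y)
  expect_gte(emb$stress, 0)
})

test_that("well-separated clusters stay separated in the map and are found by DBSCAN", {
  set.seed(35)
  centers <- rbind(rep(0, 8), rep(120, 8), c(rep(-120, 4), rep(120, 4)))
  x <- centers[rep(1:3, each = 40), ] + matrix(rnorm(120 * 8, 0, 2), 120, 8)
  p <- sketchmap_params(sigma = 60, A = 12, B = 12, a = 1, b = 2,
                        n_landmarks = 30)
  emb <- sketchmap_embed(x, p, seed = 6, metric = "periodic")
  cl <- dbscan_cluster(emb$coords, eps = 15, min_points = 3)
  expect_equal(max(cl), 3)
  expect_true(all(cl > 0))
  truth <- rep(1:3, each = 40)
  # the clustering must be a relabeling of the ground truth
  expect_equal(length(unique(paste(cl, truth))), 3)
})

test_that("PCA matches the eigendecomposition oracle and conserves variance", {
  set.seed(36)
  x <- matrix(rnorm(40), 10, 4)
  res <- pca(x)
  expect_equal(res$sdev^2, oracle_pca_var(x), tolerance = 1e-9)
  expect_equal(sum(res$sdev^2), sum(apply(x, 2, var)), tolerance = 1e-9)
  expect_equal(sum(res$explained), 1, tolerance = 1e-12)
  # scores are orthogonal
  g <- crossprod(res$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-9)
})

test_that("PCA of collinear 2-D data explains everything on one axis", {
  t <- seq(-3, 3, length.out = 50)
  x <- cbind(2 * t + 1, -t + 4)
  res <- pca(x)
  expect_equal(res$explained[1], 1, tolerance = 1e-12)
  expect_equal(res$rank, 1)
})
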