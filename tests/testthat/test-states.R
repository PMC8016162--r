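test_that("DBSCAN separates two tight blobs with no noise", {
  set.seed(51)
  blob1 <- matrix(rnorm(20, 0, 0.05), 10, 2)
  blob2 <- matrix(rnorm(20, 0, 0.05), 10, 2) + 5
  pts <- rbind(blob1, blob2)
  cl <- dbscan_cluster(pts, eps = 0.5, min_points = 3)
  expect_equal(max(cl), 2)
  expect_true(all(cl > 0))
  expect_equal(length(unique(cl[1:10])), 1)
  expect_equal(length(unique(cl[11:20])), 1)
})

test_that("DBSCAN limits: tiny eps gives all noise, identical points one cluster", {
  set.seed(52)
  pts <- matrix(runif(40, 0, 100), 20, 2)
  expect_true(all(dbscan_cluster(pts, eps = 1e-9, min_points = 3) == -1))
  same <- matrix(1.5, 7, 2)
  expect_true(all(dbscan_cluster(same, eps = 0.1, min_points = 3) == 1))
})

test_that("points outside the analysis window are pre-labeled noise", {
  pts <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
               matrix(rnorm(20, 100, 0.1), 10, 2))
  cl <- dbscan_cluster(pts, eps = 1, min_points = 3,
                       window = c(-60, 60, -60, 60))
  expect_true(all(cl[11:20] == -1))
  expect_true(all(cl[1:10] == 1))
})

test_that("DBSCAN equals the brute-force reference on random instances", {
  set.seed(53)
  for (rep in 1:25) {
    n <- sample(5:200, 1)
    k <- sample(1:4, 1)
    centers <- matrix(runif(2 * k, -20, 20), k, 2)
    pts <- centers[sample(k, n, replace = TRUE), , drop = FALSE] +
      matrix(rnorm(2 * n, 0, runif(1, 0.3, 3)), n, 2)
    eps <- runif(1, 0.2, 4)
    mp <- sample(1:6, 1)
    got <- canonical_labels(dbscan_cluster(pts, eps, mp))
    want <- canonical_labels(oracle_dbscan(pts, eps, mp))
    expect_identical(got, want)
  }
})

test_that("signature strings are canonical (sorted, '+'-joined, empty native)", {
  expect_equal(signature_string(), "")
  expect_equal(signature_string("A", "S4-S3"), "A|S4-S3")
  expect_equal(signature_string(c("C", "A"), c("S3-S2", "S4-S3")),
               "A|S4-S3+C|S3-S2")
  expect_error(signature_string("A", "S9-S8"), "boundary")
})

test_that("flip classification is invariant under rotation about the pore axis", {
  spec <- sf_geometry_spec(flip_signature = list(c(1, 1), c(4, 3)),
                           angular_noise = 0)
  traj <- build_filter_coordinates(spec, seed = 54)
  sel <- synthetic_sf_selection(spec)
  sig0 <- classify_flips(traj, sel)
  th <- 37 * pi / 180
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  coords <- traj$coords
  coords[1, , ] <- coords[1, , ] %*% rot
  sig1 <- classify_flips(trajectory(traj$atoms, coords[1, , ]), sel)
  expect_equal(sig1, sig0)
})

test_that("exactly tangential carbonyls are not flipped (strict <)", {
  # Mirror-symmetric toy filter with all atoms on the y = 0 line and all
  # coordinates exact multiples of 0.25, so the pore-axis origin is
  # exactly (0, 0) in floating point and a purely y-directed C->O vector
  # has an exactly zero inward radial cosine.
  build_toy <- function(a129_o_offset) {
    rows <- list()
    for (side in c(1, -1)) {
      chains <- if (side == 1) c("A", "B") else c("C", "D")
      for (ci in 1:2) {
        ch <- chains[ci]
        base <- side * (if (ci == 1) 6 else 14)
        for (pos in 1:5) {
          res <- 128L + pos
          cx <- base + side * 0.5 * pos
          o_off <- c(-side * 1.25, 0)
          if (ch == "A" && pos == 1) o_off <- a129_o_offset
          if (ch == "C" && pos == 1) o_off <- -a129_o_offset
          rows[[length(rows) + 1]] <- data.frame(
            atom_name = c("N", "CA", "C", "O"),
            residue_name = "GLY", residue_index = res, chain_id = ch,
            x = c(cx, cx + side * 0.25, cx + side * 0.5,
                  cx + side * 0.5 + o_off[1]),
            y = c(0, 0, 0, o_off[2]), z = pos, stringsAsFactors = FALSE)
        }
      }
    }
    df <- do.call(rbind, rows)
    atoms <- atom_table(df$atom_name, df$residue_name, df$residue_index,
                        df$chain_id, df$x, df$y, df$z)
    trajectory(atoms, as.matrix(df[, c("x", "y", "z")]))
  }
  sel <- sf_selection(c("A", "B", "C", "D"), rep(129L, 4))
  # tangential: C->O along +y, origin along -x from C => cosine exactly 0
  sig <- classify_flips(build_toy(c(0, 1.25)), sel)
  expect_equal(sig, "")
  # pointing outward (+x, away from the axis): flipped
  sig2 <- classify_flips(build_toy(c(1.25, 0)), sel)
  expect_equal(sig2, signature_string(c("A", "C"), c("S4-S3", "S4-S3")))
})

test_that("degenerate C->O vectors raise an error", {
  spec <- sf_geometry_spec(angular_noise = 0)
  traj <- build_filter_coordinates(spec, seed = 56)
  iC <- poreflow:::atom_index(traj$atoms, "A", 129, "C")
  iO <- poreflow:::atom_index(traj$atoms, "A", 129, "O")
  coords <- traj$coords
  coords[1, iO, 1:2] <- coords[1, iC, 1:2]
  expect_error(
    classify_flips(trajectory(traj$atoms, coords[1, , ]),
                   synthetic_sf_selection(spec)),
    "degenerate")
})

test_that("label_states maps signatures to the I-VII vocabulary", {
  sigs <- c("", "A|S4-S3", "B|S4-S3", "A|S3-S2", "C|S2-S1",
            "A|S4-S3+B|S3-S2", "A|S3-S2+A|S1-S0",
            "A|S1-S0+A|S2-S1+A|S3-S2", "D|S1-S0")
  cl <- seq_along(sigs)
  # each "cluster" holds three identical frames
  tr <- label_states(rep(cl, each = 3), rep(sigs, each = 3))
  got <- as.character(tr$state[seq(1, length(sigs) * 3, by = 3)])
  expect_equal(got, c("I", "II", "II'", "III", "IV", "V", "VI", "VII",
                      "other"))
})

test_that("cluster labels use the modal signature; ties prefer fewer flips", {
  cl <- rep(1L, 5)
  sigs <- c("", "", "A|S4-S3", "A|S4-S3", "A|S3-S2")
  tr <- label_states(cl, sigs)
  expect_equal(unname(tr$cluster_states["1"]), "I")  # 2-2 tie, fewer flips
  cl2 <- rep(1L, 3)
  tr2 <- label_states(cl2, c("A|S4-S3", "A|S4-S3", ""))
  expect_equal(unname(tr2$cluster_states["1"]), "II")
})

test_that("noise frames are labeled other", {
  tr <- label_states(c(1L, 1L, -1L), c("", "", ""))
  expect_equal(as.character(tr$state), c("I", "I", "other"))
})

test_that("population tables normalize to 100 over all frames", {
  tr1 <- label_states(rep(1L, 10), rep("", 10))
  pop1 <- population_table(list(only = tr1))
  expect_equal(unname(pop1["only", "I"]), 100)
  expect_equal(sum(pop1), 100)

  set.seed(57)
  states <- sample(c("I", "II", "other"), 997, replace = TRUE)
  pop2 <- population_table(list(x = states))
  expect_equal(sum(pop2["x", ]), 100, tolerance = 1e-9)
})

test_that("a two-state Markov condition recovers its 70/30 stationary split", {
  means <- matrix(c(0, 90), 2, 44)
  ks <- state_kinetics_spec(
    c("I", "II"),
    matrix(c(-0.03, 0.03, 0.07, -0.07), 2, 2, byrow = TRUE),
    means, kappa = Inf, signatures = c("", "A|S4-S3"))
  expect_equal(unname(stationary_distribution(ks)), c(0.7, 0.3))
  sim <- simulate_dihedral_series(ks, 1e5, 0.1, seed = 58)
  # cluster directly on two dihedral columns (the embedding is exercised
  # in the acceptance suite; populations only need the state labels)
  cl <- dbscan_cluster(sim$angles[, 1:2], eps = 5, min_points = 3)
  tr <- label_states(cl, sim$signatures)
  pop <- population_table(list(cond = tr))
  expect_equal(unname(pop["cond", "I"]), 70, tolerance = 2)
  expect_equal(unname(pop["cond", "II"]), 30, tolerance = 2)
})

test_that("sum_states reproduces the printed II + II' arithmetic", {
  tab <- study_populations()
  t2 <- t(tab)                              # conditions as rows
  expect_equal(sum_states(t2, c("II", "II'"), "CHARMM-KWK"), 47.1)
  expect_equal(sum_states(t2, c("II", "II'"), "AMBER-KWK"), 15.6)
  expect_equal(sum_states(t2, character(0), "AMBER-KK"), 0)
})
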