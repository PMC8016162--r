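test_that("dihedral matches hand values for planar arrangements", {
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)), 0)
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)), 180)
})

test_that("dihedral agrees with the atan2 oracle on random quadruples", {
  set.seed(42)
  for (rep in 1:200) {
    pts <- matrix(rnorm(12), 4, 3)
    # resample until the quadruple is non-degenerate
    while (abs(oracle_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])) < 1e-6)
      pts <- matrix(rnorm(12), 4, 3)
    expect_equal(dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                 oracle_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                 tolerance = 1e-9)
  }
})

test_that("dihedral symmetries: order reversal and z mirror", {
  set.seed(43)
  for (rep in 1:50) {
    pts <- matrix(rnorm(12), 4, 3)
    a <- dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    rev <- dihedral(pts[4, ], pts[3, ], pts[2, ], pts[1, ])
    expect_equal(rev, a, tolerance = 1e-9)
    mir <- pts
    mir[, 3] <- -mir[, 3]
    b <- dihedral(mir[1, ], mir[2, ], mir[3, ], mir[4, ])
    if (abs(abs(a) - 180) > 1e-6)
      expect_equal(b, -a, tolerance = 1e-9)
  }
})

test_that("degenerate quadruples raise an undefined-dihedral error", {
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "collinear|coincident")
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear|coincident")
})

test_that("extract_sf_dihedrals recovers the generator's torsions at zero noise", {
  spec <- sf_geometry_spec(angular_noise = 0)
  traj <- build_filter_coordinates(spec, seed = 1)
  sel <- synthetic_sf_selection(spec)
  m <- extract_sf_dihedrals(traj, sel)
  expect_equal(dim(m), c(1, 44))
  phis <- m[1, grepl("_phi$", colnames(m))]
  psis <- m[1, grepl("_psi$", colnames(m))]
  chis <- m[1, grepl("_chi1$", colnames(m))]
  expect_equal(unname(phis), rep(spec$phi, 20), tolerance = 1e-6)
  expect_equal(unname(psis), rep(spec$psi, 20), tolerance = 1e-6)
  expect_equal(unname(chis), rep(spec$chi1, 4), tolerance = 1e-6)
})

test_that("the 44-column plan has the documented labels and order", {
  spec <- sf_geometry_spec()
  traj <- build_filter_coordinates(spec, seed = 1)
  sel <- synthetic_sf_selection(spec)
  m <- extract_sf_dihedrals(traj, sel)
  lbl <- colnames(m)
  expect_length(lbl, 44)
  # chain-major: first 11 labels belong to chain A, ending in its chi1
  expect_true(all(grepl("^A", lbl[1:11])))
  expect_equal(lbl[1], "A129_phi")
  expect_equal(lbl[2], "A129_psi")
  expect_equal(lbl[11], "A129_chi1")
  expect_equal(lbl[12], "B129_phi")
  expect_equal(sum(grepl("_chi1$", lbl)), 4)
})

test_that("multi-frame extraction keeps one row per frame", {
  spec <- sf_geometry_spec(angular_noise = 5)
  base <- build_filter_coordinates(spec, seed = 2)
  nat <- nrow(base$atoms)
  coords <- array(NA_real_, c(7, nat, 3))
  for (f in 1:7) coords[f, , ] <- base$coords[1, , ]
  traj <- trajectory(base$atoms, coords, frame_interval = 0.1)
  m <- extract_sf_dihedrals(traj, synthetic_sf_selection(spec))
  expect_equal(nrow(m), 7)
  expect_true(all(abs(sweep(m, 2, m[1, ])) < 1e-9))
})

test_that("a selection without exactly 4 P-loops is rejected", {
  expect_error(sf_selection(c("A", "B", "C"), c(129, 129, 129)),
               "4 P-loops")
})

test_that("missing atoms are reported with chain, residue and atom name", {
  spec <- sf_geometry_spec()
  traj <- build_filter_coordinates(spec, seed = 1)
  sel <- sf_selection(c("A", "B", "C", "E"), rep(129, 4))
  err <- expect_error(extract_sf_dihedrals(traj, sel))
  expect_match(conditionMessage(err), "chain E")
})

test_that("sincos_expand puts unit-circle pairs in interleaved order", {
  m <- matrix(c(0, 90, -90, 180), 2, 2)
  e <- sincos_expand(m)
  expect_equal(dim(e), c(2, 4))
  expect_equal(e[1, 1:2], c(sin_a1 = 0, cos_a1 = 1))
  expect_equal(e[2, 1:2], c(sin_a1 = 1, cos_a1 = 0))
  set.seed(44)
  r <- matrix(runif(300, -180, 180), 10, 30)
  er <- sincos_expand(r)
  s2c2 <- er[, seq(1, 60, 2)]^2 + er[, seq(2, 60, 2)]^2
  expect_true(all(abs(s2c2 - 1) < 1e-12))
})

test_that("SF backbone RMSD is zero for identical frames and rigid motions", {
  spec <- sf_geometry_spec()
  base <- build_filter_coordinates(spec, seed = 3)
  nat <- nrow(base$atoms)
  rot <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # 90 deg about z
  coords <- array(NA_real_, c(3, nat, 3))
  coords[1, , ] <- base$coords[1, , ]
  coords[2, , ] <- base$coords[1, , ]
  coords[3, , ] <- base$coords[1, , ] %*% rot + matrix(rep(c(5, -3, 2), each = nat), nat, 3)
  traj <- trajectory(base$atoms, coords, frame_interval = 0.1)
  r <- sf_backbone_rmsd(traj, synthetic_sf_selection(spec))
  expect_equal(r[1], 0, tolerance = 1e-6)
  expect_equal(r[2], 0, tolerance = 1e-6)
  expect_equal(r[3], 0, tolerance = 1e-5)
})

test_that("fitted RMSD matches the no-fit oracle for pure residual displacements", {
  spec <- sf_geometry_spec()
  base <- build_filter_coordinates(spec, seed = 4)
  sel <- synthetic_sf_selection(spec)
  nat <- nrow(base$atoms)
  coords <- array(NA_real_, c(2, nat, 3))
  coords[1, , ] <- base$coords[1, , ]
  coords[2, , ] <- base$coords[1, , ]
  # small random displacement of every backbone atom; compare fit = TRUE
  # against the analytic no-fit RMSD after removing the optimal rigid part:
  # for small perturbations the fitted value is <= the no-fit value
  set.seed(5)
  coords[2, , ] <- coords[2, , ] + matrix(rnorm(nat * 3, 0, 0.1), nat, 3)
  traj <- trajectory(base$atoms, coords, frame_interval = 0.1)
  fitted <- sf_backbone_rmsd(traj, sel)[2]
  nofit <- sf_backbone_rmsd(traj, sel, fit = FALSE)[2]
  expect_gt(fitted, 0)
  expect_lte(fitted, nofit + 1e-9)
  # single displaced atom: no-fit RMSD is exactly d / sqrt(n)
  idx <- poreflow:::sf_backbone_indices(base$atoms, sel)
  coords2 <- coords
  coords2[2, , ] <- coords2[1, , ]
  coords2[2, idx[1], 1] <- coords2[2, idx[1], 1] + 0.8
  traj2 <- trajectory(base$atoms, coords2, frame_interval = 0.1)
  expect_equal(sf_backbone_rmsd(traj2, sel, fit = FALSE)[2],
               0.8 / sqrt(length(idx)), tolerance = 1e-9)
})

test_that("axial coordinates are translation invariant and track motion", {
  spec <- sf_geometry_spec()
  base <- build_filter_coordinates(spec, seed = 6)
  sel <- synthetic_sf_selection(spec)
  atoms2 <- rbind(base$atoms,
                  data.frame(atom_name = "K", residue_name = "POT",
                             residue_index = 1L, chain_id = "I",
                             x = 0, y = 0, z = -5))
  class(atoms2) <- class(base$atoms)
  nat <- nrow(atoms2)
  coords <- array(NA_real_, c(2, nat, 3))
  coords[1, , ] <- rbind(base$coords[1, , ], c(0, 0, -5))
  coords[2, , ] <- coords[1, , ] + matrix(rep(c(2, -7, 11), each = nat), nat, 3)
  coords[2, nat, 3] <- coords[2, nat, 3] + 5   # ion moves +5 along z on top
  traj <- trajectory(atoms2, coords, frame_interval = 0.1)
  z <- axial_coordinate(traj, nat, sel)
  expect_equal(z[2, 1] - z[1, 1], 5, tolerance = 1e-9)
})

test_that("xy_distance gives the 3-4-5 answer and z-translation invariance", {
  spec <- sf_geometry_spec()
  base <- build_filter_coordinates(spec, seed = 7)
  sel <- synthetic_sf_selection(spec)
  org <- poreflow:::sf_origin(base, sel)
  atoms2 <- rbind(base$atoms,
                  data.frame(atom_name = "P", residue_name = "LIP",
                             residue_index = 1L, chain_id = "L",
                             x = org[1, 1] + 3, y = org[1, 2] + 4, z = 0))
  class(atoms2) <- class(base$atoms)
  nat <- nrow(atoms2)
  coords <- array(NA_real_, c(2, nat, 3))
  coords[1, , ] <- rbind(base$coords[1, , ],
                         c(org[1, 1] + 3, org[1, 2] + 4, 0))
  coords[2, , ] <- coords[1, , ]
  coords[2, , 3] <- coords[2, , 3] + 25
  traj <- trajectory(atoms2, coords, frame_interval = 0.1)
  d <- xy_distance(traj, nat, sel)
  expect_equal(d[1, 1], 5, tolerance = 1e-9)
  expect_equal(d[2, 1], 5, tolerance = 1e-9)
})
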