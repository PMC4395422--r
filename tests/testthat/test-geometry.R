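# Dihedrals, torsions, C1'...C1' twist, grooves, hydrogen bonds, RMSD,
# average structures and ensemble segmentation.

test_that("dihedral matches an independent plane-normal oracle", {
  # symmetry anchors
  expect_equal(dihedral(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)), 0)
  expect_equal(dihedral(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0), c(2, -1, 0)), 180)
  set.seed(101)
  for (k in 1:1000) {
    pts <- matrix(stats::rnorm(12, sd = 3), 4, 3)
    # skip near-degenerate draws the oracle itself cannot define
    if (min(sqrt(rowSums(diff(pts)^2))) < 0.3) next
    got <- tryCatch(dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                    error = function(e) NA)
    if (is.na(got)) next
    want <- oracle_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    expect_equal(got, want, tolerance = 1e-6 / 360)
  }
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "colinear")
})

test_that("angle outputs are invariant under global rigid motion", {
  set.seed(7)
  d <- fx_b15()
  tor0 <- compute_torsions(d)
  tw0 <- step_twists(d)
  for (k in 1:3) {
    mo <- random_rigid_motion()
    d2 <- d
    d2$xyz <- apply_motion(d$xyz, mo)
    tor2 <- compute_torsions(d2)
    expect_equal(tor2$chi, tor0$chi, tolerance = 1e-6 / 250)
    expect_equal(tor2$epsilon, tor0$epsilon, tolerance = 1e-6 / 180)
    tw2 <- step_twists(d2)
    expect_equal(tw2$twist, tw0$twist, tolerance = 1e-6 / 36)
  }
})

test_that("compute_torsions recovers construction targets and termini rules", {
  d <- fx_b15()
  tor <- compute_torsions(d)
  # every chi in the anti bin, at the prescribed 250 deg
  expect_true(all(classify_chi(tor$chi) == "anti"))
  expect_equal(tor$chi, rep(250, 30), tolerance = 0.5 / 250)
  # alpha absent at the 5' terminus, epsilon/zeta absent at the 3' terminus
  expect_true(is.na(tor$alpha[tor$strand == 1 & tor$pos == 1]))
  expect_true(is.na(tor$epsilon[tor$strand == 1 & tor$pos == d$n]))
  expect_true(is.na(tor$zeta[tor$strand == 1 & tor$pos == d$n]))
  # prescribed backbone torsions reproduced within 0.5 deg everywhere
  tt <- d$torsion_targets$prescribed$pur
  for (nm in c("beta", "gamma", "delta")) {
    expect_true(all(abs(tor[[nm]] - tt[[nm]]) < 0.5, na.rm = TRUE), info = nm)
  }
})

test_that("a hand-placed chi of 79 degrees is measured as 79", {
  # inverse-rotation oracle constructs the fourth atom directly
  p1 <- c(0.3, 1.2, -0.5); p2 <- c(1.5, 0.2, 0.4); p3 <- c(2.8, 1.0, 0.1)
  p4 <- oracle_place_dihedral(p1, p2, p3, 79)
  got <- dihedral(p4, p3, p2, p1)
  expect_equal(got, 79, tolerance = 0.01 / 79)
})

test_that("c1c1_twist reproduces scripted step geometry", {
  pair <- rbind(c(3, 1, 0), c(-3, -1, 0))
  # pure translation along the step axis: no twist
  expect_equal(c1c1_twist(pair, pair + rep(1, 2) %o% c(0, 0, 3.4)), 0)
  # scripted +25 deg rotation about the axis
  R <- rotation_about_(c(0, 0, 1), 25)
  pj <- pair %*% t(R) + rep(1, 2) %o% c(0, 0, 3.4)
  expect_equal(c1c1_twist(pair, pj), 25, tolerance = 1e-6 / 25)
  # antisymmetry about a fixed reference axis
  expect_equal(c1c1_twist(pj, pair, axis = c(0, 0, 1)),
               -c1c1_twist(pair, pj, axis = c(0, 0, 1)), tolerance = 1e-9)
  # degenerate midpoints
  expect_error(c1c1_twist(pair, pair), "undefined twist")
  # B-form builder: 36.0 deg at every step
  tw <- step_twists(fx_b15())
  expect_true(all(abs(tw$twist - 36) < 0.5))
})

test_that("groove widths follow the declared phosphate-offset convention", {
  d <- fx_b15()
  gw <- groove_widths(d)
  inner <- gw$minor[!is.na(gw$minor)]
  expect_gt(length(inner), 5)
  expect_lt(stats::sd(inner), 0.1)      # helical symmetry
  expect_true(all(inner > 0))
  # offsets off the chain are absent
  expect_true(any(is.na(gw$minor)))
  expect_true(any(is.na(gw$major)))
  # toy check: distance equals the hand-computed norm
  p1 <- bzjunction:::atom_xyz(d, 1, 5, "P")
  partner <- d$pairing$pos2[d$pairing$pos1 == 5]
  p2 <- bzjunction:::atom_xyz(d, 2, partner - 3, "P")
  expect_equal(gw$minor[5], sqrt(sum((p1 - p2)^2)))
})

test_that("hydrogen-bond distances resolve specs over frames", {
  d <- fx_b15()
  # builder Watson-Crick bond in range
  h <- hbond_distances(d, "N3(C_1)-N1(G_30)")
  expect_gt(h$distance, 2.7)
  expect_lt(h$distance, 3.1)
  # same atom twice is zero
  expect_equal(hbond_distances(d, "C1'(C_1)-C1'(C_1)")$distance, 0)
  # N frames x k specs rows
  sim <- make_bz_trajectory("CAGCAGCAG", n_frames = 4, seed = 3)
  h2 <- hbond_distances(sim$trajectory,
                        c("N3(C_1)-N1(G_18)", "N1(A_2)-N3(T_17)"))
  expect_equal(nrow(h2), 8)
  expect_error(hbond_distances(d, "XX(C_1)-N1(G_30)"), "does not resolve")
})

test_that("rmsd_fit is a superposition-invariant pseudometric", {
  set.seed(11)
  X <- matrix(stats::rnorm(60), 20, 3)
  expect_equal(rmsd_fit(X, X), 0, tolerance = 1e-10)
  mo <- random_rigid_motion()
  expect_equal(rmsd_fit(apply_motion(X, mo), X), 0, tolerance = 1e-6)
  # 3-atom closed form: equilateral triangle vs a copy with one vertex
  # pulled out along its median keeps the fit analytic after centering
  A <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  B <- rbind(c(0, 0, 0), c(1, 0, 0), c(2 + 0.3, 0, 0))
  # optimal translation shifts by mean offset 0.1; rmsd = sqrt(mean(c(.1,.1,.2)^2))
  expect_equal(rmsd_fit(B, A), sqrt(mean(c(0.1, 0.1, 0.2)^2)), tolerance = 1e-8)
  # symmetry and triangle inequality on random triples
  for (k in 1:10) {
    Y <- X + matrix(stats::rnorm(60, 0, 0.5), 20, 3)
    Z <- X + matrix(stats::rnorm(60, 0, 0.5), 20, 3)
    expect_equal(rmsd_fit(X, Y), rmsd_fit(Y, X), tolerance = 1e-8)
    expect_lte(rmsd_fit(X, Z), rmsd_fit(X, Y) + rmsd_fit(Y, Z) + 1e-9)
  }
  expect_error(rmsd_fit(X[1:5, ], X), "selection error")
})

test_that("rmsd_fit agrees with the bio3d reference implementation", {
  set.seed(13)
  X <- matrix(stats::rnorm(45), 15, 3)
  Y <- X + matrix(stats::rnorm(45, 0, 0.7), 15, 3)
  got <- rmsd_fit(Y, X)
  want <- bio3d::rmsd(as.numeric(t(X)), as.numeric(t(Y)), fit = TRUE)
  expect_equal(got, want, tolerance = 1e-3)
})

test_that("average_structure obeys the half-open window convention", {
  sim <- make_bz_trajectory("CAGCAG", n_frames = 6, seed = 5, dt_ps = 10)
  tr <- sim$trajectory
  # constant trajectory: the average equals any frame
  avg <- average_structure(tr, c(0, 60))
  expect_equal(avg, tr$frames[[1]], tolerance = 1e-9, ignore_attr = TRUE)
  # a translated copy averages back onto the reference
  tr2 <- tr
  tr2$frames <- list(tr$frames[[1]],
                     sweep(tr$frames[[1]], 2, c(-5, 2, 1)))
  tr2$times <- c(0, 10)
  avg2 <- average_structure(tr2, c(0, 20))
  expect_equal(avg2, tr$frames[[1]], tolerance = 1e-7, ignore_attr = TRUE)
  # [start, end) frame counting
  expect_equal(nrow(average_structure(tr, c(0, 30))), nrow(tr$frames[[1]]))
  expect_error(average_structure(tr, c(1000, 2000)), "window error")
  # frames at t = 0,10,20 fall in [0,30); t = 30 does not
  cnt <- sum(tr$times >= 0 & tr$times < 30)
  expect_equal(cnt, 3)
})

test_that("RMSD ensemble segmentation recovers planted levels", {
  set.seed(42)
  series <- c(stats::rnorm(60, 2.8, 0.3), stats::rnorm(100, 4.7, 0.3),
              stats::rnorm(80, 6.2, 0.3))
  seg <- segment_rmsd_ensembles(series, min_dwell = 10)
  expect_equal(nrow(seg), 3)
  expect_equal(seg$mean, c(2.8, 4.7, 6.2), tolerance = 0.2 / 2.8)
  # flat series: one segment
  flat <- stats::rnorm(100, 3, 0.1)
  expect_equal(nrow(segment_rmsd_ensembles(flat, min_dwell = 10)), 1)
  # separation below threshold: one segment
  two <- c(stats::rnorm(50, 3, 0.2), stats::rnorm(50, 3.3, 0.2))
  expect_equal(nrow(segment_rmsd_ensembles(two, min_dwell = 10)), 1)
})
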