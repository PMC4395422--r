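# Builders and mock trajectories: construction recovery, determinism,
# and graceful degradation with noise.

test_that("B builder realizes its fiber parameters exactly", {
  d <- fx_b15()
  expect_equal(nrow(residue_table(d)), 30)
  tw <- step_twists(d)
  expect_true(all(abs(tw$twist - 36) < 0.5))
  expect_true(all(abs(tw$rise - 3.38) < 0.05))
  tor <- compute_torsions(d)
  expect_true(all(classify_chi(tor$chi) == "anti"))
  # Watson-Crick donor-acceptor distances within range at every pair
  for (i in c(1, 5, 12)) {
    reg <- classify_hbond_registry(d, pos = i)
    expect_false(identical(reg[1], "none"))
    dd <- attr(reg, "distances")
    expect_true(all(dd > 2.7 & dd < 3.1))
  }
  expect_error(build_b_duplex("CTXG"), "sequence error")
})

test_that("Z builder realizes the left-handed dinucleotide repeat", {
  z <- fx_zcg()
  tw <- step_twists(z)
  # alternating -9 / -51: mean per dinucleotide -30 +/- 1
  din <- (tw$twist[seq(1, 10, 2)] + tw$twist[seq(2, 10, 2)]) / 2
  expect_true(all(abs(din - (-30)) < 1))
  tor <- compute_torsions(z)
  pur <- tor$resid %in% c("A", "G")
  expect_true(all(classify_chi(tor$chi[pur]) == "plus_syn"))
  st <- bzjunction:::step_classification(z)
  # purine -> pyrimidine steps carry a Z signature
  pu_py <- which(substr(st$step_label, 1, 1) == "G")
  expect_true(all(as.character(st$z_signature[pu_py]) != "none"))
  expect_error(build_z_duplex(""), "sequence error")
})

test_that("builders reproduce their declared torsion targets within 0.5 deg", {
  for (d in list(fx_b15(), fx_zcg())) {
    tor <- compute_torsions(d)
    rt <- residue_table(d)
    for (cls in c("pur", "pyr")) {
      tt <- d$torsion_targets$prescribed[[cls]]
      sel <- if (cls == "pur") rt$resid %in% c("A", "G") else rt$resid %in% c("C", "T")
      if (!any(sel)) next
      for (nm in c("beta", "gamma", "delta", "chi")) {
        err <- abs(tor[[nm]][sel] - tt[[nm]])
        err <- pmin(err, 360 - err)
        expect_true(all(err < 0.5, na.rm = TRUE),
                    info = paste(d$helix, cls, nm))
      }
    }
  }
})

test_that("builder output feeds every analysis operation without warnings", {
  d <- fx_b15()
  expect_no_warning(compute_torsions(d))
  expect_no_warning(step_twists(d))
  expect_no_warning(groove_widths(d))
  expect_no_warning(bzjunction:::step_classification(d))
})

test_that("trajectory generation is deterministic given the seed", {
  s1 <- make_bz_trajectory("CAGCAGCAG", z_window = 4:5, n_frames = 6,
                           noise_sigma = 0.2, seed = 9,
                           events = list(list(kind = "flip", pos = 5,
                                              frames = 2:5, from = 250,
                                              to = 79, direction = "cis")))
  s2 <- make_bz_trajectory("CAGCAGCAG", z_window = 4:5, n_frames = 6,
                           noise_sigma = 0.2, seed = 9,
                           events = list(list(kind = "flip", pos = 5,
                                              frames = 2:5, from = 250,
                                              to = 79, direction = "cis")))
  expect_identical(s1$trajectory$frames, s2$trajectory$frames)
  expect_identical(s1$truth, s2$truth)
  # different seed changes the noise
  s3 <- make_bz_trajectory("CAGCAGCAG", z_window = 4:5, n_frames = 6,
                           noise_sigma = 0.2, seed = 10)
  expect_false(identical(s1$trajectory$frames[[1]], s3$trajectory$frames[[1]]))
})

test_that("noise-free single-frame output equals the base structure", {
  sim <- make_bz_trajectory("CAGCAG", n_frames = 1, noise_sigma = 0, seed = 1)
  d <- build_b_duplex("CAGCAG")
  expect_equal(sim$trajectory$frames[[1]], d$xyz, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(make_bz_trajectory("CAGCAG", z_window = 9:10), "range error")
})

test_that("label accuracy degrades gracefully with coordinate noise", {
  acc_at <- function(sigma) {
    sim <- make_bz_trajectory("CAGCAGCAGCAGCAGCAG", z_window = 8:11,
                              n_frames = 4, noise_sigma = sigma, seed = 31)
    tr <- sim$trajectory
    st <- bzjunction:::step_classification(tr, seq_along(tr$frames))
    mean(as.character(label_steps(st)$label) == sim$truth$labels[1, ])
  }
  accs <- vapply(c(0, 0.1, 0.2, 0.3), acc_at, 0)
  expect_equal(accs[1], 1)          # noise-free plants recover exactly
  expect_true(all(diff(accs) <= 1e-9))
})
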