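test_that("build_system bookkeeping matches the declared architecture", {
  p <- synthetic_params(ref_body = list(n_beads = 20,
                                        radius_of_curvature = 60),
                        mobile_bodies = 8, linkers = 10)
  sys <- build_system(p)
  expect_equal(nrow(sys$coords), 38L)
  expect_equal(n_residues(sys$topology), 38L)
  lay <- bead_layout(p)
  expect_equal(lay$n_beads, 38L)
  expect_equal(region_of(sys$topology, lay$rod[1]), "BAR")
  expect_equal(region_of(sys$topology, lay$linker[[1]][1]), "LINKER")
  expect_equal(region_of(sys$topology, lay$body[[1]][1]), "PDZ")
  # rod alone: all bonded distances equal the bond length
  p0 <- synthetic_params(ref_body = list(n_beads = 12,
                                         radius_of_curvature = 60))
  sys0 <- build_system(p0)
  bl <- sqrt(rowSums((sys0$coords[sys0$bonds$i, ] -
                        sys0$coords[sys0$bonds$j, ])^2))
  expect_equal(bl, rep(3.8, 11), tolerance = 1e-9)
})

test_that("built systems respect the hard-sphere exclusion", {
  for (nm in preset_names()) {
    sys <- build_system(load_preset(nm))
    expect_gte(min_nonbonded_distance(sys),
               2 * sys$params$bead_radius)
  }
})

test_that("invalid parameterizations are rejected", {
  expect_error(synthetic_params(mobile_bodies = 8), "one length per")
  expect_error(synthetic_params(tails = 0), "positive")
  expect_error(synthetic_params(
    tails = 4, sticky_pairs = data.frame(i = 1, j = 99, eps = 1)),
    "nonexistent")
  expect_error(synthetic_params(
    tails = 4, sticky_pairs = data.frame(i = 1, j = 5, eps = -1)),
    ">= 0")
})

test_that("identical seeds give bit-identical trajectories", {
  p <- load_preset("two_state_toy")
  sys <- build_system(p)
  a <- run_mc(sys, seed = 123, n_steps = 30000)
  b <- run_mc(sys, seed = 123, n_steps = 30000)
  expect_identical(a$coords, b$coords)
  c2 <- run_mc(sys, seed = 124, n_steps = 30000)
  expect_false(identical(a$coords, c2$coords))
  # ensemble members are distinct deterministic streams
  e1 <- simulate_ensemble(p, n_traj = 2, seed = 9, system = sys)
  e2 <- simulate_ensemble(p, n_traj = 2, seed = 9, system = sys)
  expect_identical(e1$trajectories[[1]]$coords, e2$trajectories[[1]]$coords)
  expect_false(identical(e1$trajectories[[1]]$coords,
                         e1$trajectories[[2]]$coords))
})

test_that("sampled frames respect hard spheres and bond envelopes", {
  p <- load_preset("system1_like")
  sys <- build_system(p)
  tr <- run_mc(sys, seed = 31, n_steps = 60000, record_interval = 300)
  hc <- 2 * p$bead_radius
  sigma <- 1 / sqrt(2 * p$bond_k)
  worst_bond <- 0
  for (f in seq_len(n_frames(tr))) {
    fr <- frame_coords(tr, f)
    expect_gte(min_nonbonded_distance(sys, fr), hc)
    bl <- sqrt(rowSums((fr[sys$bonds$i, ] - fr[sys$bonds$j, ])^2))
    worst_bond <- max(worst_bond, abs(bl - p$bond_length))
  }
  # a Boltzmann-distributed bond exceeds 3 sigma ~0.3% of the time, so the
  # envelope check uses 6 sigma (violation odds ~1e-9 per sample)
  expect_lt(worst_bond, 6 * sigma)
})

test_that("acceptance fraction is strictly between 0 and 1 for presets", {
  for (nm in preset_names()) {
    sys <- build_system(load_preset(nm))
    tr <- run_mc(sys, seed = 2, n_steps = 20000, record_interval = 1000,
                 n_equil = 0)
    acc <- attr(tr, "acceptance_rate")
    expect_gt(acc, 0)
    expect_lt(acc, 1)
  }
})

test_that("symmetric sticky pairs calibrate to equal probabilities", {
  p <- load_preset("system1_like")
  p$n_steps <- 300000L
  gt <- calibrate_ground_truth(p, n_steps_factor = 1)
  expect_equal(nrow(gt), 2L)
  expect_true(all(gt$probability_pct >= 0 & gt$probability_pct <= 100))

  # equality check on a longer run; binding is a rare-event process, so the
  # spread of a time-fraction estimate is governed by the number of binding
  # events, not the frame count: se ~ p * sqrt(2 / n_events)
  sys <- build_system(p)
  tr <- run_mc(sys, seed = 77, n_steps = 2000000L)
  pairs <- as.matrix(p$sticky_pairs[, c("i", "j")])
  pr <- contact_probability(tr, pairs, sys$topology)
  ne <- vapply(1:2, function(k)
    nrow(contact_events(tr, pairs[k, ], sys$topology)), 1L)
  se <- pr * sqrt(2 / pmax(ne, 1))
  tol <- 4 * sqrt(sum(se^2)) + 1
  expect_lt(abs(pr[1] - pr[2]), tol)
})

test_that("a pair held far apart by construction calibrates to ~0%", {
  p <- synthetic_params(ref_body = list(n_beads = 30,
                                        radius_of_curvature = 60),
                        tails = 3,
                        sticky_pairs = data.frame(i = 30, j = 33, eps = 0),
                        n_steps = 50000, record_interval = 100,
                        n_equil = 1000, seed = 3)
  # tail (reach ~15 A) attached at rod bead 1; rod bead 30 is ~100 A away
  gt <- calibrate_ground_truth(p, n_steps_factor = 1)
  expect_equal(gt$probability_pct, 0)
})

test_that("free linker ignores planted wells when depths are zero", {
  p <- load_preset("two_state_toy")
  p$sticky_pairs$eps <- 0
  sys <- build_system(p)
  tr <- run_mc(sys, seed = 17, n_steps = 200000)
  p2 <- p; p2$sticky_pairs <- NULL
  sys2 <- build_system(p2)
  sys2$topology <- sys$topology      # sticky set absent otherwise
  tr2 <- run_mc(sys2, seed = 17, n_steps = 200000)
  expect_identical(tr$coords, tr2$coords)
})
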