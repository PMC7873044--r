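make_blob_positions <- function(n = 3000, weights = c(0.5, 0.3, 0.2),
                                centers = rbind(c(0, 0, 0), c(30, 0, 0),
                                                c(0, 30, 0)), sd = 1.5) {
  k <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  xyz <- centers[k, ] + matrix(rnorm(3 * n, sd = sd), n, 3)
  data.frame(trajectory = "t", frame = seq_len(n), copy = "A",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

test_that("mobile positions count one observation per frame and copy", {
  p <- load_preset("system1_like")
  sys <- build_system(p)
  ens <- simulate_ensemble(p, n_traj = 2, seed = 4, system = sys)
  ens$trajectories <- lapply(ens$trajectories, function(tr) {
    tr$coords <- tr$coords[1:50, , , drop = FALSE]; tr
  })
  pos <- mobile_positions(ens, sys$topology, "PDZ", "BAR",
                          reference = sys$coords)
  expect_equal(nrow(pos), 2 * 50 * 2)      # 2 trajectories x 50 frames x 2 copies
  expect_setequal(unique(pos$copy), c("B", "C"))
})

test_that("positions are invariant under per-frame global rigid motions", {
  set.seed(19)
  p <- load_preset("system1_like")
  sys <- build_system(p)
  tr <- run_mc(sys, seed = 6, n_steps = 6000, record_interval = 300)
  pos <- mobile_positions(tr, sys$topology, "PDZ", "BAR",
                          reference = sys$coords)
  moved <- tr
  for (f in seq_len(n_frames(tr)))
    moved$coords[f, , ] <- random_rigid_motion(frame_coords(tr, f))
  pos2 <- mobile_positions(moved, sys$topology, "PDZ", "BAR",
                           reference = sys$coords)
  expect_equal(pos2$x, pos$x, tolerance = 1e-6)
  expect_equal(pos2$y, pos$y, tolerance = 1e-6)
  expect_equal(pos2$z, pos$z, tolerance = 1e-6)
})

test_that("a rigidly attached mobile unit has zero positional variance", {
  # trajectory whose frames are rigid motions of one structure
  set.seed(23)
  p <- synthetic_params(ref_body = list(n_beads = 12,
                                        radius_of_curvature = 60),
                        mobile_bodies = 6, linkers = 4)
  sys <- build_system(p)
  frames <- array(NA_real_, c(8, nrow(sys$coords), 3))
  for (f in 1:8) frames[f, , ] <- random_rigid_motion(sys$coords)
  tr <- cg_trajectory(frames)
  pos <- mobile_positions(tr, sys$topology, "PDZ", "BAR",
                          reference = sys$coords)
  expect_lt(max(apply(pos[, c("x", "y", "z")], 2, sd)), 1e-6)
})

test_that("k-means recovers planted blob weights and centroids", {
  set.seed(101)
  pos <- make_blob_positions(n = 10000)
  cl <- cluster_positions(pos, k = 3, seed = 5)
  expect_equal(sum(cl$fractions), 100, tolerance = 1e-9)
  expect_equal(cl$fractions, c(50, 30, 20), tolerance = 2)   # abs pp
  planted <- rbind(c(0, 0, 0), c(30, 0, 0), c(0, 30, 0))
  for (k in 1:3) {
    d <- sqrt(rowSums(sweep(planted, 2, cl$centroids[k, ])^2))
    expect_lt(min(d), 0.5)
  }
})

test_that("degenerate clustering cases behave as declared", {
  pos <- data.frame(trajectory = "t", frame = 1:6, copy = "A",
                    x = 1, y = 2, z = 3)
  c1 <- cluster_positions(pos, k = 1, seed = 1)
  expect_equal(c1$fractions, 100)
  expect_equal(unname(c1$centroids[1, ]), c(1, 2, 3))
  # k = n: every fraction is 100/n
  set.seed(3)
  pos2 <- make_blob_positions(n = 8)
  cn <- cluster_positions(pos2, k = 8, seed = 1)
  expect_equal(cn$fractions, rep(100 / 8, 8))
  expect_error(cluster_positions(pos2, k = 9), "between 1 and")
  expect_error(cluster_positions(pos2, k = 0), "between 1 and")
})

test_that("clustering is deterministic and order-invariant", {
  set.seed(33)
  pos <- make_blob_positions(n = 2000)
  a <- cluster_positions(pos, k = 3, seed = 11)
  b <- cluster_positions(pos, k = 3, seed = 11)
  expect_identical(a$centroids, b$centroids)
  expect_identical(a$fractions, b$fractions)
  perm <- sample.int(nrow(pos))
  c2 <- cluster_positions(pos[perm, ], k = 3, seed = 11)
  expect_equal(sort(c2$fractions), sort(a$fractions), tolerance = 1e-9)
  ord <- order(a$centroids[, 1], a$centroids[, 2])
  ord2 <- order(c2$centroids[, 1], c2$centroids[, 2])
  expect_equal(c2$centroids[ord2, ], a$centroids[ord, ], tolerance = 1e-6)
})

test_that("occupancy report flags covering clusters", {
  top <- chain_topology(6, "BAR")
  ref <- cbind(seq_len(6) * 3.8, 0, 0)
  top$special_sets$patch <- c(2L, 3L)
  pos <- data.frame(trajectory = "t", frame = 1:4, copy = "A",
                    x = c(7.6, 7.6, 200, 200), y = 0, z = 0)
  cl <- cluster_positions(pos, k = 2, seed = 1)
  rep1 <- occupancy_report(cl, top, "patch", reference = ref)
  on_patch <- which.min(rep1$min_dist)
  expect_equal(rep1$min_dist[on_patch], 0)
  expect_true(rep1$covering[on_patch])
  expect_false(rep1$covering[-on_patch])
  expect_gt(rep1$min_dist[-on_patch], 100)
  expect_error(occupancy_report(cl, top, "nope", reference = ref),
               "no special set")
})

test_that("planted sticky site attracts the top cluster; eps 0 does not", {
  p <- load_preset("system1_like")
  p$sticky_pairs <- p$sticky_pairs[1, ]      # one site, on the rod
  p$sticky_pairs$eps <- 6                    # strong planted preference
  p$mobile_bodies <- p$mobile_bodies[1]; p$linkers <- p$linkers[1]
  sys <- build_system(p)
  tr <- run_mc(sys, seed = 21, n_steps = 900000L)
  pos <- mobile_positions(tr, sys$topology, "PDZ", "BAR",
                          reference = sys$coords)
  cl <- cluster_positions(pos, k = 3, seed = 2)
  rep1 <- occupancy_report(cl, sys$topology, "sticky_ref",
                           reference = sys$coords)
  expect_true(rep1$covering[1])              # top cluster sits on the site
  p0 <- p; p0$sticky_pairs$eps <- 0
  sys0 <- build_system(p0)
  tr0 <- run_mc(sys0, seed = 21, n_steps = 900000L)
  pos0 <- mobile_positions(tr0, sys0$topology, "PDZ", "BAR",
                           reference = sys0$coords)
  cl0 <- cluster_positions(pos0, k = 3, seed = 2)
  rep0 <- occupancy_report(cl0, sys0$topology, "sticky_ref",
                           reference = sys0$coords)
  expect_false(rep0$covering[1])
})
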