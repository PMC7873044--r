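test_that("kabsch superposition recovers exact rigid motions", {
  set.seed(4)
  a <- matrix(rnorm(30, sd = 10), 10, 3)
  s0 <- kabsch_superpose(a, a)
  expect_equal(s0$rmsd, 0, tolerance = 1e-12)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)
  # 90-degree rotation about z plus translation
  rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  b <- t(rz %*% t(a)) + matrix(c(5, -3, 2), 10, 3, byrow = TRUE)
  s1 <- kabsch_superpose(b, a)
  expect_lt(s1$rmsd, 1e-9)
  expect_equal(s1$rotation %*% rz, diag(3), tolerance = 1e-9)
  expect_equal(det(s1$rotation), 1, tolerance = 1e-9)
  expect_equal(apply_superposition(b, s1), a, tolerance = 1e-9)
})

test_that("kabsch RMSD agrees with the quaternion-method oracle", {
  set.seed(5)
  for (rep in 1:25) {
    a <- matrix(rnorm(30, sd = 8), 10, 3)
    b <- matrix(rnorm(30, sd = 8), 10, 3)
    expect_equal(kabsch_superpose(a, b)$rmsd, oracle_kabsch_rmsd(a, b),
                 tolerance = 1e-9)
  }
})

test_that("collinear fit selections raise a conditioning error", {
  line <- cbind(seq_len(5) * 3.8, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("rmsd series is zero for rigid motions and follows d/sqrt(N)", {
  set.seed(6)
  ref <- matrix(rnorm(36, sd = 9), 12, 3)
  frames <- array(NA_real_, c(5, 12, 3))
  for (f in 1:5) frames[f, , ] <- random_rigid_motion(ref)
  tr <- cg_trajectory(frames)
  expect_lt(max(rmsd_series(tr, reference = ref)), 1e-9)
  # one residue displaced by d with the fit held on the others
  d <- 7
  disp <- ref; disp[12, ] <- disp[12, ] + c(d, 0, 0)
  tr2 <- cg_trajectory(array(disp, c(1, 12, 3)))
  val <- rmsd_series(tr2, reference = ref, fit_selection = 1:11,
                     calc_selection = 1:12)
  expect_equal(val, d / sqrt(12), tolerance = 1e-9)
})

test_that("rmsd series is invariant under global rigid motion of all frames", {
  set.seed(16)
  frames <- array(rnorm(4 * 10 * 3, sd = 12), c(4, 10, 3))
  tr <- cg_trajectory(frames)
  base <- rmsd_series(tr)
  q <- qr.Q(qr(matrix(rnorm(9), 3))); if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- c(11, -4, 7)
  moved <- frames
  for (f in 1:4)
    moved[f, , ] <- t(q %*% t(frames[f, , ])) +
      matrix(shift, 10, 3, byrow = TRUE)
  tr2 <- cg_trajectory(moved)
  expect_equal(rmsd_series(tr2), base, tolerance = 1e-9)
})

test_that("radius of gyration matches closed forms and invariances", {
  expect_equal(radius_of_gyration(matrix(c(0, 0, 0, 4, 0, 0), 2, 3,
                                         byrow = TRUE)), 2)
  # N collinear beads spacing d: Rg = d * sqrt((N^2 - 1) / 12)
  for (n in c(3, 5, 20)) {
    line <- cbind(seq_len(n) * 3.8, 0, 0)
    expect_equal(radius_of_gyration(line), 3.8 * sqrt((n^2 - 1) / 12),
                 tolerance = 1e-12)
  }
  expect_equal(radius_of_gyration(cbind(1:3 * 3.8, 0, 0)),
               3.8 * sqrt(2 / 3), tolerance = 1e-12)
  set.seed(11)
  fr <- matrix(rnorm(45, sd = 10), 15, 3)
  rg <- radius_of_gyration(fr)
  for (rep in 1:5)
    expect_equal(radius_of_gyration(random_rigid_motion(fr)), rg,
                 tolerance = 1e-9)
  # Rg never exceeds the maximum pairwise distance
  expect_lte(rg, max(dist(fr)))
})

test_that("anchor distances reproduce exact geometry", {
  top <- chain_topology(4, "BAR")
  coords <- array(0, c(2, 4, 3))
  coords[1, 2, ] <- c(3, 4, 0)               # frame 1: distance 5
  coords[2, 2, ] <- c(0, 0, 0)               # frame 2: coincident
  tr <- cg_trajectory(coords)
  expect_equal(anchor_distance_series(tr, top, c(1L, 2L)), c(5, 0))
  # rigid synthetic rod: end-to-end constant at 3.8 * (B - 1) when straight
  p <- synthetic_params(ref_body = list(n_beads = 8,
                                        radius_of_curvature = 1e9),
                        tails = 2, n_steps = 1000, record_interval = 100,
                        n_equil = 0)
  sys <- build_system(p)
  tr2 <- run_mc(sys, seed = 1)
  d <- anchor_distance_series(tr2, sys$topology, c(1L, 8L))
  expect_equal(d, rep(3.8 * 7, n_frames(tr2)), tolerance = 1e-6)
})

test_that("distributions normalize, bin correctly and report the median", {
  d1 <- make_distribution(rep(2.5, 100), bins = 10)
  expect_equal(sum(d1$frequency), 1)
  expect_equal(sum(d1$frequency > 0), 1L)
  set.seed(14)
  v <- rnorm(5000, 30, 5)
  d2 <- make_distribution(v, bins = 40)
  expect_equal(sum(d2$frequency), 1, tolerance = 1e-12)
  expect_equal(d2$median, median(v))
  expect_true(all(diff(d2$breaks) > 0))
  expect_error(make_distribution(numeric()), "non-empty")
  expect_error(make_distribution(v, bins = c(1, 1)), "strictly increasing")
})
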