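test_that("contact criterion boundary and separation rules are exact", {
  top <- chain_topology(10, "PDZ")
  frame <- matrix(0, 10, 3)
  frame[, 1] <- seq(0, by = 100, length.out = 10)   # spread out
  # residues 1 and 6: separation 5, at 7.9 A -> contact
  frame[6, ] <- c(7.9, 0, 0)
  expect_true(any(detect_contacts(frame, top)[, 1] == 1 &
                    detect_contacts(frame, top)[, 2] == 6))
  # residues 1 and 4: separation 3 < 5 -> never a contact
  frame[4, ] <- c(3.8, 0, 0)
  dc <- detect_contacts(frame, top)
  expect_false(any(dc[, 1] == 1 & dc[, 2] == 4))
  # exactly 8.000 is a contact, 8.001 is not
  frame2 <- matrix(seq(0, by = 100, length.out = 30), 10, 3)
  frame2[6, ] <- frame2[1, ] + c(8.0, 0, 0)
  expect_true(nrow(detect_contacts(frame2, top)) == 1)
  frame2[6, ] <- frame2[1, ] + c(8.001, 0, 0)
  expect_true(nrow(detect_contacts(frame2, top)) == 0)
})

test_that("inter-chain pairs bypass the sequence-separation rule", {
  top <- chain_topology(4, "BAR", chains = 2L)   # chains A(1:2), B(3:4)
  frame <- matrix(c(0, 0, 0,   3.8, 0, 0,
                    0, 3, 0,   100, 0, 0), 4, 3, byrow = TRUE)
  dc <- detect_contacts(frame, top)
  # (1,3): different chains, 3 A apart -> contact despite adjacency
  expect_true(any(dc[, 1] == 1 & dc[, 2] == 3))
  # (1,2): same chain, separation 1 -> excluded
  expect_false(any(dc[, 1] == 1 & dc[, 2] == 2))
})

test_that("detect_contacts matches the brute-force oracle on random frames", {
  set.seed(42)
  top <- chain_topology(60, "BAR", chains = 2L)
  for (rep in 1:20) {
    frame <- matrix(runif(180, 0, 30), 60, 3)
    got <- detect_contacts(frame, top)
    ref <- oracle_contacts(frame, top)
    expect_equal(unname(got), unname(ref))
  }
})

test_that("detection is invariant under global rigid motion", {
  set.seed(7)
  top <- chain_topology(30, "PDZ")
  frame <- matrix(runif(90, 0, 25), 30, 3)
  base <- detect_contacts(frame, top)
  for (rep in 1:5)
    expect_equal(detect_contacts(random_rigid_motion(frame), top), base)
})

test_that("cutoff and separation monotonicity hold", {
  set.seed(8)
  top <- chain_topology(40, "BAR")
  frame <- matrix(runif(120, 0, 25), 40, 3)
  key <- function(m) paste(m[, 1], m[, 2])
  c8 <- detect_contacts(frame, top, contact_criterion(cutoff = 8))
  c10 <- detect_contacts(frame, top, contact_criterion(cutoff = 10))
  expect_true(all(key(c8) %in% key(c10)))
  s5 <- detect_contacts(frame, top, contact_criterion())
  s8 <- detect_contacts(frame, top,
                        contact_criterion(min_sequence_separation = 8))
  expect_true(all(key(s8) %in% key(s5)))
})

test_that("contact probability counts pooled frames with equal weight", {
  top <- two_bead_topology()
  s1 <- c(rep(TRUE, 21), rep(FALSE, 79))        # 21 of 100
  tr <- traj_from_series(s1)
  expect_equal(contact_probability(tr, c(1L, 2L), top), 21)
  expect_equal(contact_probability(traj_from_series(rep(FALSE, 50)),
                                   c(1L, 2L), top), 0)
  # unequal-length trajectories weight by length
  ens <- cg_ensemble(traj_from_series(rep(TRUE, 30), label = "a"),
                     traj_from_series(rep(FALSE, 10), label = "b"))
  expect_equal(contact_probability(ens, c(1L, 2L), top), 75)
})

test_that("contact map is symmetric, bounded and NA on excluded cells", {
  set.seed(9)
  top <- chain_topology(20, "BAR", chains = 2L)
  coords <- array(runif(5 * 20 * 3, 0, 20), c(5, 20, 3))
  tr <- cg_trajectory(coords)
  a <- 1:8; b <- 11:18
  m1 <- contact_map(tr, a, b, top)
  m2 <- contact_map(tr, b, a, top)
  expect_equal(m1$map, t(m2$map))
  expect_true(all(m1$map[!is.na(m1$map)] >= 0 & m1$map[!is.na(m1$map)] <= 100))
  # same-group map: diagonal and near-diagonal excluded by separation
  ms <- contact_map(tr, 1:10, 1:10, top)
  expect_equal(sum(is.na(ms$map)),
               sum(!pair_eligible(top, rep(1:10, 10), rep(1:10, each = 10))))
  # permanently close residues hit 100%
  coords2 <- array(0, c(4, 20, 3))
  coords2[, , 1] <- matrix(seq(0, by = 30, length.out = 20), 4, 20,
                           byrow = TRUE)
  coords2[, 11, ] <- coords2[, 1, ]     # residue 11 (chain B) on top of 1
  m100 <- contact_map(cg_trajectory(coords2), 1L, 11L, top)
  expect_equal(unname(m100$map[1, 1]), 100)
})

test_that("log-percentage transform applies floor and log10", {
  m <- matrix(c(10, 100, 0, NA), 2, 2)
  lg <- log_percentage(m, floor_pct = 0.01)
  expect_equal(lg[1, 1], 1)
  expect_equal(lg[2, 1], 2)
  expect_equal(lg[1, 2], -2)
  expect_true(is.na(lg[2, 2]))
  expect_error(log_percentage(m, floor_pct = 0), "floor_pct > 0")
})

test_that("contact events are maximal per-trajectory runs with censor flags", {
  top <- two_bead_topology()
  ev <- contact_events(traj_from_series(c(0, 1, 1, 1, 0)), c(1L, 2L), top)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_frame, 2L)
  expect_equal(ev$length_frames, 3L)
  expect_false(ev$censored)
  ev2 <- contact_events(traj_from_series(c(1, 1, 0, 1)), c(1L, 2L), top)
  expect_equal(ev2$length_frames, c(2L, 1L))
  expect_true(all(ev2$censored))
  # events never span trajectory boundaries
  ens <- cg_ensemble(traj_from_series(c(0, 1, 1), label = "a"),
                     traj_from_series(c(1, 1, 0), label = "b"))
  ev3 <- contact_events(ens, c(1L, 2L), top)
  expect_equal(nrow(ev3), 2L)
  expect_equal(ev3$trajectory, c("a", "b"))
  expect_true(all(ev3$censored))
})

test_that("lifetime statistics follow the 1e5-step unit convention", {
  top <- two_bead_topology()
  ev <- contact_events(traj_from_series(c(0, 1, 1, 1, 0)), c(1L, 2L), top)
  lt <- lifetime_stats(ev, 10000)
  expect_equal(lt$mean, 0.3)
  expect_equal(lt$sd, 0)
  ev2 <- contact_events(traj_from_series(c(1, 1, 0, 1, 0)), c(1L, 2L), top)
  lt2 <- lifetime_stats(ev2, 10000)
  expect_equal(lt2$mean, 0.15)
  expect_equal(lt2$sd, 0.05)          # population SD
  expect_equal(lifetime_stats(ev2, 10000, sd_type = "sample")$sd,
               sd(c(0.2, 0.1)))
  expect_error(lifetime_stats(ev2[0, ], 10000), "undefined")
})

test_that("lifetime estimator recovers a planted geometric persistence", {
  # two-state Markov chain with stay probability q: run lengths are
  # geometric with mean 1/(1-q)
  set.seed(13)
  q <- 0.8
  n <- 20000L
  s <- logical(n); s[1] <- FALSE
  r <- runif(n)
  for (f in 2:n) s[f] <- if (s[f - 1]) r[f] < q else r[f] < 0.2
  top <- two_bead_topology()
  ev <- contact_events(traj_from_series(s, interval = 100000L),
                       c(1L, 2L), top)
  lt <- lifetime_stats(ev, 100000L)       # unit = 1 frame
  expected <- 1 / (1 - q)                  # 5 frames
  se <- (sqrt(q) / (1 - q)) / sqrt(lt$n_events)
  expect_lt(abs(lt$mean - expected), 3 * se)
})

test_that("probability equals summed event frames over total frames", {
  set.seed(21)
  top <- two_bead_topology()
  for (rep in 1:10) {
    s <- runif(200) < runif(1)
    tr <- traj_from_series(s)
    p <- contact_probability(tr, c(1L, 2L), top)
    ev <- contact_events(tr, c(1L, 2L), top)
    tot <- if (nrow(ev)) sum(ev$length_frames) else 0
    expect_equal(p, 100 * tot / 200)
    expect_lte(tot, 200)
  }
})

test_that("top pairs rank by probability then lifetime then index", {
  top <- chain_topology(8, "PDZ", chains = 2L)   # A: 1-4, B: 5-8
  # craft series for three inter-chain pairs with known stats
  nf <- 100L
  coords <- array(0, c(nf, 8, 3))
  for (r in 1:8) coords[, r, 1] <- r * 50
  put <- function(i, j, s) {
    # place residue j near i in frames where s is TRUE
    coords[s, j, ] <<- coords[s, i, ] + c(5, 0, 0)
  }
  # pair (1,5): 40%, runs of 4; pair (2,6): 40%, runs of 8; (3,7): 20%
  put(1, 5, rep(c(rep(TRUE, 4), rep(FALSE, 6)), 10))
  put(2, 6, rep(c(rep(TRUE, 8), rep(FALSE, 12)), 5))
  put(3, 7, rep(c(rep(TRUE, 2), rep(FALSE, 8)), 10))
  tr <- cg_trajectory(coords)
  tp <- top_pairs(tr, top, "PDZ", "PDZ", n = 2)
  expect_equal(nrow(tp), 2L)
  # tie on 40%: longer lifetime first
  expect_equal(c(tp$i[1], tp$j[1]), c(2L, 6L))
  expect_equal(c(tp$i[2], tp$j[2]), c(1L, 5L))
  # N larger than universe returns all qualifying pairs
  tp_all <- top_pairs(tr, top, "PDZ", "PDZ", n = 1000)
  expect_true(nrow(tp_all) >= 3)
  expect_true(all(diff(tp_all$probability_pct) <= 0))
})

test_that("interaction classification matches the hydropathy rules", {
  top1 <- load_topology(fixture_path("pick1_system1_like.yaml"))
  # V50-L114: both hydrophobic
  expect_equal(classify_interaction(c(50, 114), top1), "HYDROPHOBIC")
  # S130 with S608 (= chain B serine): polar pair
  expect_equal(classify_interaction(c(130, 608), top1), "POLAR")
  top2 <- load_topology(fixture_path("pick1_system2_like.yaml"))
  # K209-D347: opposite charges
  expect_equal(classify_interaction(c(209, 347), top2), "ELECTROSTATIC")
  # LYS-LYS within the basic patch: mixed
  expect_equal(classify_interaction(c(251, 252), top2), "MIXED")
  # UNK residue: UNKNOWN with warning
  topu <- cg_topology(data.frame(index = 1:2, chain_id = "A",
                                 local_index = 1:2,
                                 name = c("UNK", "GLY"), region = "OTHER"))
  expect_warning(cls <- classify_interaction(c(1, 2), topu), "UNK")
  expect_equal(cls, "UNKNOWN")
})
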