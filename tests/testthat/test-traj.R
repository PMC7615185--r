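# Trajectory selectivity metrics against brute-force oracles.

rand_traj <- function(n_atoms = 20, n_frames = 5, seed = 1) {
  set.seed(seed)
  atoms <- data.frame(index = 1:n_atoms,
                      name = sample(c("CA", "CB", "O", "N"), n_atoms, TRUE),
                      resname = sample(c("ALA", "TYR", "HOH"), n_atoms, TRUE),
                      resno = sample(1:9, n_atoms, TRUE),
                      chain = "A",
                      element = sample(c("C", "O", "N"), n_atoms, TRUE),
                      stringsAsFactors = FALSE)
  coords <- array(stats::runif(n_atoms * 3 * n_frames, -20, 20),
                  c(n_atoms, 3, n_frames))
  trajectory_bundle(atoms, coords)
}

test_that("selection grammar resolves conjunctions and rejects misses", {
  tr <- rand_traj()
  idx <- select_atoms(tr, "resi 3")
  expect_true(all(tr$atoms$resno[idx] == 3))
  idx2 <- select_atoms(tr, "resn HOH and elem O")
  expect_true(all(tr$atoms$resname[idx2] == "HOH" &
                  tr$atoms$element[idx2] == "O"))
  expect_error(select_atoms(tr, "resi 999"), "matches no atoms")
  expect_error(select_atoms(tr, "bogus 1"), "unknown selection key")
  expect_equal(select_atoms(tr, c(2L, 5L)), c(2L, 5L))
})

test_that("distances reproduce hand geometry and the pairwise oracle", {
  atoms <- data.frame(index = 1:3, name = c("A1", "A2", "B1"),
                      resname = "XXX", resno = c(1, 1, 2), chain = "A",
                      element = "C", stringsAsFactors = FALSE)
  xyz <- array(0, c(3, 3, 1))
  xyz[1, , 1] <- c(0, 0, 0)
  xyz[2, , 1] <- c(2, 0, 0)
  xyz[3, , 1] <- c(10, 0, 0)
  tr <- trajectory_bundle(atoms, xyz)
  expect_equal(distance_series(tr, "resi 1 and name A1", "resi 2"), 10)
  expect_equal(distance_series(tr, "resi 1", "resi 2", "centroid"), 9)
  xyz[2, , 1] <- c(3, 4, 0)
  tr2 <- trajectory_bundle(atoms, xyz)
  expect_equal(distance_series(tr2, 1L, 2L), 5)

  # min-pair against exhaustive brute force on random frames
  tr3 <- rand_traj(n_atoms = 60, n_frames = 50, seed = 8)
  ia <- 1:25; ib <- 26:60
  d_fast <- distance_series(tr3, ia, ib, "min_pair")
  d_brute <- vapply(1:50, function(f) {
    best <- Inf
    for (a in ia) for (b in ib)
      best <- min(best, sqrt(sum((tr3$coords[a, , f] -
                                  tr3$coords[b, , f])^2)))
    best
  }, numeric(1))
  expect_equal(d_fast, d_brute, tolerance = 1e-9)
})

test_that("hysteresis classifier ignores chatter inside the band", {
  # oscillation fully inside the band after an initial tight entry
  d <- c(3, rep(c(5.4, 5.6), 50))
  s <- classify_two_state(d, 5, 6)
  expect_equal(s$transitions, 0L)
  expect_equal(unname(s$occupancy["tight"]), 1)

  all_tight <- classify_two_state(rep(4, 10), 5, 6)
  expect_equal(unname(all_tight$occupancy["tight"]), 1)

  # frames before any crossing stay undefined
  s2 <- classify_two_state(c(5.5, 5.5, 6.5, 5.5, 4.9), 5, 6)
  expect_equal(as.character(s2$states),
               c("undefined", "undefined", "loose", "loose", "tight"))
  expect_error(classify_two_state(1:3, 6, 5), "below")
})

test_that("classifier recovers the Markov generator's occupancy", {
  g <- gen_trajectory(n_frames = 10000, seed = 20230830)
  d <- distance_series(g$traj, "resi 222 and name OH",
                       "resi 102 and name CZ2")
  s <- classify_two_state(d, 5.2, 5.8)
  truth_frac <- mean(g$truth$params$states == "tight")
  # classification itself is near-exact for well-separated states
  expect_equal(unname(s$occupancy["tight"]), truth_frac, tolerance = 0.002)
  # realized fraction converges to the stationary value; SE includes the
  # chain autocorrelation 1 - (p_tl + p_lt)
  p <- g$truth$params$stationary_tight
  rho <- exp(-(0.3 + 0.7))   # one-frame autocorrelation of the chain
  se <- sqrt(p * (1 - p) / 10000 * (1 + rho) / (1 - rho))
  expect_lt(abs(truth_frac - p), 2 * se)
})

test_that("hydration counting is inclusive, permutation-safe and monotone", {
  fx <- system.file("extdata", "synthetic_k_coordination.pdb",
                    package = "kcrkit")
  tr <- read_pdb_topology(fx)
  h <- hydration_number(tr, "resn K", "resn HOH and name O", 3.5)
  expect_equal(h$counts, 2)

  # boundary inclusion and permutation invariance
  atoms <- data.frame(index = 1:3, name = c("K", "O", "O"),
                      resname = c("K", "HOH", "HOH"), resno = c(1, 2, 3),
                      chain = "A", element = c("K", "O", "O"),
                      stringsAsFactors = FALSE)
  xyz <- array(0, c(3, 3, 1))
  xyz[2, , 1] <- c(3.5, 0, 0)    # exactly at the cutoff
  xyz[3, , 1] <- c(0, 8, 0)
  tr2 <- trajectory_bundle(atoms, xyz)
  expect_equal(hydration_number(tr2, "resn K", "resn HOH", 3.5)$counts, 1)
  perm <- c(3, 1, 2)
  tr2p <- trajectory_bundle(atoms[perm, ], xyz[perm, , , drop = FALSE])
  expect_equal(hydration_number(tr2p, "resn K", "resn HOH", 3.5)$counts, 1)
  for (cut in c(2, 3.5, 8, 9)) {
    h_lo <- hydration_number(tr2, "resn K", "resn HOH", cut)$counts
    h_hi <- hydration_number(tr2, "resn K", "resn HOH", cut + 0.5)$counts
    expect_gte(h_hi, h_lo)
  }
  expect_error(hydration_number(tr2, "resn HOH", "resn K"), "exactly one")
})

test_that("generator hydration shells match the configured counts", {
  g <- gen_trajectory(n_frames = 40, n_shell_bound = 2, n_shell_unbound = 6,
                      binding_schedule = data.frame(start_frame = 11,
                                                    end_frame = 30),
                      seed = 2)
  h <- hydration_number(g$traj, "resn K", "resn HOH and name O", 3.5)
  expect_equal(h$counts[11:30], rep(2, 20))
  expect_equal(h$counts[c(1:10, 31:40)], rep(6, 20))
})

test_that("contact occupancy and binding events agree with run-length logic", {
  d <- c(3, 3, 6, 3, 6, 6, 3, 3, 3, 6)
  ev <- detect_binding_events(d, cutoff_a = 4, min_dwell = 1)
  expect_equal(ev$events$start_frame, c(1, 4, 7))
  expect_equal(ev$events$end_frame, c(2, 4, 9))
  expect_equal(ev$bound_fraction, 0.6)
  ev2 <- detect_binding_events(d, cutoff_a = 4, min_dwell = 2)
  expect_equal(nrow(ev2$events), 2)
  expect_equal(detect_binding_events(rep(10, 5), 4)$bound_fraction, 0)

  # alternate contact/no-contact gives exactly 0.5
  atoms <- data.frame(index = 1:2, name = c("NH1", "OD1"),
                      resname = c("ARG", "ASP"), resno = c(244, 116),
                      chain = "A", element = c("N", "O"),
                      stringsAsFactors = FALSE)
  xyz <- array(0, c(2, 3, 10))
  xyz[2, 1, ] <- rep(c(2.9, 8), 5)
  tr <- trajectory_bundle(atoms, xyz)
  co <- contact_occupancy(tr, "resi 244", "resi 116", 4.0)
  expect_equal(co$fraction, 0.5)
  # bound fraction with min_dwell 1 equals contact occupancy
  ev3 <- detect_binding_events(co$distances, 4.0, 1)
  expect_equal(ev3$bound_fraction, co$fraction)

  static <- trajectory_bundle(atoms, array(c(0, 0, 0, 2.9, 0, 0),
                                           c(2, 3, 1)))
  expect_equal(contact_occupancy(static, 1L, 2L, 4.0)$fraction, 1)
})
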