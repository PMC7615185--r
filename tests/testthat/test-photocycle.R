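# Photocycle scheme propagation, cube synthesis, SVD, global and target
# fitting, and pyranine differencing.

test_that("single-species decay and the Bateman chain solution are exact", {
  sc1 <- photocycle_scheme(c("A", "ground"),
                           rbind(c(0, 3), c(0, 0)), c(A = 1))
  tt <- c(0, 0.1, 0.5, 1, 2)
  p1 <- propagate_scheme(sc1, tt)
  expect_equal(unname(p1["A", ]), exp(-3 * tt), tolerance = 1e-12)

  p2 <- propagate_scheme(chain2_scheme(2, 1), tt)
  expect_equal(unname(p2["B", ]), 2 * (exp(-tt) - exp(-2 * tt)),
               tolerance = 1e-10)
})

test_that("population is conserved and matches a stiff ODE oracle", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(2:5, 1)
    sp <- c(paste0("S", 1:n), "ground")
    K <- matrix(0, n + 1, n + 1, dimnames = list(sp, sp))
    # random sparse forward topology
    for (a in 1:n) {
      targets <- sample((a + 1):(n + 1), min(2, n + 1 - a))
      K[a, targets] <- 10^stats::runif(length(targets), -1, 2)
    }
    sc <- photocycle_scheme(sp, K, stats::setNames(0.8, "S1"))
    tt <- 10^seq(-3, 1, length.out = 25)
    p <- propagate_scheme(sc, tt)
    expect_lt(max(abs(colSums(p) - 1)), 1e-9)
    # brute-force stiff integration oracle
    A <- t(K) - diag(rowSums(K))
    ode <- deSolve::lsoda(sc$init, c(0, tt),
                          function(t, y, parms) list(A %*% y),
                          rtol = 1e-10, atol = 1e-12)
    expect_equal(unname(p), unname(t(ode[-1, -1])), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("degenerate (defective) rate matrices fall back to the ODE path", {
  # equal-rate chain: A -> B -> ground with k1 = k2 is defective
  p <- propagate_scheme(chain2_scheme(1, 1), c(0.5, 1, 2))
  expect_equal(attr(p, "method"), "ode")
  expect_equal(unname(p["B", ]), c(0.5, 1, 2) * exp(-c(0.5, 1, 2)),
               tolerance = 1e-8)
})

test_that("cube synthesis is linear in populations", {
  wl <- seq(350, 650, by = 5)
  spectra <- band_spectra(c("A", "B"), wl, c(420, 560))
  tt <- c(0.1, 1)
  zero <- synthesize_cube(matrix(0, 2, 2, dimnames = list(c("A", "B"))),
                          spectra, wl, tt)
  expect_true(all(zero$delta_a == 0))
  one <- synthesize_cube(matrix(c(1, 0, 1, 0), 2, 2,
                                dimnames = list(c("A", "B"))),
                         spectra, wl, tt)
  expect_equal(one$delta_a[, 1], spectra$A)
  half <- synthesize_cube(matrix(0.5, 2, 2, dimnames = list(c("A", "B"))),
                          spectra, wl, tt)
  expect_equal(half$delta_a[, 1], (spectra$A + spectra$B) / 2)
  expect_error(synthesize_cube(one <- matrix(1, 1, 2,
                                             dimnames = list("A")),
                               list(A = 1:3), wl, tt), "grid mismatch")
})

test_that("svd_rank finds the constructed rank, noiseless and at SNR 100", {
  wl <- seq(350, 650, by = 2)
  tt <- 10^seq(-5, 0, length.out = 60)
  spectra <- band_spectra(paste0("S", 1:4), wl, c(380, 450, 520, 600))
  sc <- chain_scheme(c(3000, 300, 30, 3))
  pops <- propagate_scheme(sc, tt)
  cube <- synthesize_cube(pops, spectra, wl, tt)
  expect_equal(svd_rank(cube)$rank, 4L)

  rank1 <- synthesize_cube(pops["S1", , drop = FALSE], spectra["S1"], wl, tt)
  expect_equal(svd_rank(rank1)$rank, 1L)

  set.seed(20230830)
  noisy <- cube
  noisy$delta_a <- noisy$delta_a +
    matrix(stats::rnorm(length(noisy$delta_a),
                        0, max(abs(noisy$delta_a)) / 100),
           nrow(noisy$delta_a))
  expect_equal(svd_rank(noisy)$rank, 4L)
})

test_that("SVD reconstruction from significant components explains the cube", {
  wl <- seq(350, 650, by = 2)
  tt <- 10^seq(-5, 0, length.out = 60)
  spectra <- band_spectra(paste0("S", 1:3), wl, c(400, 500, 600))
  cube <- synthesize_cube(propagate_scheme(chain_scheme(c(1000, 100, 10)),
                                           tt), spectra, wl, tt)
  r <- svd_rank(cube)
  k <- seq_len(r$rank)
  recon <- r$u[, k, drop = FALSE] %*%
    diag(r$singular_values[k], r$rank) %*% t(r$v[, k, drop = FALSE])
  expect_gt(1 - sum((cube$delta_a - recon)^2) / sum(cube$delta_a^2), 0.99)
})

test_that("global exponential fit recovers chain relaxation eigenvalues", {
  wl <- seq(350, 650, by = 2)
  tt <- 10^seq(-5, 0.5, length.out = 80)
  rates <- c(2000, 160, 12)
  spectra <- band_spectra(paste0("S", 1:3), wl, c(400, 500, 600))
  cube <- synthesize_cube(propagate_scheme(chain_scheme(rates), tt),
                          spectra, wl, tt)
  gf <- global_exponential_fit(cube, 3)
  expect_equal(sort(1 / gf$tau, decreasing = TRUE), rates, tolerance = 0.1)
  expect_lt(gf$residual_norm, 1e-6 * sqrt(sum(cube$delta_a^2)))

  # single component, noiseless: exact tau and DAS
  one <- synthesize_cube(propagate_scheme(chain_scheme(50), tt)["S1", ,
                                                                drop = FALSE],
                         spectra["S1"], wl, tt)
  g1 <- global_exponential_fit(one, 1)
  expect_equal(g1$tau, 1 / 50, tolerance = 1e-6)
  expect_equal(as.numeric(g1$das), spectra$S1, tolerance = 1e-6)
})

test_that("target fitting recovers two-step chain rates and flags degeneracy", {
  wl <- seq(350, 650, by = 2)
  tt <- 10^seq(-5, 1, length.out = 80)
  spectra <- band_spectra(c("A", "B"), wl, c(420, 560))
  sc <- chain2_scheme(40, 4)
  cube <- synthesize_cube(propagate_scheme(sc, tt), spectra, wl, tt)
  ft <- fit_target_scheme(cube, sc)
  expect_equal(unname(ft$rates), c(40, 4), tolerance = 1e-3)
  expect_true(ft$identifiable)

  # equal-rate chain: eigenvalues coincide, identifiability warning
  sc_deg <- chain2_scheme(5, 5)
  cube_deg <- synthesize_cube(propagate_scheme(sc_deg, tt), spectra, wl, tt)
  expect_warning(fit_target_scheme(cube_deg, sc_deg,
                                   init_rates = c(5, 5), n_starts = 1),
                 "unidentifiable")

  # over-parameterized topology is rejected up front
  sp <- c("A", "B", "ground")
  K <- rbind(c(0, 1, 1), c(1, 0, 1), c(0, 0, 0))
  dimnames(K) <- list(sp, sp)
  over <- photocycle_scheme(sp, K, c(A = 1))
  expect_error(fit_target_scheme(cube, over), "non-identifiable")
})

test_that("pyranine differencing returns the release lag", {
  tt <- seq(0, 0.02, by = 1e-5)
  rise <- function(t0) ifelse(tt < t0, 0, 1 - exp(-(tt - t0) / 5e-4))
  m1 <- rise(2e-3)                       # reference M1 rise
  release <- rise(3e-3)                  # proton release 1 ms later
  pr <- proton_release_trace(tt, with_dye = release + 0.2 * m1,
                             without_dye = 0.2 * m1,
                             ref_times_s = tt, ref_trace = m1)
  expect_equal(pr$difference, release, tolerance = 1e-12)
  expect_equal(pr$lag_s, 1e-3, tolerance = 2e-5)

  same <- proton_release_trace(tt, m1, m1, ref_times_s = tt, ref_trace = m1)
  expect_true(all(same$difference == 0))
  expect_error(proton_release_trace(tt, m1, m1, ref_times_s = tt,
                                    ref_trace = rep(1, length(tt))),
               "half-rise")
})
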