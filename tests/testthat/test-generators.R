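# Determinism and pipeline compatibility of the synthetic-data
# generators.

test_that("generators are pure functions of (params, seed)", {
  sol <- kna_solutions()
  p <- permeability_set(1, 1 / 25.7, 0)
  a <- gen_iv_dataset(p, sol, noise_sd_pa = 2, seed = 77)
  b <- gen_iv_dataset(p, sol, noise_sd_pa = 2, seed = 77)
  expect_identical(a$recording$currents_pa, b$recording$currents_pa)
  c <- gen_iv_dataset(p, sol, noise_sd_pa = 2, seed = 78)
  expect_false(identical(a$recording$currents_pa, c$recording$currents_pa))

  t1 <- gen_trajectory(n_frames = 50, seed = 5)
  t2 <- gen_trajectory(n_frames = 50, seed = 5)
  expect_identical(t1$traj$coords, t2$traj$coords)

  s1 <- gen_spectrum("hckcr1_wt_dark", noise_sd = 0.01, seed = 3)
  s2 <- gen_spectrum("hckcr1_wt_dark", noise_sd = 0.01, seed = 3)
  expect_identical(s1$spectrum$absorbance, s2$spectrum$absorbance)

  # generators do not disturb the caller's RNG stream
  set.seed(123); before <- stats::runif(3)
  set.seed(123); invisible(gen_photocurrent(noise_sd_pa = 1, seed = 9))
  expect_identical(stats::runif(3), before)
})

test_that("iv generator: flat at gmax 0, analytic zero crossing otherwise", {
  sol <- kna_solutions()
  p <- permeability_set(1, 1 / 25.7, 0)
  flat <- gen_iv_dataset(p, sol, gmax = 0)
  expect_true(all(flat$recording$currents_pa == 0))

  d <- gen_iv_dataset(p, sol)
  est <- estimate_erev(d$recording, measure = "steady")
  expect_equal(est$value_mv, d$truth$params$erev_mv, tolerance = 0.01)
  expect_error(gen_iv_dataset(p, sol, voltages_mv = c(-200, 0)),
               "150 mV")
})

test_that("photocurrent generator truth is recovered by the fitters", {
  g <- gen_photocurrent(off_components = list(amplitude_pa = -150,
                                              tau_s = 0.02))
  off <- g$time_s > g$light_off_s
  fit <- fit_exponential_kinetics(g$time_s[off], g$current_pa[off], 1)
  expect_equal(fit$tau, 0.02, tolerance = 1e-3)
  expect_equal(fit$amplitudes, -150, tolerance = 0.01)

  m <- extract_photocurrent_metrics(g$time_s, g$current_pa,
                                    g$light_on_s, g$light_off_s)
  expect_equal(m$steady_pa, -150, tolerance = 1)
  expect_error(gen_photocurrent(on_components = list(amplitude_pa = 1,
                                                     tau_s = -1)),
               "tau")
})

test_that("transient-absorption generator: zero input, rank and noise", {
  sc0 <- photocycle_scheme(c("A", "ground"), rbind(c(0, 5), c(0, 0)),
                           c(A = 0))
  wl <- seq(330, 700, by = 5)
  g0 <- gen_transient_absorption(scheme = sc0,
                                 spectra = band_spectra("A", wl, 500),
                                 wavelengths_nm = wl,
                                 times_s = 10^seq(-3, 0, length.out = 20))
  expect_true(all(g0$cube$delta_a == 0))

  g <- gen_transient_absorption(snr = Inf,
                                times_s = 10^seq(-6, 1, length.out = 60),
                                wavelengths_nm = seq(330, 700, by = 4))
  expect_equal(svd_rank(g$cube)$rank, 4L)  # 4 distinct bands by design
  gn <- gen_transient_absorption(snr = 50, seed = 6,
                                 times_s = 10^seq(-6, 1, length.out = 60),
                                 wavelengths_nm = seq(330, 700, by = 4))
  expect_equal(stats::sd(gn$cube$delta_a - g$cube$delta_a),
               gn$truth$params$noise_sd, tolerance = 0.02)
})

test_that("trajectory generator honours switch-rate and schedule contracts", {
  frozen <- gen_trajectory(n_frames = 200, k_tight_to_loose = 0,
                           k_loose_to_tight = 0, start_state = "tight",
                           seed = 12)
  expect_true(all(frozen$truth$params$states == "tight"))
  d <- distance_series(frozen$traj, "resi 222 and name OH",
                       "resi 102 and name CZ2")
  s <- classify_two_state(d, 5.2, 5.8)
  expect_equal(unname(s$occupancy["tight"]), 1)
  expect_error(gen_trajectory(d_tight_a = 7, d_loose_a = 4), "below")
})

test_that("every generator output satisfies its consumer's preconditions", {
  sol <- kna_solutions()
  expect_s3_class(gen_iv_dataset(permeability_set(1, 0.05, 0),
                                 sol)$recording, "iv_recording")
  expect_s3_class(gen_spectrum(lambda_max_nm = 450)$spectrum, "spectrum")
  g <- gen_titration_series()
  expect_no_error(fit_titration_pka(g$ph, g$absorbance))
  m <- gen_melting_curve()
  expect_no_error(fit_sigmoid_midpoint(m$temperature_c, m$response))
  ch <- gen_chromatogram(c("all-trans-15-syn" = 0.5, "13-cis-15-anti" = 0.5))
  expect_no_error(unmix_composition(
    integrate_peaks(ch$time_min, ch$absorbance, ch$windows)))
  tr <- gen_trajectory(n_frames = 10, seed = 3)
  expect_no_error(hydration_number(tr$traj, "resn K",
                                   "resn HOH and name O"))
  f <- gen_fip_trace(stim_on_s = 20, stim_off_s = 30, dip_fraction = 0.1)
  expect_no_error(compute_dff_metrics(f$time_s, f$fluor, 20, 30))
})
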