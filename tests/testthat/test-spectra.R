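# Lambda-max extraction, spectral shifts, titration and sigmoid fits.

test_that("packaged pigment presets reproduce the printed maxima", {
  wt1 <- gen_spectrum("hckcr1_wt_dark")$spectrum
  expect_equal(as.numeric(find_lambda_max(wt1)), 521)
  expect_equal(as.numeric(find_lambda_max(
    gen_spectrum("hckcr1_d105n")$spectrum)), 508)
  expect_equal(as.numeric(find_lambda_max(
    gen_spectrum("hckcr1_d229n")$spectrum)), 386)
  expect_equal(as.numeric(find_lambda_max(
    gen_spectrum("hckcr2_wt_dark")$spectrum)), 486)
})

test_that("parabolic refinement resolves off-grid peaks within 0.5 nm", {
  set.seed(21)
  for (i in 1:20) {
    centre <- stats::runif(1, 420, 560)
    fwhm <- stats::runif(1, 20, 60)
    wl <- seq(250, 750, by = 5)  # coarse grid, centre off-grid
    s <- spectrum(wl, exp(-0.5 * ((wl - centre) /
                                  (fwhm / 2.355))^2))
    expect_equal(as.numeric(find_lambda_max(s, refine = TRUE)), centre,
                 tolerance = 0.5)
  }
})

test_that("flat and edge-peaked spectra are rejected", {
  wl <- 400:500
  expect_error(find_lambda_max(spectrum(wl, rep(1, length(wl)))), "flat")
  expect_error(find_lambda_max(spectrum(wl, wl)), "edge")
})

test_that("spectral shifts are antisymmetric and match the printed values", {
  a <- gen_spectrum("hckcr1_wt_dark")$spectrum
  b <- gen_spectrum("hckcr2_wt_dark")$spectrum
  expect_equal(spectral_shift(a, a), 0)
  expect_equal(spectral_shift(a, b), 35)
  expect_equal(spectral_shift(b, a), -35)
  expect_equal(spectral_shift(a, gen_spectrum("hckcr1_d229n")$spectrum), 135)
  expect_equal(spectral_shift(a, gen_spectrum("hckcr1_d105n")$spectrum), 13)
})

test_that("titration fits recover pKa and Hill coefficient", {
  g <- gen_titration_series(pka = 4.0, hill_n = 1, ph = 2:11)
  fit <- fit_titration_pka(g$ph, g$absorbance)
  expect_equal(fit$pka, 4.0, tolerance = 0.0025)
  expect_equal(fit$hill_n, 1, tolerance = 0.01)
  # midpoint identity on the fitted curve
  a_mid <- fit$a_low + (fit$a_high - fit$a_low) /
    (1 + 10^(fit$hill_n * (fit$pka - fit$pka)))
  expect_equal(a_mid, (fit$a_low + fit$a_high) / 2)

  set.seed(9)
  for (i in 1:10) {
    pka <- stats::runif(1, 3, 10)
    n <- stats::runif(1, 0.5, 2)
    g <- gen_titration_series(pka = pka, hill_n = n,
                              ph = seq(1, 12, by = 0.5))
    fit <- fit_titration_pka(g$ph, g$absorbance)
    expect_equal(fit$pka, pka, tolerance = 0.02)
    expect_equal(fit$hill_n, n, tolerance = 0.02)
  }
})

test_that("double-transition titrations leave a diagnostic residual", {
  ph <- seq(1, 12, by = 0.25)
  y2 <- 1 / (1 + 10^(2 * (3.5 - ph))) + 1 / (1 + 10^(2 * (9 - ph)))
  fit2 <- fit_titration_pka(ph, y2)
  g <- gen_titration_series(pka = 6, ph = ph)
  fit1 <- fit_titration_pka(g$ph, g$absorbance)
  expect_gt(fit2$residual_norm, 100 * max(fit1$residual_norm, 1e-8))
})

test_that("4PL melting fits recover Tm and honour normalization", {
  g <- gen_melting_curve(tm_c = 60)
  fit <- fit_sigmoid_midpoint(g$temperature_c, g$response, normalize_to = 4)
  expect_equal(fit$midpoint, 60, tolerance = 0.002)
  # the 4 degree reference maps to 1 after normalization
  g2 <- gen_melting_curve(tm_c = 55, upper = 250)  # arbitrary raw units
  i4 <- which(g2$temperature_c == 4)
  norm <- g2$response / g2$response[i4]
  fit2 <- fit_sigmoid_midpoint(g2$temperature_c, g2$response,
                               normalize_to = 4)
  expect_equal(fit2$midpoint, 55, tolerance = 0.01)
  expect_equal(norm[i4], 1)
  expect_error(fit_sigmoid_midpoint(g$temperature_c,
                                    rep(1, length(g$temperature_c))),
               "flat")
})

test_that("log-axis sigmoid fit returns a concentration-scale midpoint", {
  conc <- 10^seq(-9, -4, by = 0.5)
  y <- 1 / (1 + (5e-7 / conc))          # midpoint 5e-7 on log axis
  fit <- fit_sigmoid_midpoint(conc, y, log_x = TRUE)
  expect_equal(fit$midpoint, 5e-7, tolerance = 0.05)
})
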