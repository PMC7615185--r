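# Synthetic-data generators with serialized ground truth.  Every
# generator is a pure function of (parameters, seed): regeneration with
# the same arguments is bit-identical.  Defaults emulate the
# experimental conditions the analysis stages were designed for.

DEFAULT_SEED <- 20230830

# run expr with a locally seeded RNG, restoring global state afterwards
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# ground-truth record serialized alongside every dataset
.truth <- function(generator, params, seed) {
  list(generator = generator, params = params, seed = seed)
}

#' GHK constant-field flux current (single ion)
#'
#' The constant-field current for an ion of valence z:
#' I = P z^2 F^2 V / (RT) * ([C]_i - [C]_o exp(-zFV/RT)) /
#' (1 - exp(-zFV/RT)), evaluated in the V -> 0 limit by its Taylor
#' expansion.  Used by the I-V generator; the analysis side never
#' depends on it.
#'
#' @param v_mv Membrane voltage (mV).
#' @param c_out,c_in Concentrations (mM).
#' @param p Relative permeability.
#' @param z Valence.
#' @param temperature Temperature (K).
#' @return Current in arbitrary units proportional to p.
#' @export
ghk_flux_current <- function(v_mv, c_out, c_in, p, z = 1,
                             temperature = 298) {
  u <- z * v_mv / (1000 * .GAS_R * temperature / .FARADAY)  # zFV/RT
  small <- abs(u) < 1e-6
  out <- numeric(length(v_mv))
  eu <- exp(-u[!small])
  out[!small] <- p * z * u[!small] * (c_in - c_out * eu) / (1 - eu)
  out[small] <- p * z * (c_in - c_out) +
    p * z * u[small] * (c_in + c_out) / 2
  out
}

#' Generate a synthetic voltage-clamp I-V family
#'
#' Per-step currents follow the summed GHK constant-field fluxes of K,
#' Na and Cl scaled by `gmax`, gated on during the light window with
#' mono-exponential activation (and mono-exponential deactivation after
#' light-off), plus additive Gaussian noise.  The zero-current voltage
#' of the noiseless family equals the analytic GHK reversal potential.
#'
#' @param perms A [permeability_set()] (ground truth).
#' @param sol A [solution_pair()].
#' @param voltages_mv Voltage grid (mV), within +/- 150 mV; default the
#'   -96..+4 mV, 10 mV-spaced selectivity protocol.
#' @param gmax Conductance scale (pA per flux unit).
#' @param noise_sd_pa Additive noise SD (pA).
#' @param tau_on_s,tau_off_s Gating time constants (s).
#' @param duration_s,light_on_s,light_off_s,sampling_hz Protocol timing.
#' @param seed RNG seed.
#' @return List: `recording` ([iv_recording()]), `truth`.
#' @export
gen_iv_dataset <- function(perms, sol,
                           voltages_mv = seq(-96, 4, by = 10),
                           gmax = 10, noise_sd_pa = 0,
                           tau_on_s = 0.002, tau_off_s = 0.01,
                           duration_s = 1, light_on_s = 0.2,
                           light_off_s = 0.7, sampling_hz = 5000,
                           seed = DEFAULT_SEED) {
  stopifnot(inherits(perms, "permeability_set"), inherits(sol, "solution_pair"))
  if (any(abs(voltages_mv) > 150))
    stop("voltage grid must lie within +/- 150 mV", call. = FALSE)
  tgrid <- seq(0, duration_s, by = 1 / sampling_hz)
  gate <- numeric(length(tgrid))
  lit <- tgrid >= light_on_s & tgrid <= light_off_s
  gate[lit] <- 1 - exp(-(tgrid[lit] - light_on_s) / tau_on_s)
  post <- tgrid > light_off_s
  g_end <- 1 - exp(-(light_off_s - light_on_s) / tau_on_s)
  gate[post] <- g_end * exp(-(tgrid[post] - light_off_s) / tau_off_s)
  steady <- vapply(voltages_mv, function(v) {
    ghk_flux_current(v, .conc(sol, "outer", "K"), .conc(sol, "inner", "K"),
                     perms$p_K, 1, sol$temperature) +
    ghk_flux_current(v, .conc(sol, "outer", "Na"), .conc(sol, "inner", "Na"),
                     perms$p_Na, 1, sol$temperature) +
    ghk_flux_current(v, .conc(sol, "outer", "Cl"), .conc(sol, "inner", "Cl"),
                     perms$p_Cl, -1, sol$temperature)
  }, numeric(1))
  currents <- .with_seed(seed, {
    m <- outer(gate, gmax * steady)
    if (noise_sd_pa > 0)
      m <- m + matrix(stats::rnorm(length(m), 0, noise_sd_pa), nrow(m))
    m
  })
  rec <- iv_recording(tgrid, voltages_mv, currents, light_on_s, light_off_s,
                      sampling_hz, junction_corrected = TRUE)
  list(recording = rec,
       truth = .truth("gen_iv_dataset",
                      list(p_K = perms$p_K, p_Na = perms$p_Na,
                           p_Cl = perms$p_Cl,
                           erev_mv = ghk_reversal_voltage(perms, sol),
                           gmax = gmax, noise_sd_pa = noise_sd_pa), seed))
}

# unit-peak Gaussian band on a wavelength grid
.gauss_band <- function(wl, centre, fwhm) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  exp(-0.5 * ((wl - centre) / s)^2)
}

#' Default species difference spectra for the parallel-chain scheme
#'
#' Gaussian bands (30 nm FWHM by default) centred at the probe
#' wavelengths of the flash-photolysis intermediates -- 617 nm for the K
#' pair, 480 nm for the spectrally indistinguishable L/N set, 384 and
#' 404 nm for the two M states -- each minus the dark-state band at 521
#' nm so the ground state contributes zero difference absorbance.
#' Paired intermediates share one band, so the default cube has
#' spectral rank 4 while its kinetics carry all eight rates.
#'
#' @param wavelengths_nm Wavelength grid (default 330-700 nm, 1 nm).
#' @param centres Named vector of band centres (nm) per intermediate.
#' @param fwhm_nm Band FWHM (nm).
#' @param dark_centre_nm Dark-state band centre (nm).
#' @return Named list of difference spectra.
#' @export
kcr_species_spectra <- function(wavelengths_nm = seq(330, 700, by = 1),
                                centres = c(K1 = 617, K2 = 617, L1 = 480,
                                            L2 = 480, N1 = 480, N2 = 480,
                                            M1 = 384, M2 = 404),
                                fwhm_nm = 30, dark_centre_nm = 521) {
  dark <- .gauss_band(wavelengths_nm, dark_centre_nm, 100)
  lapply(centres, function(cc)
    .gauss_band(wavelengths_nm, cc, fwhm_nm) - dark)
}

#' Default spectral grouping of the paired-chain intermediates
#'
#' Matches [kcr_species_spectra()]: both K states share one band, the
#' four L/N states share one, and each M state has its own.
#'
#' @return Named character vector mapping species to group labels.
#' @export
kcr_spectral_groups <- function() {
  c(K1 = "K", K2 = "K", L1 = "LN", L2 = "LN", N1 = "LN", N2 = "LN",
    M1 = "M1", M2 = "M2")
}

#' Generate a synthetic transient-absorption cube
#'
#' Propagates the scheme, synthesizes the cube from the species
#' difference spectra, and adds Gaussian noise with SD = peak |dA| /
#' SNR.
#'
#' @param scheme A [photocycle_scheme()] (default [kcr_default_scheme()]).
#' @param spectra Named list of species difference spectra (default
#'   [kcr_species_spectra()] on `wavelengths_nm`).
#' @param wavelengths_nm Wavelength grid (nm).
#' @param times_s Time grid (default log-spaced 1 us to 10 s).
#' @param snr Signal-to-noise ratio (peak |dA| / noise SD); `Inf` for
#'   noiseless.
#' @param seed RNG seed.
#' @return List: `cube` ([ta_cube()]), `populations`, `truth`.
#' @export
gen_transient_absorption <- function(scheme = kcr_default_scheme(),
                                     spectra = NULL,
                                     wavelengths_nm = seq(330, 700, by = 1),
                                     times_s = 10^seq(-6, 1,
                                                      length.out = 250),
                                     snr = Inf, seed = DEFAULT_SEED) {
  if (is.null(spectra)) spectra <- kcr_species_spectra(wavelengths_nm)
  pops <- propagate_scheme(scheme, times_s)
  cube <- synthesize_cube(pops, spectra, wavelengths_nm, times_s)
  noise_sd <- 0
  if (is.finite(snr)) {
    noise_sd <- max(abs(cube$delta_a)) / snr
    cube$delta_a <- .with_seed(seed, cube$delta_a +
      matrix(stats::rnorm(length(cube$delta_a), 0, noise_sd),
             nrow(cube$delta_a)))
  }
  list(cube = cube, populations = pops,
       truth = .truth("gen_transient_absorption",
                      list(rates = scheme$rates[scheme$rates > 0],
                           snr = snr, noise_sd = noise_sd), seed))
}

#' Generate a gated multi-exponential photocurrent trace
#'
#' During the light window the current activates as
#' sum_i a_i (1 - exp(-(t - t_on)/tau_on_i)); after light-off it decays
#' as the sum of the off components.  Additive Gaussian noise.
#'
#' @param on_components,off_components data.frame-like lists with
#'   `amplitude_pa` and `tau_s` vectors for the on and off phases.
#' @param duration_s,light_on_s,light_off_s,sampling_hz Protocol timing.
#' @param noise_sd_pa Additive noise SD (pA).
#' @param seed RNG seed.
#' @return List: `time_s`, `current_pa`, `light_on_s`, `light_off_s`,
#'   `truth`.
#' @export
gen_photocurrent <- function(on_components = list(amplitude_pa = -200,
                                                  tau_s = 0.005),
                             off_components = list(amplitude_pa = -200,
                                                   tau_s = 0.01),
                             duration_s = 1, light_on_s = 0.2,
                             light_off_s = 0.6, sampling_hz = 10000,
                             noise_sd_pa = 0, seed = DEFAULT_SEED) {
  if (any(c(on_components$tau_s, off_components$tau_s) <= 0))
    stop("tau values must be > 0", call. = FALSE)
  tgrid <- seq(0, duration_s, by = 1 / sampling_hz)
  y <- numeric(length(tgrid))
  lit <- tgrid >= light_on_s & tgrid <= light_off_s
  for (i in seq_along(on_components$tau_s))
    y[lit] <- y[lit] + on_components$amplitude_pa[i] *
      (1 - exp(-(tgrid[lit] - light_on_s) / on_components$tau_s[i]))
  post <- tgrid > light_off_s
  for (i in seq_along(off_components$tau_s))
    y[post] <- y[post] + off_components$amplitude_pa[i] *
      exp(-(tgrid[post] - light_off_s) / off_components$tau_s[i])
  y <- .with_seed(seed, if (noise_sd_pa > 0)
    y + stats::rnorm(length(y), 0, noise_sd_pa) else y)
  list(time_s = tgrid, current_pa = y, light_on_s = light_on_s,
       light_off_s = light_off_s,
       truth = .truth("gen_photocurrent",
                      list(on = on_components, off = off_components,
                           noise_sd_pa = noise_sd_pa), seed))
}

# packaged dark-state pigment presets: printed lambda-max values, single
# Gaussian bands of 100 nm FWHM (shape chosen for testability)
.SPECTRUM_PRESETS <- list(
  hckcr1_wt_dark = 521,
  hckcr2_wt_dark = 486,
  hckcr1_d105n   = 508,
  hckcr1_d229n   = 386
)

#' Generate a synthetic absorption spectrum
#'
#' A single Gaussian band (100 nm FWHM, unit peak) on a 250-750 nm, 1 nm
#' grid, plus optional Gaussian noise.  Named presets carry the
#' dark-state absorption maxima of the packaged pigment fixtures:
#' `hckcr1_wt_dark` (521 nm), `hckcr2_wt_dark` (486 nm),
#' `hckcr1_d105n` (508 nm), `hckcr1_d229n` (386 nm).
#'
#' @param preset Preset name, or `NULL` to use `lambda_max_nm`.
#' @param lambda_max_nm Band centre (nm) when no preset is given.
#' @param fwhm_nm Band FWHM (nm, default 100).
#' @param wavelengths_nm Wavelength grid.
#' @param noise_sd Additive noise SD (AU).
#' @param seed RNG seed.
#' @return List: `spectrum` ([spectrum()]), `truth`.
#' @export
gen_spectrum <- function(preset = NULL, lambda_max_nm = NULL, fwhm_nm = 100,
                         wavelengths_nm = seq(250, 750, by = 1),
                         noise_sd = 0, seed = DEFAULT_SEED) {
  if (!is.null(preset)) {
    if (!preset %in% names(.SPECTRUM_PRESETS))
      stop("unknown preset '", preset, "'; available: ",
           paste(names(.SPECTRUM_PRESETS), collapse = ", "), call. = FALSE)
    lambda_max_nm <- .SPECTRUM_PRESETS[[preset]]
  }
  if (is.null(lambda_max_nm))
    stop("supply a preset or lambda_max_nm", call. = FALSE)
  a <- .gauss_band(wavelengths_nm, lambda_max_nm, fwhm_nm)
  a <- .with_seed(seed, if (noise_sd > 0)
    a + stats::rnorm(length(a), 0, noise_sd) else a)
  list(spectrum = spectrum(wavelengths_nm, a,
                           label = preset %||% paste0(lambda_max_nm, "nm")),
       truth = .truth("gen_spectrum",
                      list(preset = preset, lambda_max_nm = lambda_max_nm,
                           fwhm_nm = fwhm_nm, noise_sd = noise_sd), seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic pH titration series
#'
#' Readout absorbance following A(pH) = A_low + (A_high - A_low) /
#' (1 + 10^(n (pKa - pH))) plus Gaussian noise.
#'
#' @param pka,hill_n,a_low,a_high Ground-truth sigmoid parameters.
#' @param ph Vector of pH values (default 2..11 integers).
#' @param noise_sd Additive noise SD.
#' @param seed RNG seed.
#' @return List: `ph`, `absorbance`, `truth`.
#' @export
gen_titration_series <- function(pka = 4.0, hill_n = 1, a_low = 0,
                                 a_high = 1, ph = 2:11, noise_sd = 0,
                                 seed = DEFAULT_SEED) {
  a <- a_low + (a_high - a_low) / (1 + 10^(hill_n * (pka - ph)))
  a <- .with_seed(seed, if (noise_sd > 0)
    a + stats::rnorm(length(a), 0, noise_sd) else a)
  list(ph = ph, absorbance = a,
       truth = .truth("gen_titration_series",
                      list(pka = pka, hill_n = hill_n, a_low = a_low,
                           a_high = a_high, noise_sd = noise_sd), seed))
}

#' Generate a synthetic HPLC chromatogram of retinal oximes
#'
#' Gaussian elution peaks whose areas are composition_i * epsilon_i *
#' scale, so the reciprocal-epsilon unmixing inverts the composition
#' exactly in the noiseless limit.  Returns the retention windows
#' (centre +/- 4 sigma) needed by [integrate_peaks()].
#'
#' @param composition Named mole fractions (must sum to 1).
#' @param epsilon Extinction table (default [retinal_epsilon360()]).
#' @param retention_min Named peak centres (min); defaults spread the
#'   eight canonical isomers 2 min apart.
#' @param width_min Gaussian sigma of each peak (min).
#' @param scale Area scale factor.
#' @param time_min Time axis (min).
#' @param noise_sd Additive noise SD (AU).
#' @param seed RNG seed.
#' @return List: `time_min`, `absorbance`, `windows`, `truth`.
#' @export
gen_chromatogram <- function(composition,
                             epsilon = retinal_epsilon360(),
                             retention_min = NULL, width_min = 0.15,
                             scale = 1e-4, time_min = seq(0, 20, by = 0.01),
                             noise_sd = 0, seed = DEFAULT_SEED) {
  if (abs(sum(composition) - 1) > 1e-9)
    stop("composition must sum to 1", call. = FALSE)
  iso <- names(composition)
  if (is.null(retention_min))
    retention_min <- stats::setNames(2 + 2 * (seq_along(iso) - 1), iso)
  y <- numeric(length(time_min))
  for (s in iso) {
    area <- composition[[s]] * epsilon[[s]] * scale
    amp <- area / (width_min * sqrt(2 * pi))
    y <- y + amp * exp(-0.5 * ((time_min - retention_min[[s]]) /
                               width_min)^2)
  }
  y <- .with_seed(seed, if (noise_sd > 0)
    y + stats::rnorm(length(y), 0, noise_sd) else y)
  windows <- lapply(stats::setNames(iso, iso), function(s)
    c(retention_min[[s]] - 4 * width_min, retention_min[[s]] + 4 * width_min))
  list(time_min = time_min, absorbance = y, windows = windows,
       truth = .truth("gen_chromatogram",
                      list(composition = as.list(composition),
                           scale = scale, width_min = width_min,
                           noise_sd = noise_sd), seed))
}

#' Generate a synthetic two-state trajectory with hydration and binding
#'
#' Builds a minimal topology -- a probe side-chain atom (resi 222 OH)
#' whose distance to an anchor atom (resi 102 CZ2) follows a two-state
#' (tight/loose) Markov chain with Gaussian jitter; a K+ ion whose
#' hydration shell holds a configurable number of water oxygens per
#' binding state; site atoms (resi 116 OD1, resi 120 OG1) that the ion
#' approaches during scheduled binding episodes; and bulk waters.
#' Frames are written deterministically from the seed.
#'
#' @param n_frames Number of frames.
#' @param d_tight_a,d_loose_a State mean probe-anchor distances
#'   (Angstrom), `d_tight_a < d_loose_a`.
#' @param k_tight_to_loose,k_loose_to_tight Per-frame switching rates;
#'   the stationary tight fraction is k_lt / (k_tl + k_lt).
#' @param jitter_sd_a Gaussian distance jitter (Angstrom, default 0.2).
#' @param n_shell_bound,n_shell_unbound Water oxygens inside the 3.5 A
#'   shell while the ion is bound / unbound.
#' @param n_waters Total water count.
#' @param binding_schedule data.frame with `start_frame`, `end_frame`
#'   rows during which the ion sits at the site; `NULL` for never bound.
#' @param dt_ps Frame interval (ps, default 200).
#' @param start_state `"tight"` or `"loose"`.
#' @param seed RNG seed.
#' @return List: `traj` ([trajectory_bundle()]), `truth` (includes the
#'   per-frame state path and bound flags).
#' @export
gen_trajectory <- function(n_frames = 1000, d_tight_a = 4, d_loose_a = 7,
                           k_tight_to_loose = 0.3, k_loose_to_tight = 0.7,
                           jitter_sd_a = 0.2, n_shell_bound = 2,
                           n_shell_unbound = 6, n_waters = 8,
                           binding_schedule = NULL, dt_ps = 200,
                           start_state = "tight", seed = DEFAULT_SEED) {
  if (d_tight_a >= d_loose_a)
    stop("d_tight_a must be below d_loose_a", call. = FALSE)
  if (max(n_shell_bound, n_shell_unbound) > n_waters)
    stop("n_waters must cover the largest hydration shell", call. = FALSE)
  atoms <- data.frame(
    index = seq_len(5 + n_waters),
    name = c("CZ2", "OH", "K", "OD1", "OG1", rep("O", n_waters)),
    resname = c("TRP", "TYR", "K", "ASP", "THR", rep("HOH", n_waters)),
    resno = c(102L, 222L, 500L, 116L, 120L, 600L + seq_len(n_waters)),
    chain = "A",
    element = c("C", "O", "K", "O", "O", rep("O", n_waters)),
    stringsAsFactors = FALSE)
  site <- c(20, 0, 0)
  bound <- rep(FALSE, n_frames)
  if (!is.null(binding_schedule))
    for (i in seq_len(nrow(binding_schedule)))
      bound[binding_schedule$start_frame[i]:binding_schedule$end_frame[i]] <-
        TRUE
  out <- .with_seed(seed, {
    states <- character(n_frames)
    cur <- start_state
    # exact one-frame discretization of the two-state CTMC: stationary
    # tight fraction is k_loose_to_tight / (k_tight_to_loose + k_loose_to_tight)
    S <- k_tight_to_loose + k_loose_to_tight
    decay <- if (S > 0) (1 - exp(-S)) / S else 1
    p_tl <- k_tight_to_loose * decay
    p_lt <- k_loose_to_tight * decay
    for (f in seq_len(n_frames)) {
      states[f] <- cur
      u <- stats::runif(1)
      cur <- if (cur == "tight") {
        if (u < p_tl) "loose" else "tight"
      } else {
        if (u < p_lt) "tight" else "loose"
      }
    }
    d <- ifelse(states == "tight", d_tight_a, d_loose_a) +
      stats::rnorm(n_frames, 0, jitter_sd_a)
    coords <- array(0, c(nrow(atoms), 3, n_frames))
    shell_dirs <- matrix(stats::rnorm(3 * n_waters), n_waters, 3)
    shell_dirs <- shell_dirs / sqrt(rowSums(shell_dirs^2))
    for (f in seq_len(n_frames)) {
      coords[1, , f] <- c(0, 0, 0)                 # anchor
      coords[2, , f] <- c(d[f], 0, 0)              # probe
      ion <- if (bound[f]) site + c(2.8, 0, 0) else site + c(10, 0, 0)
      coords[3, , f] <- ion
      coords[4, , f] <- site                        # OD1
      coords[5, , f] <- site + c(0, 3, 0)           # OG1
      n_shell <- if (bound[f]) n_shell_bound else n_shell_unbound
      for (w in seq_len(n_waters)) {
        r <- if (w <= n_shell) 2.8 else 8 + w
        coords[5 + w, , f] <- ion + r * shell_dirs[w, ]
      }
    }
    list(coords = coords, states = states, distances = d)
  })
  list(traj = trajectory_bundle(atoms, out$coords, dt_ps = dt_ps),
       truth = .truth("gen_trajectory",
                      list(d_tight_a = d_tight_a, d_loose_a = d_loose_a,
                           k_tight_to_loose = k_tight_to_loose,
                           k_loose_to_tight = k_loose_to_tight,
                           stationary_tight = k_loose_to_tight /
                             (k_tight_to_loose + k_loose_to_tight),
                           n_shell_bound = n_shell_bound,
                           n_shell_unbound = n_shell_unbound,
                           states = out$states, bound = bound), seed))
}

#' Generate a synthetic FSEC-TS melting curve
#'
#' 4-parameter logistic response over a temperature grid (default 20-95
#' degrees C plus the 4 degree reference), plus Gaussian noise.
#'
#' @param tm_c Melting midpoint (degrees C).
#' @param scale_c Logistic scale (degrees C; negative slope built in).
#' @param lower,upper Asymptotes (folded fraction at high / low T).
#' @param temperature_c Temperature grid.
#' @param noise_sd Additive noise SD.
#' @param seed RNG seed.
#' @return List: `temperature_c`, `response`, `truth`.
#' @export
gen_melting_curve <- function(tm_c = 60, scale_c = 3, lower = 0, upper = 1,
                              temperature_c = c(4, seq(20, 95, by = 5)),
                              noise_sd = 0, seed = DEFAULT_SEED) {
  y <- lower + (upper - lower) / (1 + exp((temperature_c - tm_c) / scale_c))
  y <- .with_seed(seed, if (noise_sd > 0)
    y + stats::rnorm(length(y), 0, noise_sd) else y)
  list(temperature_c = temperature_c, response = y,
       truth = .truth("gen_melting_curve",
                      list(tm_c = tm_c, scale_c = scale_c, lower = lower,
                           upper = upper, noise_sd = noise_sd), seed))
}

#' Generate a synthetic fiber-photometry fluorescence trace
#'
#' Double-exponential photobleaching multiplied into a constant
#' fluorescence level, an optional fractional dip during the stimulation
#' window with mono-exponential on/off transitions, and Gaussian noise.
#'
#' @param duration_s,sampling_hz Trace length and frame rate.
#' @param f0 Baseline fluorescence (AU).
#' @param bleach_amplitudes,bleach_taus_s Double-exponential bleach
#'   components (fractions of f0 and their time constants).
#' @param stim_on_s,stim_off_s Stimulation window; `NULL` for none.
#' @param dip_fraction Fractional fluorescence decrease during
#'   stimulation (e.g. 0.2 for a 20 percent dip).
#' @param dip_tau_s Transition time constant (s).
#' @param noise_sd Additive noise SD (AU).
#' @param seed RNG seed.
#' @return List: `time_s`, `fluor`, `truth`.
#' @export
gen_fip_trace <- function(duration_s = 60, sampling_hz = 20, f0 = 100,
                          bleach_amplitudes = c(0.15, 0.1),
                          bleach_taus_s = c(8, 60),
                          stim_on_s = NULL, stim_off_s = NULL,
                          dip_fraction = 0, dip_tau_s = 0.5,
                          noise_sd = 0, seed = DEFAULT_SEED) {
  tgrid <- seq(0, duration_s, by = 1 / sampling_hz)
  bleach <- 1 - sum(bleach_amplitudes) +
    colSums(bleach_amplitudes * t(exp(-outer(tgrid, bleach_taus_s, "/"))))
  dip <- numeric(length(tgrid))
  if (!is.null(stim_on_s)) {
    inwin <- tgrid >= stim_on_s & tgrid <= stim_off_s
    dip[inwin] <- dip_fraction *
      (1 - exp(-(tgrid[inwin] - stim_on_s) / dip_tau_s))
    post <- tgrid > stim_off_s
    dip_end <- dip_fraction * (1 - exp(-(stim_off_s - stim_on_s) / dip_tau_s))
    dip[post] <- dip_end * exp(-(tgrid[post] - stim_off_s) / dip_tau_s)
  }
  f <- f0 * bleach * (1 - dip)
  f <- .with_seed(seed, if (noise_sd > 0)
    f + stats::rnorm(length(f), 0, noise_sd) else f)
  list(time_s = tgrid, fluor = f,
       truth = .truth("gen_fip_trace",
                      list(f0 = f0, bleach_amplitudes = bleach_amplitudes,
                           bleach_taus_s = bleach_taus_s,
                           dip_fraction = dip_fraction,
                           noise_sd = noise_sd), seed))
}
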