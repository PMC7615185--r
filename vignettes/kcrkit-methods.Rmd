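---
title: "Models and methods behind kcrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kcrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kcrkit)
```

`kcrkit` analyzes potassium-selective channelrhodopsin (KCR)
experiments across five surfaces: voltage-clamp electrophysiology,
flash-photolysis photocycle kinetics, absorption spectroscopy,
HPLC-based retinal isomer quantification, and molecular-trajectory
selectivity metrics.  This vignette records the models, their
assumptions, the tunable parameters, and the numerical decisions — the
things a reviewer or maintainer would otherwise have to reverse-engineer
from the code.

## Ion selectivity from reversal potentials

A channel permeant to K⁺ and Na⁺ reverses at the
Goldman–Hodgkin–Katz (GHK) voltage

$$E_{rev} = \frac{RT}{F}\,\ln\frac{P_K [K]_o + P_{Na}[Na]_o + P_{Cl}[Cl]_i}
                               {P_K [K]_i + P_{Na}[Na]_i + P_{Cl}[Cl]_o},$$

with $T = 298\,$K, $F = 96485\,$C/mol, $R = 8.314\,$J/(K·mol) by
default (overridable per `solution_pair`).  Assumptions we adopt and
their justification:

* **Activities equal concentrations.**  Whole-cell selectivity work in
  this field uses nominal solution concentrations directly; no
  activity-coefficient correction is applied.
* **Anion convention.**  Chloride enters with inner/outer
  concentrations swapped, the standard constant-field convention.  All
  selectivity fits here use $P_{Cl}=0$, so this choice does not affect
  any reported ratio.
* **Divalents excluded.**  Ca²⁺/Mg²⁺ are carried in `solution_pair`
  for bookkeeping only; a constant-field treatment of divalents is a
  different equation and out of scope.
* **Junction potentials.**  Voltages carry a `junction_corrected`
  flag; the correction itself is an additive offset supplied by the
  user (computed externally, e.g. by an acquisition-software
  calculator).  Henderson-equation computation is deliberately not
  implemented.

With $P_{Cl}=0$ the inversion for $x = P_K/P_{Na}$ at a measured
$E_{rev}$ is closed-form: writing $r = e^{E F/RT}$,
$x = ([Na]_o - r[Na]_i)/(r[K]_i - [K]_o)$.  A negative or infinite
root means the measured reversal is inconsistent with the imposed
gradients and raises a diagnostic error rather than returning a clamped
value.  In the fully gradient-free case (symmetric solutions, 0 mV)
every ratio satisfies the equation and the conventional 1 is returned.
Per-cell series can be reduced either as the mean of per-cell ratios
(default) or as the ratio at the pooled mean reversal; the two differ
by ~1% at typical spreads because the inversion is convex in
$E_{rev}$.

**Reversal from I–V families.**  Per-step photocurrent amplitudes
(signed peak, or mean of the final 10% of the light window) form the
I–V table; the zero crossing is found by piecewise-linear
interpolation between the bracketing steps.  When the protocol does not
bracket zero, the two steps with smallest |I| define a line whose root
is reported with `method = "extrapolated"`.  Multiple sign changes are
an error listing every crossing — a non-monotone I–V is a data-quality
problem the analyst must see, not something to resolve silently.

**Gaussian low-pass.**  The −3 dB definition fixes the kernel width:
a Gaussian kernel with $\sigma_t$ has response
$H(f) = e^{-2\pi^2\sigma_t^2 f^2}$, so requiring $|H(f_c)| = 2^{-1/2}$
gives $\sigma_t = \sqrt{\ln 2}/(2\pi f_c)$.  The kernel is truncated at
$6\sigma$, renormalized (exact DC gain 1), and edges are handled by
reflection.  The FFT check in the test suite confirms 0.7071 ± 1% at
the cutoff for sampling rates ≥ 20× the cutoff.

**Exponential kinetics.**  `fit_exponential_kinetics()` fits
$c + \sum_i a_i e^{-t/\tau_i}$ (1–3 components) by Nelder–Mead simplex
over $\log\tau$ with 8 log-spaced multi-starts spanning the segment
duration; amplitudes and offset are profiled out by linear least
squares at every step (variable projection), which removes the
amplitude directions from the nonlinear search entirely.  Time
constants return sorted ascending.  Convergence tolerance is 1e−10 on
relative SSE change; a single component uses bounded Brent search.

**Fiber-photometry ΔF/F.**  Bleaching is corrected by *dividing* by a
double-exponential trend fitted with the stimulation window and the
10 s rebound period excluded.  Division rather than subtraction is a
deliberate choice: bleaching scales the signal multiplicatively, and a
subtractive correction re-anchored to the start of the recording
mis-scales response amplitudes once an appreciable fraction of the
fluorophore has bleached (in testing, a 10% dip read as 8.2%).  The
baseline (mean of the 5 s before stimulation) is computed before the
0.5 Hz display filter is applied, so filter bleed from the stimulus
edge cannot tilt it.  Preconditions: at least 5 s of pre-stimulus data.

## Photocycle kinetics

**Scheme propagation.**  A photocycle is a set of spectrally distinct
intermediates connected by first-order rates, draining into an
absorbing ground state.  `propagate_scheme()` solves
$\dot c = A c$ ($A$ the generator) exactly by eigendecomposition —
the Bateman solution for chains.  If the eigenvector basis is
ill-conditioned (condition number > 1e8, e.g. a chain with equal
rates), propagation falls back to a stiff `lsoda` integration at
rtol 1e−10 and flags the output.  Total population including the
ground state is conserved to 1e−9 (tested against a brute-force stiff
integration on random schemes).

**Default topology.**  The default KCR-like scheme is two parallel
four-intermediate chains, K₁→L₁→M₁→N₁→ground and
K₂→L₂→M₂→N₂→ground, with the photoactivated population (default 40%
of the protein, split evenly) starting in the K states.  The paired
naming of intermediates motivates the parallel layout, but the true
connectivity of any given channel is an experimental question — the
topology is therefore fully user-configurable (JSON-serializable via
`write_scheme_json()`) and never hard-coded into the fitters.  Default
chain rates (3.3e5, 2.1e4, 1.3e3, 81 s⁻¹ and 8.3e4, 5.2e3, 325,
20 s⁻¹) were chosen once as a realistically powered experiment: every
relaxation time sits well inside the 1 µs–10 s observation window
(K decays in microseconds, N in tens of milliseconds), and adjacent
relaxation eigenvalues are separated by ≈4×, comfortably above the 3×
separation below which exponentials become practically inseparable.

**Spectral model.**  Species difference spectra are Gaussian bands
(30 nm FWHM) at the intermediates' probe wavelengths — 617 nm for the
K pair, 480 nm for the spectrally indistinguishable L/N set, 384 and
404 nm for the two M states — minus the 521 nm dark-state band, so
the ground state contributes zero difference absorbance.  Two
consequences matter:

* The default cube has **spectral rank 4** (four distinct bands among
  eight intermediates) while its kinetics carry all eight rates;
  `svd_rank()` on the noiseless default cube reports 4.
* Spectral sharing is what makes target fitting informative.  With one
  free spectrum per species, *any* unidirectional scheme spans exactly
  the free-multi-exponential model — the fit can do no better than
  decay-associated spectra, and at realistic noise eight free
  eigenvalues are not individually recoverable.  Passing
  `spectral_groups` (the default grouping is `kcr_spectral_groups()`)
  constrains paired species to one shared spectrum and restores
  identifiability.  This mirrors experimental practice, where paired
  intermediates are monitored at a single probe wavelength.

**Rank estimation.**  `svd_rank()` keeps leading components while the
singular-value ratio $s_i/s_1$ stays ≥ 0.01 *and* both singular
vectors keep lag-1 autocorrelation ≥ 0.8 (noise components are
spectrally and temporally unstructured).  Both thresholds are standard
flash-photolysis practice and configurable.

**Global and target fitting.**  `global_exponential_fit()` fits shared
time constants with decay-associated spectra profiled linearly
(variable projection), Nelder–Mead multi-start plus a
Levenberg–Marquardt polish on the projected residuals.
`fit_target_scheme()` does the same over the log-rates of a fixed
topology with (possibly group-shared) species spectra profiled out.
Rate seeding follows the standard eigenvalue-matching recipe: a global
fit with as many components as free rates supplies the relaxation
eigenvalues, which are assigned to edges by the magnitude ranking of
the topology's placeholder rates (declare edges fastest-first, as the
default scheme does).  Structural over-parameterization (more free
rates than intermediates) is rejected up front; fitted relaxation
eigenvalues that collapse within 5% of each other raise an
identifiability warning.  Under the default study conditions (1 nm
wavelength grid, 250 log-spaced time points, SNR 30 defined as peak
|ΔA| / noise SD) all eight rates are recovered within 10% — typically
2–7% — as the test suite verifies on a seeded cube.

**Pyranine differencing.**  The proton-release trace is the pointwise
difference of transient-absorption traces recorded with and without the
pH dye (linear resampling to a common grid if needed); the release lag
is the signed difference between the half-rise times (first crossing of
the min-max midpoint, linearly interpolated) of the difference trace
and a supplied reference intermediate trace.

## Spectra, titrations and sigmoids

λmax is the grid argmax, with optional 3-point parabolic refinement
(ties break toward shorter wavelength and are flagged; an argmax on the
window edge is an error).  Shifts use unrefined grid peaks by default,
so shifts between like-gridded fixtures are exact integers.  The
packaged pigment presets — `hckcr1_wt_dark` (521 nm), `hckcr2_wt_dark`
(486 nm), `hckcr1_d105n` (508 nm), `hckcr1_d229n` (386 nm) — are
single Gaussian bands of 100 nm FWHM and unit peak on a 250–750 nm,
1 nm grid: the band centers carry the real dark-state maxima, while
the band *shape* is a synthetic construction chosen for testability,
not a measured spectrum.

pH titrations fit
$A(\mathrm{pH}) = A_{low} + (A_{high}-A_{low})/(1+10^{\,n(pK_a-\mathrm{pH})})$;
melting/binding series fit a 4-parameter logistic with the midpoint
reported in original units (Tm for temperature series; a dissociation-
constant-like midpoint on a log10 axis for concentration series).  Both
use Levenberg–Marquardt (`minpack.lm::nlsLM`) because Gauss–Newton
`nls` fails with a "singular gradient" on exact-fit synthetic data.
A midpoint outside the data range is flagged `extrapolated`; a flat
response is an error.  Confidence intervals come from the Jacobian at
the optimum.

## Retinal isomer unmixing

Mole fractions from 360 nm HPLC peak areas are
$f_i = (A_i/\varepsilon_i)/\sum_j (A_j/\varepsilon_j)$ using the eight
canonical oxime extinction coefficients (54,900 / 51,600 / 49,000 /
52,100 / 35,000 / 29,600 / 39,300 / 30,600 M⁻¹cm⁻¹ for
all-trans/13-cis/11-cis/9-cis × 15-syn/15-anti).  The 15-syn/anti
split is kept internally; `reduce_to_c_isomers()` sums the pairs, the
level at which photoproduct changes are usually discussed.  Peak
integration is trapezoidal above a straight-line baseline between the
window endpoints (the integration method is a package choice; nothing
in the workflow depends on it beyond linearity), with negative areas
clipped to zero under a warning and overlapping windows rejected.

## Trajectory metrics

Selections are conjunctions over atom-table columns
(`"resi 222 and name OH"`); centroids are unweighted, distances are
plain Euclidean on raw coordinates.  **Periodic imaging is
unsupported**: the synthetic generator never wraps coordinates, and a
coordinate span > 500 Å triggers a warning.  Default cutoffs follow
MD-analysis convention — 3.5 Å ion–water-oxygen first shell
(inclusive boundary), 4.0 Å side-chain N/O salt bridge, 5.0 Å site
binding — all configurable, none claimed to reproduce any particular
published fraction.

The two-state classifier uses hysteresis: enter *tight* below the low
threshold, *loose* above the high threshold, keep the previous label
inside the band (frames before the first crossing are `undefined` and
excluded from occupancies).  This makes chatter inside the band produce
zero spurious transitions, which naive single-threshold labeling cannot
guarantee.  Binding events are maximal runs of frames within cutoff,
filtered by a minimum dwell; with dwell 1 the bound fraction equals the
contact occupancy by construction.

## Synthetic-data generators

Every generator is a pure function of (parameters, seed): regeneration
is bit-identical, the caller's RNG stream is left untouched, and the
ground truth (including, for trajectories, the per-frame state path)
is returned alongside the data.  Design points worth recording:

* **I–V synthesis** uses the GHK constant-field *flux* equation per
  ion, scaled by a conductance factor and gated with mono-exponential
  activation/deactivation.  The analysis side never depends on this
  choice; its only load-bearing property is that the noiseless
  zero-current voltage equals the GHK voltage-equation reversal.
* **Two-state trajectories** use the exact one-frame discretization of
  the continuous-time Markov chain
  ($p_{switch} = k/S\,(1-e^{-S})$, $S$ the rate sum), so the
  frame-sampled stationary tight fraction is exactly
  $k_{l\to t}/S$ — a naive per-frame Bernoulli would bias it.
  Distances jitter with SD 0.2 Å around the state means; hydration
  shells place the configured number of water oxygens at 2.8 Å.
* **Noise** is additive Gaussian throughout, with SNR defined as peak
  signal over noise SD and written into the truth record.
* The default seed everywhere is 20230830.

What the generators emulate — and what they do not: GHK-shaped I–V
families with gating noise, but no series-resistance or capacitance
artifacts; Gaussian-band difference spectra, but no baseline drift or
chirp; telegraph-plus-jitter side-chain dynamics, but no force-field
physics, no periodic box, no correlated water motion.  Green tests
therefore demonstrate that the estimators are correct on data matching
their model assumptions at realistic noise; they do not certify
robustness to every instrumental artifact of real recordings.

## Problem sizes and reproducibility

The test suite and acceptance analyses run at the sizes a desk
reanalysis would use: 501-point spectra, 11-step I–V families at
1–5 kHz, one 371 × 250 transient-absorption cube for the
eight-rate recovery, 10⁴ trajectory frames for occupancy convergence.
All stochastic tests fix their seeds.  `scripts/acceptance.R --seed N
--out f.json` recomputes the headline quantities (GHK ratios at the
wild-type and mutant reversal potentials; fixture λmax values and
shifts) from the installed package alone.

## Known limitations

* The GHK layer handles monovalent K⁺/Na⁺/Cl⁻ only; divalent
  permeation and surface-charge effects are out of scope.
* Target fitting assumes unidirectional first-order schemes; reversible
  steps are expressible in the rate matrix but identifiability with
  free spectra degrades quickly, and no branching-ratio priors are
  offered.
* Excitation-pulse deconvolution, spectral chirp correction and
  anisotropy are not implemented; time zero is taken as the flash.
* The trajectory layer is an analysis layer: it does not run dynamics,
  compute free energies, or image periodic boundaries.
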