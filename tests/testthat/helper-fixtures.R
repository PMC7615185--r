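# Shared fixtures built in code.

hek_solutions <- function() {
  solution_pair(outer = c(K = 4, Na = 150, Cl = 158),
                inner = c(K = 140, Na = 0, Cl = 4))
}

# K/Na-only solutions for the closed-form inversion checks
kna_solutions <- function() {
  solution_pair(outer = c(K = 4, Na = 150), inner = c(K = 140, Na = 0))
}

# tiny two-step chain scheme A -> B -> ground
chain2_scheme <- function(k1 = 2, k2 = 1) {
  photocycle_scheme(c("A", "B", "ground"),
                    rbind(c(0, k1, 0), c(0, 0, k2), c(0, 0, 0)),
                    c(A = 1))
}

# linear chain of n intermediates with given decay rates
chain_scheme <- function(rates) {
  n <- length(rates)
  sp <- c(paste0("S", seq_len(n)), "ground")
  K <- matrix(0, n + 1, n + 1, dimnames = list(sp, sp))
  for (i in seq_len(n)) K[i, i + 1] <- rates[i]
  photocycle_scheme(sp, K, stats::setNames(1, sp[1]))
}

# distinct Gaussian difference spectra for a set of species
band_spectra <- function(species, wavelengths, centres, fwhm = 40) {
  stats::setNames(lapply(centres, function(cc) {
    s <- fwhm / (2 * sqrt(2 * log(2)))
    exp(-0.5 * ((wavelengths - cc) / s)^2)
  }), species)
}
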