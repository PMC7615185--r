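# Goldman-Hodgkin-Katz voltage equation and its inversion for the
# two-cation (K+/Na+) permeability ratio.

.FARADAY <- 96485    # C/mol
.GAS_R   <- 8.314    # J/(K mol)
.KNOWN_IONS <- c("K", "Na", "Cl", "Cs", "Li", "Gu", "Ca", "Mg")

#' Ionic solutions on both membrane faces
#'
#' Bundles the extracellular ("outer") and intracellular ("inner") ion
#' concentrations together with the recording temperature.  These are the
#' inputs of the GHK voltage equation.  Divalents (Ca, Mg) may be carried
#' for bookkeeping but never enter the GHK quotient, which uses K, Na and
#' Cl only.
#'
#' @param outer Named numeric vector of extracellular concentrations (mM).
#'   Names must be drawn from K, Na, Cl, Cs, Li, Gu, Ca, Mg.
#' @param inner Named numeric vector of intracellular concentrations (mM).
#' @param temperature Absolute temperature in K (default 298).
#' @return An object of class `solution_pair`.
#' @examples
#' # Tyrode bath vs K-gluconate pipette
#' solution_pair(outer = c(K = 4, Na = 150), inner = c(K = 140, Na = 0))
#' @export
solution_pair <- function(outer, inner, temperature = 298) {
  check_side <- function(x, side) {
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop(side, " concentrations must be a named vector", call. = FALSE)
    bad <- setdiff(names(x), .KNOWN_IONS)
    if (length(bad))
      stop("unknown ion name(s) in ", side, ": ", paste(bad, collapse = ", "),
           " (known: ", paste(.KNOWN_IONS, collapse = ", "), ")", call. = FALSE)
    if (any(!is.finite(x)) || any(x < 0))
      stop(side, " concentrations must be finite and >= 0", call. = FALSE)
    x
  }
  outer <- check_side(outer, "outer")
  inner <- check_side(inner, "inner")
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0)
    stop("temperature must be a single positive value in K", call. = FALSE)
  structure(list(outer = outer, inner = inner, temperature = temperature),
            class = "solution_pair")
}

# concentration of one ion on one face, 0 if absent
.conc <- function(sol, side, ion) {
  x <- sol[[side]]
  if (ion %in% names(x)) unname(x[[ion]]) else 0
}

#' Relative ion permeabilities
#'
#' Dimensionless permeabilities relative to a reference ion whose entry is
#' fixed at 1 (K by convention).
#'
#' @param p_K,p_Na,p_Cl Relative permeabilities, all >= 0.
#' @param reference Which entry is the reference (must equal 1).
#' @return An object of class `permeability_set`.
#' @examples
#' permeability_set(p_K = 1, p_Na = 1 / 25.7, p_Cl = 0)
#' @export
permeability_set <- function(p_K = 1, p_Na = 0, p_Cl = 0, reference = "K") {
  p <- c(K = p_K, Na = p_Na, Cl = p_Cl)
  if (any(!is.finite(p)) || any(p < 0))
    stop("permeabilities must be finite and >= 0", call. = FALSE)
  if (!reference %in% names(p))
    stop("reference must be one of K, Na, Cl", call. = FALSE)
  if (abs(p[[reference]] - 1) > 1e-12)
    stop("reference permeability p_", reference, " must equal 1", call. = FALSE)
  structure(list(p_K = p_K, p_Na = p_Na, p_Cl = p_Cl, reference = reference),
            class = "permeability_set")
}

# RT/F in mV at the solution's temperature
.rt_over_f_mv <- function(sol) 1000 * .GAS_R * sol$temperature / .FARADAY

#' GHK reversal potential
#'
#' Evaluates the Goldman-Hodgkin-Katz voltage equation
#' \deqn{E = \frac{RT}{F}\,\ln
#'   \frac{p_K [K]_o + p_{Na} [Na]_o + p_{Cl} [Cl]_i}
#'        {p_K [K]_i + p_{Na} [Na]_i + p_{Cl} [Cl]_o}}
#' with F = 96485 C/mol and R = 8.314 J/(K mol).  Anions enter with inner
#' and outer concentrations swapped, following the standard convention.
#'
#' @param perms A [permeability_set()].
#' @param sol A [solution_pair()].
#' @return Reversal potential in mV.
#' @examples
#' sol <- solution_pair(c(K = 4, Na = 150), c(K = 140, Na = 0))
#' ghk_reversal_voltage(permeability_set(1, 1 / 25.7, 0), sol)  # ~ -68 mV
#' @export
ghk_reversal_voltage <- function(perms, sol) {
  stopifnot(inherits(perms, "permeability_set"), inherits(sol, "solution_pair"))
  if (perms$p_K <= 0 && perms$p_Na <= 0)
    stop("at least one cation permeability (p_K, p_Na) must be > 0",
         call. = FALSE)
  num <- perms$p_K * .conc(sol, "outer", "K") +
         perms$p_Na * .conc(sol, "outer", "Na") +
         perms$p_Cl * .conc(sol, "inner", "Cl")
  den <- perms$p_K * .conc(sol, "inner", "K") +
         perms$p_Na * .conc(sol, "inner", "Na") +
         perms$p_Cl * .conc(sol, "outer", "Cl")
  if (den <= 0)
    stop("GHK denominator p_K[K]i + p_Na[Na]i + p_Cl[Cl]o is not positive",
         call. = FALSE)
  if (num <= 0)
    stop("GHK numerator p_K[K]o + p_Na[Na]o + p_Cl[Cl]i is not positive",
         call. = FALSE)
  .rt_over_f_mv(sol) * log(num / den)
}

#' Invert the GHK equation for the K+/Na+ permeability ratio
#'
#' Solves the two-cation GHK voltage equation algebraically for
#' P_K/P_Na at a measured reversal potential, with P_Cl fixed at 0 (the
#' convention used for whole-cell KCR selectivity estimates).  With
#' r = exp(E F / RT) the unique root is
#' \deqn{P_K/P_{Na} = \frac{[Na]_o - r\,[Na]_i}{r\,[K]_i - [K]_o}.}
#'
#' @param erev_mv Measured reversal potential in mV (junction-corrected).
#' @param sol A [solution_pair()] with K and Na entries.
#' @param p_cl Chloride permeability; must be 0 (the closed-form
#'   two-cation inversion).
#' @return The permeability ratio P_K/P_Na (dimensionless).
#' @examples
#' sol <- solution_pair(c(K = 4, Na = 150), c(K = 140, Na = 0))
#' infer_permeability_ratio(-68.4, sol)  # ~ 25.9
#' @export
infer_permeability_ratio <- function(erev_mv, sol, p_cl = 0) {
  stopifnot(inherits(sol, "solution_pair"))
  if (!identical(p_cl, 0) && !(is.numeric(p_cl) && p_cl == 0))
    stop("closed-form inversion requires p_cl = 0", call. = FALSE)
  if (!is.finite(erev_mv))
    stop("erev_mv must be finite", call. = FALSE)
  ko <- .conc(sol, "outer", "K");  ki <- .conc(sol, "inner", "K")
  nao <- .conc(sol, "outer", "Na"); nai <- .conc(sol, "inner", "Na")
  if (ko + ki == 0 || nao + nai == 0)
    stop("solutions must contain K and Na entries on at least one face",
         call. = FALSE)
  r <- exp(erev_mv / .rt_over_f_mv(sol))
  den <- r * ki - ko
  num <- nao - r * nai
  # gradient-free case (e.g. symmetric solutions at 0 mV): every ratio
  # satisfies the equation; return the conventional 1
  scale <- max(ko, ki, nao, nai)
  if (abs(den) < 1e-12 * scale && abs(num) < 1e-12 * scale) return(1)
  if (den <= 0)
    stop("measured erev is not consistent with the K gradient: ",
         "r*[K]i - [K]o = ", signif(den, 4), " <= 0 gives no positive root",
         call. = FALSE)
  ratio <- num / den
  if (!is.finite(ratio) || ratio < 0)
    stop("inconsistent ion gradients: inferred P_K/P_Na = ",
         signif(ratio, 4), " is not a positive finite ratio", call. = FALSE)
  ratio
}

#' Reduce per-cell reversal potentials to a permeability ratio
#'
#' Whole-cell selectivity series yield one reversal potential per cell.
#' The headline ratio can be reduced either as the mean of per-cell
#' ratios (default) or as the ratio at the pooled mean reversal
#' potential; both are provided because the two reductions differ
#' slightly for curved inversions.
#'
#' @param erevs_mv Numeric vector of per-cell reversal potentials (mV).
#' @param sol A [solution_pair()].
#' @param method `"per_cell_mean"` or `"pooled_erev"`.
#' @return A list with `ratio`, `method`, per-cell `ratios`, and `n`.
#' @export
permeability_ratio_summary <- function(erevs_mv, sol,
                                       method = c("per_cell_mean",
                                                  "pooled_erev")) {
  method <- match.arg(method)
  ratios <- vapply(erevs_mv, infer_permeability_ratio, numeric(1), sol = sol)
  ratio <- switch(method,
    per_cell_mean = mean(ratios),
    pooled_erev   = infer_permeability_ratio(mean(erevs_mv), sol))
  list(ratio = ratio, method = method, ratios = ratios, n = length(erevs_mv))
}
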