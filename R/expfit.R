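# Multi-exponential least-squares fitting by Nelder-Mead simplex with
# multi-start, used for photocurrent on/off kinetics and bleach trends.

# Variable projection: given log-taus, solve amplitudes + offset linearly.
.expfit_sse <- function(log_tau, t, y, offset) {
  tau <- exp(log_tau)
  X <- vapply(tau, function(tt) exp(-t / tt), numeric(length(t)))
  X <- if (offset) cbind(1, X) else matrix(X, nrow = length(t))
  fit <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) return(list(sse = Inf))
  list(sse = sum(fit$residuals^2), coef = fit$coefficients,
       resid = fit$residuals)
}

#' Fit a sum of decaying exponentials
#'
#' Least-squares fit of `offset + sum_i a_i exp(-t / tau_i)` to a trace
#' segment.  The nonlinear time constants are optimized by Nelder-Mead
#' simplex in log-tau space with 8 log-spaced multi-starts spanning the
#' segment duration; amplitudes and offset are profiled out by linear
#' least squares at every step (variable projection).  Time constants are
#' returned sorted ascending with their amplitudes.
#'
#' @param t Time axis of the segment (s), relative or absolute.
#' @param y Trace values (e.g. pA).
#' @param n_components Number of exponential components, 1 to 3.
#' @param offset Fit an additive constant offset (default TRUE).
#' @param n_starts Number of multi-start initializations (default 8).
#' @param reltol Relative SSE convergence tolerance (default 1e-10).
#' @return A list of class `exp_fit`: `tau` (s, ascending), `amplitudes`
#'   (matching order), `offset`, `sse`, `residual_norm`, `converged`.
#' @examples
#' t <- seq(0, 0.1, by = 1e-4)
#' y <- 5 * exp(-t / 0.01)
#' fit_exponential_kinetics(t, y, n_components = 1)$tau  # 0.01
#' @export
fit_exponential_kinetics <- function(t, y, n_components = 1, offset = TRUE,
                                     n_starts = 8, reltol = 1e-10) {
  stopifnot(length(t) == length(y))
  if (!n_components %in% 1:3)
    stop("n_components must be 1, 2 or 3", call. = FALSE)
  if (length(t) < 5 * n_components)
    stop("segment too short: need >= ", 5 * n_components, " samples",
         call. = FALSE)
  t0 <- t - t[1]
  span <- max(t0)
  dt <- min(diff(t0))
  if (span <= 0 || dt <= 0) stop("time axis must be increasing", call. = FALSE)

  # multi-start grids: each start spreads n log-spaced taus over a window
  # of [dt, span] shifted between starts
  lo <- log(dt); hi <- log(2 * span)
  starts <- lapply(seq_len(n_starts), function(s) {
    frac <- (s - 1) / max(1, n_starts - 1)
    width <- (hi - lo) * (0.35 + 0.65 * frac)
    centre <- lo + frac * (hi - lo - width) + width / 2
    seq(centre - width / 2, centre + width / 2,
        length.out = max(2, n_components))[seq_len(n_components)]
  })

  best <- NULL
  for (st in starts) {
    obj <- function(p) .expfit_sse(p, t0, y, offset)$sse
    res <- if (n_components == 1) {
      stats::optim(st, obj, method = "Brent",
                   lower = lo - 5, upper = hi + 5)
    } else {
      stats::optim(st, obj, method = "Nelder-Mead",
                   control = list(reltol = reltol, maxit = 5000))
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (!is.finite(best$value)) {
    stop("exponential fit failed to converge from any start; best SSE = ",
         best$value, call. = FALSE)
  }
  sol <- .expfit_sse(best$par, t0, y, offset)
  tau <- exp(best$par)
  amp <- if (offset) sol$coef[-1] else sol$coef
  off <- if (offset) sol$coef[1] else 0
  ord <- order(tau)
  structure(list(tau = unname(tau[ord]), amplitudes = unname(amp[ord]),
                 offset = unname(off), sse = sol$sse,
                 residual_norm = sqrt(sol$sse),
                 converged = isTRUE(best$convergence == 0)),
            class = "exp_fit")
}
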