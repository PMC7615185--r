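# Absorption-spectrum analytics: lambda-max extraction, spectral shifts,
# pH-titration pKa fits and 4-parameter logistic midpoint fits.

#' Absorption spectrum
#'
#' @param wavelength_nm Strictly increasing wavelength grid (nm).
#' @param absorbance Absorbance (AU), same length, finite.
#' @param label Optional label.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelength_nm, absorbance, label = NULL) {
  if (is.unsorted(wavelength_nm, strictly = TRUE))
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  if (length(wavelength_nm) != length(absorbance))
    stop("axes must have equal length", call. = FALSE)
  if (any(!is.finite(absorbance)))
    stop("absorbance must be finite", call. = FALSE)
  structure(list(wavelength_nm = wavelength_nm, absorbance = absorbance,
                 label = label), class = "spectrum")
}

#' Wavelength of maximum absorbance
#'
#' Grid argmax within an optional window; with `refine = TRUE` a 3-point
#' parabolic interpolation around the argmax gives sub-grid precision.
#' Ties are broken toward the shortest wavelength (flagged), and an
#' argmax on the window edge or a flat spectrum is an error.
#'
#' @param spec A [spectrum()].
#' @param window Optional `c(min_nm, max_nm)` search window.
#' @param refine Parabolic sub-grid refinement (default FALSE, so values
#'   land exactly on the grid).
#' @return Peak wavelength (nm) with attributes `"tied"` and
#'   `"refined"`.
#' @export
find_lambda_max <- function(spec, window = NULL, refine = FALSE) {
  stopifnot(inherits(spec, "spectrum"))
  w <- spec$wavelength_nm
  a <- spec$absorbance
  if (!is.null(window)) {
    keep <- w >= window[1] & w <= window[2]
    if (sum(keep) < 3) stop("window contains fewer than 3 points",
                            call. = FALSE)
    w <- w[keep]; a <- a[keep]
  }
  if (diff(range(a)) == 0)
    stop("flat spectrum: no absorbance maximum", call. = FALSE)
  imax <- which(a == max(a))
  tied <- length(imax) > 1
  i <- imax[1]
  if (i == 1 || i == length(a))
    stop("absorbance maximum lies on the window edge at ", w[i],
         " nm; widen the window", call. = FALSE)
  out <- w[i]
  if (refine) {
    y1 <- a[i - 1]; y2 <- a[i]; y3 <- a[i + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom < 0) {
      delta <- 0.5 * (y1 - y3) / denom
      out <- w[i] + delta * (w[i + 1] - w[i])
    }
  }
  structure(out, tied = tied, refined = refine)
}

#' Signed spectral shift between two spectra
#'
#' lambda_max(a) - lambda_max(b), in nm.  Unrefined grid peaks by
#' default so shifts between like-gridded spectra are exact grid
#' differences; pass `refine = TRUE` for sub-grid peaks.
#'
#' @param a,b [spectrum()] objects.
#' @param refine Passed to [find_lambda_max()].
#' @return Shift in nm (positive when `a` peaks at longer wavelength).
#' @export
spectral_shift <- function(a, b, refine = FALSE) {
  as.numeric(find_lambda_max(a, refine = refine)) -
    as.numeric(find_lambda_max(b, refine = refine))
}

#' Fit a pH titration with a Henderson-Hasselbalch sigmoid
#'
#' Fits A(pH) = A_low + (A_high - A_low) / (1 + 10^(n (pKa - pH))) by
#' least squares, where A_low/A_high are the acid/alkaline asymptotes of
#' the absorbance at the readout wavelength and n the Hill coefficient.
#' Confidence intervals come from the Jacobian at the optimum.
#'
#' @param ph Numeric vector of pH values (>= 4 points).
#' @param absorbance Readout absorbance at each pH.
#' @return List of class `titration_fit`: `pka`, `hill_n`, `a_low`,
#'   `a_high`, `ci_pka` (95 percent), `residual_norm`, `extrapolated`
#'   (TRUE when the midpoint falls outside the pH range), `fitted`.
#' @export
fit_titration_pka <- function(ph, absorbance) {
  stopifnot(length(ph) == length(absorbance))
  if (length(ph) < 4) stop("need >= 4 pH points", call. = FALSE)
  df <- data.frame(x = ph, y = absorbance)
  dir_up <- stats::cor(ph, absorbance) >= 0
  a_lo0 <- if (dir_up) min(absorbance) else max(absorbance)
  a_hi0 <- if (dir_up) max(absorbance) else min(absorbance)
  mid0 <- stats::approx(absorbance, ph, xout = (a_lo0 + a_hi0) / 2,
                        ties = mean)$y
  if (is.na(mid0)) mid0 <- stats::median(ph)
  fit <- minpack.lm::nlsLM(y ~ a_lo + (a_hi - a_lo) /
                             (1 + 10^(n * (pka - x))),
                           data = df,
                           start = list(a_lo = a_lo0, a_hi = a_hi0,
                                        pka = mid0, n = 1),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    rep(NA_real_, 4))
  res <- stats::resid(fit)
  structure(list(pka = unname(cf["pka"]), hill_n = unname(cf["n"]),
                 a_low = unname(cf["a_lo"]), a_high = unname(cf["a_hi"]),
                 ci_pka = unname(cf["pka"] + c(-1.96, 1.96) * se["pka"]),
                 residual_norm = sqrt(sum(res^2)),
                 extrapolated = cf["pka"] < min(ph) || cf["pka"] > max(ph),
                 fitted = stats::fitted(fit)),
            class = "titration_fit")
}

#' 4-parameter logistic midpoint fit
#'
#' Fits y = lower + (upper - lower) / (1 + exp((midpoint - x) / scale))
#' for thermostability (melting temperature) or, with `log_x = TRUE`,
#' binding series (midpoint on a log10 concentration axis).  When
#' `normalize_to` is given, responses are first divided by the response
#' at that reference x (e.g. the 4 degree C sample of a thermal series),
#' so the reference maps to 1.
#'
#' @param x Dose/temperature axis (>= 5 points).
#' @param response Response values.
#' @param normalize_to Optional reference x whose response defines 1.0.
#' @param log_x Fit the midpoint on log10(x) (concentration series).
#' @return List of class `sigmoid_fit`: `midpoint` (original x units),
#'   `lower`, `upper`, `scale`, `residual_norm`, `extrapolated`,
#'   `fitted`.
#' @export
fit_sigmoid_midpoint <- function(x, response, normalize_to = NULL,
                                 log_x = FALSE) {
  stopifnot(length(x) == length(response))
  if (length(x) < 5) stop("need >= 5 points", call. = FALSE)
  if (!is.null(normalize_to)) {
    i <- which.min(abs(x - normalize_to))
    if (response[i] == 0)
      stop("reference response at x = ", x[i], " is zero", call. = FALSE)
    response <- response / response[i]
  }
  xf <- if (log_x) log10(x) else x
  if (diff(range(response)) == 0)
    stop("flat response: no sigmoidal transition to fit", call. = FALSE)
  lo0 <- min(response); hi0 <- max(response)
  mid0 <- stats::approx(response, xf, xout = (lo0 + hi0) / 2,
                        ties = mean)$y
  if (is.na(mid0)) mid0 <- stats::median(xf)
  sc0 <- diff(range(xf)) / 10
  if (stats::cor(xf, response) < 0) sc0 <- -sc0
  df <- data.frame(x = xf, y = response)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ lo + (hi - lo) / (1 + exp((mid - x) / sc)),
                      data = df,
                      start = list(lo = lo0, hi = hi0, mid = mid0, sc = sc0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e)
      stop("sigmoid fit did not converge: ", conditionMessage(e),
           call. = FALSE))
  cf <- stats::coef(fit)
  lower <- min(cf["lo"], cf["hi"]); upper <- max(cf["lo"], cf["hi"])
  mid <- unname(cf["mid"])
  structure(list(midpoint = if (log_x) 10^mid else mid,
                 lower = unname(lower), upper = unname(upper),
                 scale = unname(cf["sc"]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 extrapolated = mid < min(xf) || mid > max(xf),
                 fitted = stats::fitted(fit)),
            class = "sigmoid_fit")
}
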