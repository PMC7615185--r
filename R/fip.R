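# Fiber-photometry dF/F with double-exponential bleach correction.

#' Bleach-corrected dF/F and inhibition/rebound metrics
#'
#' Photobleaching is removed by fitting a double-exponential trend
#' (plus offset) to the fluorescence time series with the stimulation
#' window and the 10 s rebound period excluded, then dividing the trace
#' by the trend (bleach scales the signal multiplicatively, so division
#' leaves response amplitudes in fractional units regardless of how much
#' signal has bleached away).  Baseline is the mean of the corrected
#' trace over the 5 s immediately before stimulation, taken before
#' filtering so edge bleed from the stimulus transient cannot tilt it;
#' dF/F = (F - baseline) / baseline is then low-pass filtered at 0.5 Hz.
#' The peak-inhibited amplitude is the minimum dF/F during stimulation;
#' the rebound is the maximum dF/F in the 10 s after stimulus cessation.
#'
#' @param time_s Time axis (s), uniform sampling.
#' @param fluor Raw fluorescence trace (arbitrary units, > 0).
#' @param stim_on_s,stim_off_s Stimulation window (s); must start at
#'   least 5 s into the record.
#' @param lowpass_hz Post-correction low-pass cutoff (default 0.5 Hz).
#' @return A list of class `dff_result`: `dff` (trace), `baseline`
#'   (raw-unit baseline), `peak_inhibited`, `rebound`, `trend`.
#' @export
compute_dff_metrics <- function(time_s, fluor, stim_on_s, stim_off_s,
                                lowpass_hz = 0.5) {
  stopifnot(length(time_s) == length(fluor))
  fs <- 1 / stats::median(diff(time_s))
  if (stim_on_s - time_s[1] < 5)
    stop("need >= 5 s of pre-stimulus data before stim_on_s", call. = FALSE)
  if (stim_off_s <= stim_on_s || stim_off_s > time_s[length(time_s)])
    stop("stimulation window must lie inside the record", call. = FALSE)

  # bleach trend on samples outside the stimulus and rebound windows
  keep <- time_s < stim_on_s | time_s > stim_off_s + 10
  trend_fit <- fit_exponential_kinetics(time_s[keep], fluor[keep],
                                        n_components = 2, offset = TRUE)
  t0 <- time_s - time_s[1]
  trend <- trend_fit$offset +
    colSums(trend_fit$amplitudes * t(exp(-outer(t0, trend_fit$tau, "/"))))
  if (any(trend <= 0))
    stop("fitted bleach trend is not positive; cannot normalize",
         call. = FALSE)
  corrected <- fluor / trend           # dimensionless, ~1 at baseline

  base_win <- time_s >= stim_on_s - 5 & time_s < stim_on_s
  # baseline from the unfiltered corrected trace: the 5 s mean is itself a
  # strong low-pass and stays free of filter bleed from the stimulus edge
  baseline <- mean(corrected[base_win])
  if (!is.finite(baseline) || baseline == 0)
    stop("baseline fluorescence is zero; dF/F undefined", call. = FALSE)

  if (lowpass_hz > 0 && fs > 2 * lowpass_hz)
    corrected <- lowpass_gaussian(corrected, lowpass_hz, fs)
  dff <- (corrected - baseline) / baseline

  stim <- time_s >= stim_on_s & time_s <= stim_off_s
  post <- time_s > stim_off_s & time_s <= stim_off_s + 10
  baseline <- baseline * mean(trend[base_win])   # back to raw units
  structure(list(dff = dff, baseline = baseline,
                 peak_inhibited = min(dff[stim]),
                 rebound = if (any(post)) max(dff[post]) else NA_real_,
                 trend = trend),
            class = "dff_result")
}
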