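# Voltage-clamp I-V recordings: construction, photocurrent metrics and
# reversal-potential estimation.

#' Voltage-clamp recording with stepped test voltages
#'
#' Holds one light-evoked current trace per voltage step on a shared time
#' grid, plus the light window needed to extract photocurrent amplitudes.
#'
#' @param time_s Shared time grid (s), strictly increasing.
#' @param voltages_mv Voltage steps (mV), strictly increasing.
#' @param currents_pa Matrix of currents (pA), one column per step,
#'   `length(time_s)` rows.
#' @param light_on_s,light_off_s Light window (s), inside the record.
#' @param sampling_hz Sampling rate (Hz).
#' @param junction_corrected Logical flag: voltages already corrected for
#'   the liquid-junction potential.  The correction itself is a
#'   user-supplied additive offset applied before construction.
#' @return An object of class `iv_recording`.
#' @export
iv_recording <- function(time_s, voltages_mv, currents_pa,
                         light_on_s, light_off_s, sampling_hz,
                         junction_corrected = FALSE) {
  currents_pa <- as.matrix(currents_pa)
  if (is.unsorted(time_s, strictly = TRUE))
    stop("time_s must be strictly increasing", call. = FALSE)
  if (is.unsorted(voltages_mv, strictly = TRUE))
    stop("voltage steps must be strictly increasing", call. = FALSE)
  if (nrow(currents_pa) != length(time_s) ||
      ncol(currents_pa) != length(voltages_mv))
    stop("currents_pa must be length(time_s) x length(voltages_mv)",
         call. = FALSE)
  if (light_on_s < time_s[1] || light_off_s > time_s[length(time_s)] ||
      light_on_s >= light_off_s)
    stop("light window must lie inside the record", call. = FALSE)
  structure(list(time_s = time_s, voltages_mv = voltages_mv,
                 currents_pa = currents_pa, light_on_s = light_on_s,
                 light_off_s = light_off_s, sampling_hz = sampling_hz,
                 junction_corrected = isTRUE(junction_corrected)),
            class = "iv_recording")
}

#' Photocurrent amplitude and desensitization metrics of one trace
#'
#' Baseline is the pre-light mean; peak is the extremum of largest
#' magnitude during the light window (currents are signed); steady state
#' is the mean over the final 10 percent of the light window.  Both are
#' baseline-subtracted with sign preserved.
#'
#' @param time_s Time axis (s).
#' @param current_pa Current trace (pA).
#' @param light_on_s,light_off_s Light window (s).
#' @return A list of class `photocurrent_metrics`: `baseline_pa`,
#'   `peak_pa`, `steady_pa`, `time_to_peak_s`.
#' @export
extract_photocurrent_metrics <- function(time_s, current_pa,
                                         light_on_s, light_off_s) {
  stopifnot(length(time_s) == length(current_pa))
  if (light_on_s < time_s[1] || light_off_s > time_s[length(time_s)] ||
      light_on_s >= light_off_s)
    stop("light window must lie inside the record", call. = FALSE)
  pre <- time_s < light_on_s
  if (!any(pre))
    stop("no baseline segment before light onset", call. = FALSE)
  base <- mean(current_pa[pre])
  lit <- time_s >= light_on_s & time_s <= light_off_s
  seg <- current_pa[lit] - base
  ipk <- which.max(abs(seg))
  tail_from <- light_off_s - 0.1 * (light_off_s - light_on_s)
  tail <- time_s >= tail_from & time_s <= light_off_s
  structure(list(baseline_pa = base, peak_pa = seg[ipk],
                 steady_pa = mean(current_pa[tail]) - base,
                 time_to_peak_s = time_s[lit][ipk]),
            class = "photocurrent_metrics")
}

#' Estimate the reversal potential from an I-V family
#'
#' Builds the I-V table from per-step photocurrent amplitudes (peak or
#' steady-state), then locates the zero crossing.  Interpolation between
#' the two bracketing steps is preferred; when every amplitude has the
#' same sign, the crossing is linearly extrapolated from the two steps
#' whose currents are nearest zero and the estimate is flagged
#' accordingly.  Multiple sign changes are an error (listing every
#' crossing) rather than a silent choice.
#'
#' @param rec An [iv_recording()].
#' @param measure `"peak"` or `"steady"` photocurrent amplitude.
#' @return A list of class `erev_estimate`: `value_mv`, `method`
#'   (`"interpolated"` or `"extrapolated"`), `bracket_mv`, `iv_table`
#'   (data.frame voltage_mv / current_pa), `junction_corrected`.
#' @export
estimate_erev <- function(rec, measure = c("peak", "steady")) {
  stopifnot(inherits(rec, "iv_recording"))
  measure <- match.arg(measure)
  if (length(rec$voltages_mv) < 2)
    stop("need at least 2 voltage steps", call. = FALSE)
  amps <- vapply(seq_along(rec$voltages_mv), function(i) {
    m <- extract_photocurrent_metrics(rec$time_s, rec$currents_pa[, i],
                                      rec$light_on_s, rec$light_off_s)
    if (measure == "peak") m$peak_pa else m$steady_pa
  }, numeric(1))
  v <- rec$voltages_mv
  iv <- data.frame(voltage_mv = v, current_pa = amps)
  s <- sign(amps)
  if (any(s == 0)) {
    iz <- which(s == 0)
    if (length(iz) > 1)
      stop("multiple zero currents at ", paste(v[iz], collapse = ", "),
           " mV", call. = FALSE)
    out <- list(value_mv = v[iz], method = "interpolated",
                bracket_mv = c(v[max(1, iz - 1)], v[min(length(v), iz + 1)]),
                iv_table = iv, junction_corrected = rec$junction_corrected)
    return(structure(out, class = "erev_estimate"))
  }
  cross <- which(s[-length(s)] * s[-1] < 0)
  root_of <- function(i) {
    v[i] - amps[i] * (v[i + 1] - v[i]) / (amps[i + 1] - amps[i])
  }
  if (length(cross) > 1) {
    roots <- vapply(cross, root_of, numeric(1))
    stop("non-monotone I-V with multiple zero crossings at ",
         paste(signif(roots, 4), collapse = ", "), " mV", call. = FALSE)
  }
  if (length(cross) == 1) {
    i <- cross
    val <- root_of(i)
    out <- list(value_mv = val, method = "interpolated",
                bracket_mv = c(v[i], v[i + 1]))
  } else {
    # all one sign: extrapolate from the two steps nearest zero current
    ord <- order(abs(amps))[1:2]
    i <- sort(ord)
    if (amps[i[2]] == amps[i[1]])
      stop("flat I-V: cannot extrapolate a zero crossing", call. = FALSE)
    val <- v[i[1]] - amps[i[1]] * (v[i[2]] - v[i[1]]) /
           (amps[i[2]] - amps[i[1]])
    out <- list(value_mv = val, method = "extrapolated",
                bracket_mv = v[i])
  }
  out$iv_table <- iv
  out$junction_corrected <- rec$junction_corrected
  structure(out, class = "erev_estimate")
}
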