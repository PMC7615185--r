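# Gaussian low-pass filtering of sampled current/fluorescence traces.

#' Gaussian low-pass filter with a -3 dB cutoff
#'
#' Convolves the trace with a normalized Gaussian kernel whose width is
#' chosen so the frequency response passes |H| = 2^(-1/2) (-3 dB) at
#' `cutoff_hz`:  sigma_t = sqrt(ln 2) / (2 pi f_c), since the
#' continuous response is H(f) = exp(-2 pi^2 sigma_t^2 f^2).  Edges are
#' handled by reflection, so a constant trace is returned unchanged.
#'
#' @param trace Numeric vector, uniformly sampled.
#' @param cutoff_hz -3 dB cutoff frequency (Hz).
#' @param sampling_hz Sampling rate (Hz); must exceed 2 * cutoff_hz.
#' @return Filtered trace, same length as input.
#' @examples
#' t <- seq(0, 1, by = 1 / 20000)
#' y <- sin(2 * pi * 1000 * t)
#' yf <- lowpass_gaussian(y, cutoff_hz = 1000, sampling_hz = 20000)
#' max(abs(yf)) / max(abs(y))  # ~ 0.707
#' @export
lowpass_gaussian <- function(trace, cutoff_hz, sampling_hz) {
  if (!is.numeric(trace) || length(trace) < 2)
    stop("trace must be a numeric vector of length >= 2", call. = FALSE)
  if (cutoff_hz <= 0 || sampling_hz <= 0)
    stop("cutoff_hz and sampling_hz must be positive", call. = FALSE)
  if (cutoff_hz >= sampling_hz / 2)
    stop("cutoff_hz (", cutoff_hz, " Hz) must be below the Nyquist frequency ",
         sampling_hz / 2, " Hz", call. = FALSE)
  sigma_t <- sqrt(log(2)) / (2 * pi * cutoff_hz)
  sigma_n <- sigma_t * sampling_hz
  radius <- max(1L, ceiling(6 * sigma_n))
  k <- exp(-0.5 * ((-radius:radius) / sigma_n)^2)
  k <- k / sum(k)
  n <- length(trace)
  if (radius >= n)
    stop("trace too short (", n, " samples) for kernel radius ", radius,
         call. = FALSE)
  # reflect edges
  padded <- c(trace[radius:1 + 1], trace, trace[n - seq_len(radius)])
  out <- stats::filter(padded, k, method = "convolution", sides = 2)
  as.numeric(out[(radius + 1):(radius + n)])
}
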