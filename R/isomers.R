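# Retinal isomer quantification from HPLC peak areas at 360 nm.

#' Molar extinction coefficients of retinal oxime isomers at 360 nm
#'
#' The eight canonical retinal-oxime species resolved by HPLC, with the
#' standard molar extinction coefficients at 360 nm (M^-1 cm^-1) used to
#' convert peak areas to mole fractions.
#'
#' @return Named numeric vector of epsilon_360 values.
#' @export
retinal_epsilon360 <- function() {
  c("all-trans-15-syn"  = 54900,
    "all-trans-15-anti" = 51600,
    "13-cis-15-syn"     = 49000,
    "13-cis-15-anti"    = 52100,
    "11-cis-15-syn"     = 35000,
    "11-cis-15-anti"    = 29600,
    "9-cis-15-syn"      = 39300,
    "9-cis-15-anti"     = 30600)
}

#' Molar composition from HPLC peak areas
#'
#' Converts 360 nm peak areas to mole fractions by weighting each area
#' with the reciprocal extinction coefficient:
#' fraction_i = (A_i / eps_i) / sum_j (A_j / eps_j).  The result is
#' scale-invariant in the areas and always sums to 1.
#'
#' @param areas Named numeric vector of peak areas (AU x min), >= 0 and
#'   not all zero; names must appear in `epsilon`.
#' @param epsilon Named extinction-coefficient table (default
#'   [retinal_epsilon360()]).
#' @return Named vector of mole fractions, class `isomer_composition`.
#' @examples
#' unmix_composition(c("all-trans-15-syn" = 1, "9-cis-15-anti" = 1))
#' @export
unmix_composition <- function(areas, epsilon = retinal_epsilon360()) {
  if (is.null(names(areas)))
    stop("areas must be named by isomer", call. = FALSE)
  unknown <- setdiff(names(areas), names(epsilon))
  if (length(unknown))
    stop("unknown isomer name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (any(areas < 0))
    stop("peak areas must be >= 0", call. = FALSE)
  if (all(areas == 0))
    stop("all peak areas are zero", call. = FALSE)
  w <- areas / epsilon[names(areas)]
  structure(w / sum(w), class = "isomer_composition")
}

#' Light-minus-dark composition difference
#'
#' Elementwise difference of two compositions over the same isomer set;
#' the differences sum to zero by construction.
#'
#' @param light,dark `isomer_composition` vectors (same isomer sets).
#' @return Named vector of per-isomer fraction changes.
#' @export
composition_difference <- function(light, dark) {
  if (!setequal(names(light), names(dark)))
    stop("compositions cover different isomer sets", call. = FALSE)
  unclass(light) - unclass(dark)[names(light)]
}

#' Collapse 15-syn/15-anti oxime pairs to C-isomer fractions
#'
#' Sums the syn and anti oxime forms of each retinal C-isomer
#' (all-trans, 13-cis, 11-cis, 9-cis), the level at which photoproduct
#' changes are usually discussed.
#'
#' @param composition An `isomer_composition`.
#' @return Named vector of C-isomer fractions.
#' @export
reduce_to_c_isomers <- function(composition) {
  base <- sub("-15-(syn|anti)$", "", names(composition))
  tapply(unclass(composition), base, sum)[unique(base)]
}

#' Integrate chromatogram peaks over retention windows
#'
#' Baseline-corrected trapezoidal integration: within each retention
#' window the baseline is the straight line between the signal values at
#' the window endpoints; the area is the trapezoidal integral of the
#' signal above that line.  Negative areas are clipped to zero with a
#' warning.  Windows must be disjoint and inside the record.
#'
#' @param time_min Retention time axis (min), increasing.
#' @param absorbance Detector signal (AU at 360 nm).
#' @param windows Named list of `c(start_min, end_min)` windows, one per
#'   isomer.
#' @return Named vector of areas (AU x min).
#' @export
integrate_peaks <- function(time_min, absorbance, windows) {
  stopifnot(length(time_min) == length(absorbance))
  iv <- t(vapply(windows, function(w) sort(w[1:2]), numeric(2)))
  ord <- order(iv[, 1])
  if (any(iv[ord, 1][-1] < iv[ord, 2][-nrow(iv)]))
    stop("retention windows overlap", call. = FALSE)
  if (min(iv) < time_min[1] || max(iv) > time_min[length(time_min)])
    stop("retention windows extend outside the record", call. = FALSE)
  areas <- vapply(seq_along(windows), function(i) {
    w <- iv[i, ]
    keep <- time_min >= w[1] & time_min <= w[2]
    tt <- time_min[keep]; yy <- absorbance[keep]
    base <- yy[1] + (yy[length(yy)] - yy[1]) *
      (tt - tt[1]) / (tt[length(tt)] - tt[1])
    z <- yy - base
    sum(diff(tt) * (z[-1] + z[-length(z)]) / 2)
  }, numeric(1))
  names(areas) <- names(windows)
  if (any(areas < 0)) {
    warning("negative peak area(s) clipped to 0: ",
            paste(names(areas)[areas < 0], collapse = ", "), call. = FALSE)
    areas[areas < 0] <- 0
  }
  areas
}
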