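#' Factory wavenumber axis of the emulated spectrometer
#'
#' The emulated CCD covers Raman shifts of roughly 400 to 2000 cm^-1 with a
#' uniform spacing of 950/520 cm^-1 (about 1.83 cm^-1 per pixel), anchored so
#' that bins fall exactly on 800 and 1750 cm^-1. With this axis the fingerprint
#' truncation to the closed interval \[800, 1750\] cm^-1 retains exactly 521
#' spectral bins.
#'
#' @param n_left number of bins below 800 cm^-1 (default 218, reaching
#'   ~401.7 cm^-1).
#' @param n_right number of bins above 800 cm^-1 (default 656, reaching
#'   ~1998.5 cm^-1).
#' @return A list with `wavenumber` (numeric vector), `coefficients`
#'   (intercept/slope of the pixel -> cm^-1 map, pixel index starting at 0)
#'   and `spacing` (cm^-1 per pixel).
#' @export
factory_axis <- function(n_left = 218L, n_right = 656L) {
  spacing <- 950 / 520
  nu0 <- 800 - n_left * spacing
  wavenumber <- nu0 + spacing * seq(0L, n_left + n_right)
  list(
    wavenumber = wavenumber,
    coefficients = c(intercept = nu0, slope = spacing),
    spacing = spacing
  )
}

#' Fingerprint-region truncation window
#'
#' Lower- and upper-bound Raman shifts (cm^-1) of the retained fingerprint
#' region. Bins at exactly 800 or 1750 cm^-1 are retained (closed interval).
#' @return Numeric vector `c(lower, upper)`.
#' @export
fingerprint_window <- function() c(lower = 800, upper = 1750)
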