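# indexes of strict local maxima of a numeric vector
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
}

# sub-pixel apex by least-squares parabola over a +/- w window
parabolic_apex <- function(y, i, w = 3L) {
  idx <- max(1L, i - w):min(length(y), i + w)
  if (length(idx) < 3L) return(i)
  fit <- lm(y[idx] ~ poly(idx, 2L, raw = TRUE))
  b <- coef(fit)
  if (!is.finite(b[[3]]) || b[[3]] >= 0) return(i)
  apex <- -b[[2]] / (2 * b[[3]])
  if (apex < min(idx) || apex > max(idx)) i else apex
}

#' Fit the pixel-to-wavenumber axis calibration
#'
#' Detects the peaks of a wavenumber reference material (polycarbonate-like,
#' with known Raman peak positions), locates each apparent peak to sub-pixel
#' precision by parabolic interpolation of the local maximum, pairs apparent
#' pixels with the declared positions in order, and fits a least-squares
#' polynomial pixel -> cm^-1 map (degree 1 by default).
#'
#' @param references calibration references as produced by
#'   [generate_references()] (needs `wavenumber_reference` and
#'   `known_peaks`).
#' @param degree polynomial degree of the map (1 to 3).
#' @param n_pixels axis length for the fitted wavenumber vector; defaults to
#'   the reference length.
#' @return A calibrated axis: list with `wavenumber`, `coefficients`
#'   (ascending powers of pixel index, 0-based), `residual_rms` (cm^-1) and
#'   `matched` (tibble of apparent pixel vs known position).
#' @export
fit_axis_calibration <- function(references, degree = 1L,
                                 n_pixels = NULL) {
  wref <- references$wavenumber_reference
  known <- sort(references$known_peaks)
  y <- savgol_smooth(as.numeric(wref$counts), order = 3L, window = 7L)
  floor_ <- median(y)
  cand <- local_maxima(y)
  cand <- cand[y[cand] - floor_ > 0.25 * (max(y) - floor_)]
  if (length(cand) < 3L) {
    abort(sprintf("axis calibration failed: only %d reference peak(s) detected",
                  length(cand)))
  }
  if (length(cand) > length(known)) {
    cand <- sort(cand[order(y[cand] - floor_, decreasing = TRUE)][
      seq_along(known)])
  }
  if (length(cand) < length(known)) {
    known <- known[seq_along(cand)]  # pair in order with what was found
  }
  if (length(cand) < 3L) abort("fewer than 3 matched calibration peaks")
  apex <- vapply(cand, function(i) parabolic_apex(y, i), numeric(1))
  pixel0 <- apex - 1 + wref$pixel[1]  # 0-based pixel coordinate
  fit <- lm(known ~ poly(pixel0, degree, raw = TRUE))
  coefs <- as.numeric(coef(fit))
  rms <- sqrt(mean(fit$residuals^2))
  n_pixels <- n_pixels %||% nrow(wref)
  px <- seq_len(n_pixels) - 1
  wavenumber <- as.numeric(cbind(1, poly(px, degree, raw = TRUE)) %*% coefs)
  list(
    wavenumber = wavenumber,
    coefficients = coefs,
    residual_rms = rms,
    matched = tibble(pixel = pixel0, known = known)
  )
}

#' Instrument response correction
#'
#' Divides a spectrum by the relative spectral response of the instrument,
#' estimated as the ratio of the measured response-standard spectrum to its
#' known smooth emission curve. The estimated correction is lightly smoothed
#' (the physical response is smooth) and normalized to unit mean, so the
#' correction changes spectral shape, not overall scale.
#'
#' @param spectrum spectrum data frame (`wavenumber`, `intensity`).
#' @param response data frame with columns `measured` and `known`, row-aligned
#'   with `spectrum`.
#' @param smooth_window Savitzky-Golay window for the correction curve
#'   (0 disables smoothing).
#' @return Corrected spectrum tibble (stage preserved).
#' @export
correct_instrument_response <- function(spectrum, response,
                                        smooth_window = 31L) {
  stopifnot(is_spectrum_df(spectrum))
  if (!all(c("measured", "known") %in% names(response))) {
    abort("response needs columns measured and known")
  }
  if (nrow(response) != nrow(spectrum)) {
    abort("response reference is not aligned with the spectrum")
  }
  corr <- response$measured / response$known
  if (smooth_window >= 5L && nrow(response) >= smooth_window) {
    corr <- savgol_smooth(corr, order = 3L, window = smooth_window)
  }
  if (any(!is.finite(corr)) || any(corr <= 0)) {
    abort("estimated instrument response must be strictly positive")
  }
  corr <- corr / mean(corr)
  out <- spectrum_tbl(spectrum$wavenumber, spectrum$intensity / corr)
  attr(out, "stage") <- spectrum_stage(spectrum)
  out
}
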