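#' Subtract the dark-count background from repeat frames
#'
#' Elementwise subtraction of the laser-off dark frame from each repeat CCD
#' frame. Values may become negative; no clipping is applied.
#'
#' @param frames numeric matrix, repeats x pixels.
#' @param dark_frame numeric vector of length `ncol(frames)`.
#' @return Matrix of the same shape.
#' @export
subtract_dark <- function(frames, dark_frame) {
  frames <- as.matrix(frames)
  if (ncol(frames) != length(dark_frame)) {
    abort("frame length does not match dark frame length")
  }
  sweep(frames, 2L, dark_frame, "-")
}

#' Remove cosmic-ray events using the repeat structure
#'
#' Cosmic-ray spikes hit a single frame and are uncorrelated across the
#' repeat measurements at the same location. Per spectral bin, values that
#' deviate from the across-repeat median by more than `k` robust scales
#' (scaled MAD) are replaced by that bin's across-repeat median; all other
#' values are untouched. Bins whose repeats are constant (zero MAD) are never
#' flagged.
#'
#' @param frames numeric matrix, repeats x pixels (>= 3 repeats).
#' @param k detection threshold in robust-scale units.
#' @return Matrix of the same shape with flagged values replaced.
#' @export
remove_cosmic_rays <- function(frames, k = 8) {
  frames <- as.matrix(frames)
  if (nrow(frames) < 3L) {
    warn("fewer than 3 repeat frames; cosmic-ray removal skipped")
    return(frames)
  }
  med <- apply(frames, 2L, median)
  scale <- apply(frames, 2L, mad)  # 1.4826 * MAD
  dev <- abs(sweep(frames, 2L, med, "-"))
  lim <- k * scale
  flag <- sweep(dev, 2L, lim, ">") & rep(scale > 0, each = nrow(frames))
  if (any(flag)) {
    repl <- matrix(rep(med, each = nrow(frames)), nrow = nrow(frames))
    frames[flag] <- repl[flag]
  }
  frames
}

#' Average repeat frames into one spectrum
#'
#' Arithmetic per-bin mean of the repeat measurements acquired at the same
#' location, increasing signal-to-noise by ~sqrt(number of repeats).
#'
#' @param frames numeric matrix, repeats x pixels (or a single vector).
#' @param wavenumber optional axis; when supplied a spectrum tibble is
#'   returned.
#' @return Numeric vector, or a tibble (`wavenumber`, `intensity`) with stage
#'   `"raw_mean"` when `wavenumber` is given.
#' @export
average_repeats <- function(frames, wavenumber = NULL) {
  if (is.null(dim(frames))) frames <- matrix(frames, nrow = 1L)
  m <- colMeans(frames)
  if (is.null(wavenumber)) return(m)
  spectrum_tbl(wavenumber, m, stage = "raw_mean")
}

#' Truncate a spectrum to the fingerprint region
#'
#' Retains the spectral bins whose Raman shift lies in the closed interval
#' \[800, 1750\] cm^-1, discarding the low-count region below 800 cm^-1 and
#' everything above 1750 cm^-1. Bins at exactly 800 or 1750 cm^-1 are kept.
#' On the factory axis this yields exactly 521 bins.
#'
#' @param spectrum a data frame with columns `wavenumber` and `intensity`.
#' @param window lower/upper bounds, defaults to [fingerprint_window()].
#' @return The truncated spectrum tibble (stage preserved).
#' @export
truncate_spectrum <- function(spectrum, window = fingerprint_window()) {
  stopifnot(is_spectrum_df(spectrum))
  tol <- 1e-6  # keep boundary bins under floating-point jitter
  keep <- spectrum$wavenumber >= window[[1]] - tol &
    spectrum$wavenumber <= window[[2]] + tol
  if (!any(keep)) abort("truncation removed every spectral bin")
  out <- as_tibble(spectrum[keep, , drop = FALSE])
  attr(out, "stage") <- spectrum_stage(spectrum)
  out
}

#' Savitzky-Golay smoothing
#'
#' Order-3 Savitzky-Golay filter with an 11-bin window (defaults used
#' throughout the pipeline). Edge bins are handled by the filter's
#' polynomial fit over the truncated edge windows, so polynomials of degree
#' <= 3 are reproduced exactly everywhere.
#'
#' @param spectrum spectrum data frame or bare numeric vector.
#' @param order polynomial order.
#' @param window filter window length (odd).
#' @return Same type as the input, smoothed; stage set to `"smoothed"` for
#'   data-frame input.
#' @export
savgol_smooth <- function(spectrum, order = 3L, window = 11L) {
  vec <- if (is_spectrum_df(spectrum)) spectrum$intensity else spectrum
  if (window %% 2L == 0L) abort("window must be odd")
  if (length(vec) < window) abort("window exceeds spectrum length")
  sm <- as.numeric(signal::sgolayfilt(vec, p = order, n = window))
  if (!is_spectrum_df(spectrum)) return(sm)
  spectrum_tbl(spectrum$wavenumber, sm, stage = "smoothed")
}

#' Standard normal variate (SNV) normalization
#'
#' Per-spectrum z-scoring: subtract the spectrum mean and divide by its
#' population (divide-by-n) standard deviation, removing multiplicative
#' intensity scale. The result has mean 0 and population sd 1.
#'
#' @param spectrum spectrum data frame or bare numeric vector.
#' @return Same type as the input; stage `"snv"` for data-frame input.
#' @export
snv_normalize <- function(spectrum) {
  vec <- if (is_spectrum_df(spectrum)) spectrum$intensity else spectrum
  s <- pop_sd(vec)
  if (s == 0) abort("cannot SNV-normalize a spectrum with zero dispersion")
  z <- (vec - mean(vec)) / s
  if (!is_spectrum_df(spectrum)) return(z)
  spectrum_tbl(spectrum$wavenumber, z, stage = "snv")
}
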