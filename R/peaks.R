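#' Peak-detection settings
#'
#' Defaults follow the pipeline's Gaussian peak-fitting convention for
#' SNV-normalized spectra (whose intensities typically range from about -2
#' to 7): minimum prominence 0.1, minimum height 0.5 above the spectrum
#' minimum, +/- 2 cm^-1 position tolerance, 50 percent consensus across
#' measurements and at most 11 retained peaks.
#'
#' @param prominence_min minimum peak prominence (SNV units).
#' @param height_min minimum height above the spectrum minimum (SNV units).
#' @param position_tolerance peak-position matching tolerance (cm^-1).
#' @param consensus_fraction fraction of measurements in which a peak must
#'   appear to be retained.
#' @param max_peaks maximum number of consensus peaks.
#' @return A `peak_config` list.
#' @export
peak_config <- function(prominence_min = 0.1, height_min = 0.5,
                        position_tolerance = 2, consensus_fraction = 0.5,
                        max_peaks = 11L) {
  stopifnot(prominence_min > 0, height_min > 0, position_tolerance > 0,
            consensus_fraction > 0, consensus_fraction <= 1, max_peaks >= 1)
  structure(list(prominence_min = prominence_min, height_min = height_min,
                 position_tolerance = position_tolerance,
                 consensus_fraction = consensus_fraction,
                 max_peaks = as.integer(max_peaks)),
            class = "peak_config")
}

# topographic prominence of local maxima
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    h <- y[p]
    left <- y[seq_len(p - 1L)]
    higher_l <- which(left > h)
    lo_l <- if (length(higher_l) == 0) min(left, h) else
      min(left[(max(higher_l) + 1L):(p - 1L)])
    right <- y[(p + 1L):length(y)]
    higher_r <- which(right > h)
    lo_r <- if (length(higher_r) == 0) min(right, h) else
      min(right[seq_len(min(higher_r) - 1L)])
    h - max(lo_l, lo_r)
  }, numeric(1))
}

# FWHM estimate from half-prominence crossings, in bins
apparent_width <- function(y, p, prom) {
  half <- y[p] - prom / 2
  l <- p
  while (l > 1L && y[l] > half) l <- l - 1L
  r <- p
  while (r < length(y) && y[r] > half) r <- r + 1L
  max(r - l, 2L)
}

#' Fit Gaussian peaks in one spectrum
#'
#' Local maxima passing the prominence and height thresholds are each fit
#' with a Gaussian plus constant offset over a window of +/- 3 initial width
#' estimates; fits that fail to converge, or whose position wanders beyond
#' the matching tolerance, fall back to the apparent (grid) position, height
#' and half-prominence width.
#'
#' @param spectrum spectrum data frame (`wavenumber`, `intensity`), normally
#'   at stage `"snv"`.
#' @param config a [peak_config()].
#' @return Tibble with one row per detected peak: `position` (cm^-1),
#'   `height` (spectrum value at the apex, SNV units), `width` (full width
#'   at half maximum, cm^-1).
#' @export
fit_peaks <- function(spectrum, config = peak_config()) {
  stopifnot(is_spectrum_df(spectrum))
  y <- spectrum$intensity
  nu <- spectrum$wavenumber
  spacing <- (nu[length(nu)] - nu[1]) / (length(nu) - 1L)
  cand <- local_maxima(y)
  if (length(cand) == 0L) {
    return(tibble(position = numeric(0), height = numeric(0),
                  width = numeric(0)))
  }
  prom <- peak_prominence(y, cand)
  floor_ <- min(y)
  ok <- prom >= config$prominence_min & (y[cand] - floor_) >= config$height_min
  cand <- cand[ok]
  prom <- prom[ok]
  if (length(cand) == 0L) {
    return(tibble(position = numeric(0), height = numeric(0),
                  width = numeric(0)))
  }
  fwhm_const <- 2 * sqrt(2 * log(2))
  rows <- purrr::map2_dfr(cand, prom, function(p, pr) {
    w_bins <- apparent_width(y, p, pr)
    sigma0 <- w_bins * spacing / fwhm_const
    half_win <- max(3L, ceiling(3 * w_bins / fwhm_const))
    idx <- max(1L, p - half_win):min(length(y), p + half_win)
    apparent <- tibble(position = nu[p], height = y[p],
                       width = w_bins * spacing)
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        yy ~ c0 + h * exp(-(xx - mu)^2 / (2 * s^2)),
        data = list(yy = y[idx], xx = nu[idx]),
        start = list(c0 = min(y[idx]), h = y[p] - min(y[idx]),
                     mu = nu[p], s = sigma0),
        lower = c(-Inf, 0, min(nu[idx]), spacing / 2),
        upper = c(Inf, Inf, max(nu[idx]), diff(range(nu[idx]))),
        control = minpack.lm::nls.lm.control(maxiter = 100)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) return(apparent)
    cf <- coef(fit)
    if (abs(cf[["mu"]] - nu[p]) > config$position_tolerance) return(apparent)
    tibble(position = cf[["mu"]], height = cf[["c0"]] + cf[["h"]],
           width = fwhm_const * cf[["s"]])
  })
  rows[order(rows$position), ]
}

#' Consensus peaks across a dataset
#'
#' Clusters fitted peaks across measurements by position (within the
#' matching tolerance of the running cluster median) and retains the
#' clusters present in at least `consensus_fraction` of all measurements
#' (boundary inclusive), capped at `max_peaks` by descending occurrence.
#' Clusters whose canonical (median) position falls in the haemoglobin
#' region \[1500, 1620\] cm^-1 are excluded.
#'
#' @param peaks tibble of fitted peaks across the dataset; needs columns
#'   `location_id`, `position`, `height`, `width` (see [dataset_peaks()]).
#' @param n_measurements total number of measurements in the dataset.
#' @param config a [peak_config()].
#' @return Tibble of consensus peaks: `position`, `occurrence` (fraction of
#'   measurements), `median_width`, `n`.
#' @export
consensus_peaks <- function(peaks, n_measurements, config = peak_config()) {
  stopifnot(n_measurements >= 1)
  empty <- tibble(position = numeric(0), occurrence = numeric(0),
                  median_width = numeric(0), n = integer(0))
  if (nrow(peaks) == 0L) return(empty)
  pk <- peaks[order(peaks$position), ]
  cluster <- integer(nrow(pk))
  cur <- 1L
  members <- pk$position[1]
  cluster[1] <- cur
  for (i in seq_len(nrow(pk))[-1]) {
    if (abs(pk$position[i] - median(members)) <= config$position_tolerance) {
      members <- c(members, pk$position[i])
    } else {
      cur <- cur + 1L
      members <- pk$position[i]
    }
    cluster[i] <- cur
  }
  pk$cluster <- cluster
  out <- pk |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      position = median(.data$position),
      occurrence = dplyr::n_distinct(.data$location_id) / n_measurements,
      median_width = median(.data$width),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::select(-"cluster") |>
    dplyr::filter(.data$occurrence >= config$consensus_fraction,
                  .data$position < 1500 | .data$position > 1620)
  out <- out[order(-out$occurrence, out$position), ]
  utils::head(out, config$max_peaks)
}

#' Fit peaks for every spectrum of a dataset
#'
#' @param spectra a `raman_spectra` tibble.
#' @param config a [peak_config()].
#' @return Tibble of fitted peaks with a `location_id` column.
#' @export
dataset_peaks <- function(spectra, config = peak_config()) {
  nu <- attr(spectra, "wavenumber")
  purrr::map_dfr(seq_len(nrow(spectra)), function(i) {
    pk <- fit_peaks(spectrum_tbl(nu, spectra$spectrum[[i]], "snv"), config)
    if (nrow(pk) == 0L) return(pk)
    dplyr::mutate(pk, location_id = spectra$location_id[i], .before = 1L)
  })
}
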