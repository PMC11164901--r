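# resolve truncation + calibration + per-site response corrections once
chain_setup <- function(references, n_pixels, sites,
                        window = fingerprint_window()) {
  coefs <- references$nominal_coefficients
  pixel0 <- seq_len(n_pixels) - 1
  nu_prov <- coefs[["intercept"]] + coefs[["slope"]] * pixel0
  spacing <- coefs[["slope"]]
  keep <- nu_prov >= window[[1]] - 1e-6 & nu_prov <= window[[2]] + 1e-6
  if (!any(keep)) abort("truncation removed every spectral bin")

  calib <- fit_axis_calibration(references, n_pixels = n_pixels)
  nu_cal <- calib$wavenumber
  # re-check truncation on the calibrated axis: drop bins that drifted
  # materially (more than half a bin) outside the fingerprint window
  drifted <- keep & (nu_cal < window[[1]] - spacing / 2 |
                       nu_cal > window[[2]] + spacing / 2)
  if (any(drifted)) {
    warn(sprintf("%d bin(s) drifted outside [%g, %g] after calibration",
                 sum(drifted), window[[1]], window[[2]]))
    keep <- keep & !drifted
  }

  corrections <- lapply(setNames(sites, sites), function(s) {
    ref <- references$response_reference
    ref <- ref[ref$site == s, , drop = FALSE]
    ref <- ref[order(ref$pixel), , drop = FALSE][keep, , drop = FALSE]
    corr <- ref$measured / ref$known
    if (length(corr) >= 31L) corr <- savgol_smooth(corr, 3L, 31L)
    if (any(!is.finite(corr)) || any(corr <= 0)) {
      abort(sprintf("nonpositive response estimate for site %s", s))
    }
    corr / mean(corr)
  })

  list(keep = keep, wavenumber = nu_cal[keep], calibration = calib,
       corrections = corrections)
}

chain_one <- function(frames, dark, site, setup, min_bubble_width,
                      keep_stages = FALSE) {
  f <- subtract_dark(frames, dark)                         # (1)
  f <- remove_cosmic_rays(f)                               # (2)
  f <- f[, setup$keep, drop = FALSE]                       # (3)+(4) recheck
  corr <- setup$corrections[[site]]                        # (5)
  f <- sweep(f, 2L, corr, "/")
  mean_spec <- average_repeats(f, setup$wavenumber)        # (6)
  bf <- bubblefill(mean_spec, min_bubble_width)            # (7)
  smoothed <- savgol_smooth(
    spectrum_tbl(bf$wavenumber, bf$raman, "baseline_removed"))  # (8)
  final <- snv_normalize(smoothed)                         # (9)
  if (!keep_stages) return(final)
  attr(final, "stages") <- list(raw_mean = mean_spec, baseline = bf,
                                smoothed = smoothed)
  final
}

#' Preprocess one raw acquisition into an SNV-normalized spectrum
#'
#' Applies the full nine-step conditioning chain to the repeat frames of one
#' probed location: (1) dark-count subtraction, (2) cosmic-ray removal,
#' (3) fingerprint truncation on the provisional factory axis, (4) x-axis
#' calibration against the wavenumber reference (bins drifting outside the
#' window are dropped), (5) instrument response correction, (6) averaging of
#' the repeat frames, (7) BubbleFill baseline removal, (8) Savitzky-Golay
#' smoothing (order 3, window 11) and (9) SNV normalization.
#'
#' @param acquisition one acquisition: a list or one-row tibble with
#'   `frames` (repeats x pixels matrix), `dark` (vector) and `site`.
#' @param references calibration references ([generate_references()]).
#' @param min_bubble_width minimum bubble diameter for the baseline step
#'   (cm^-1).
#' @param keep_stages attach intermediate stages as an attribute.
#' @return SNV-stage spectrum tibble (`wavenumber`, `intensity`).
#' @export
preprocess_acquisition <- function(acquisition, references,
                                   min_bubble_width = 60,
                                   keep_stages = FALSE) {
  frames <- acquisition$frames
  dark <- acquisition$dark
  if (is.list(frames) && !is.matrix(frames)) frames <- frames[[1]]
  if (is.list(dark)) dark <- dark[[1]]
  site <- as.character(acquisition$site)[1]
  setup <- chain_setup(references, n_pixels = ncol(frames), sites = site)
  chain_one(frames, dark, site, setup, min_bubble_width, keep_stages)
}

#' Preprocess every acquisition of a cohort
#'
#' Runs the nine-step chain of [preprocess_acquisition()] on each location,
#' fitting the axis calibration and per-site response corrections once.
#'
#' @param cohort a `raman_cohort`.
#' @param min_bubble_width minimum bubble diameter (cm^-1).
#' @return A `raman_spectra` tibble: one row per location with the metadata
#'   columns and a `spectrum` list-column of SNV intensities; the common
#'   wavenumber axis is stored in `attr(, "wavenumber")`.
#' @export
preprocess_cohort <- function(cohort, min_bubble_width = 60) {
  stopifnot(inherits(cohort, "raman_cohort"))
  acq <- cohort$acquisitions
  if (!"frames" %in% names(acq)) {
    abort("cohort was generated with frames = FALSE; nothing to preprocess")
  }
  setup <- chain_setup(cohort$references,
                       n_pixels = ncol(acq$frames[[1]]),
                       sites = unique(acq$site))
  spectra <- purrr::map(seq_len(nrow(acq)), function(i) {
    chain_one(acq$frames[[i]], acq$dark[[i]], acq$site[i], setup,
              min_bubble_width)$intensity
  })
  out <- acq[, setdiff(names(acq), c("frames", "dark"))]
  out$spectrum <- spectra
  attr(out, "wavenumber") <- setup$wavenumber
  attr(out, "calibration") <- setup$calibration
  class(out) <- c("raman_spectra", class(out))
  out
}

#' Spectra table as a numeric matrix
#'
#' @param spectra a `raman_spectra` tibble from [preprocess_cohort()].
#' @return locations x bins matrix; column names are the wavenumbers.
#' @export
spectra_matrix <- function(spectra) {
  m <- do.call(rbind, spectra$spectrum)
  rownames(m) <- spectra$location_id
  colnames(m) <- format(attr(spectra, "wavenumber"), trim = TRUE)
  m
}

#' Spectra table in long (tidy) format
#'
#' @param spectra a `raman_spectra` tibble.
#' @return Long tibble: `location_id`, `label`, `wavenumber`, `intensity`.
#' @export
spectra_long <- function(spectra) {
  nu <- attr(spectra, "wavenumber")
  purrr::map_dfr(seq_len(nrow(spectra)), function(i) {
    tibble(location_id = spectra$location_id[i], label = spectra$label[i],
           wavenumber = nu, intensity = spectra$spectrum[[i]])
  })
}
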