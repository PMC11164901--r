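# smooth per-site relative gain curve (instrument response)
site_response <- function(cfg, site, wavenumber = cfg$axis$wavenumber) {
  phase <- c(site_a = 0.7, site_b = 2.6)[[site]]
  1 + cfg$site_gain_amplitude * sin(2 * pi * (wavenumber - 400) / 1600 + phase)
}

# NIST-standard-like known smooth emission curve of the response reference
known_standard_curve <- function(wavenumber) {
  0.6 + 0.8 * exp(-((wavenumber - 1100) / 500)^2)
}

gaussian_mixture <- function(wavenumber, position, amplitude, sigma) {
  out <- numeric(length(wavenumber))
  for (k in seq_along(position)) {
    out <- out + amplitude[k] *
      exp(-(wavenumber - position[k])^2 / (2 * sigma[k]^2))
  }
  out
}

draw_counts <- function(lambda, noise) {
  if (noise == "none") return(lambda)
  rpois(length(lambda), lambda)
}

add_cosmic_spikes <- function(frame, lambda, rate) {
  n_spike <- rpois(1L, rate)
  if (n_spike == 0L) return(frame)
  n_pix <- length(frame)
  for (s in seq_len(n_spike)) {
    centre <- sample.int(n_pix, 1L)
    width <- sample.int(3L, 1L)
    factor <- runif(1L, 10, 100)
    idx <- centre:min(n_pix, centre + width - 1L)
    frame[idx] <- frame[idx] + factor * pmax(lambda[idx], 1)
  }
  frame
}

#' Generate a synthetic two-site Raman cohort
#'
#' Simulates raw probe acquisitions with the statistical structure of a
#' multi-site neurosurgical Raman study: each patient belongs to one site and
#' one tumor pathology and contributes a balanced set of tumor and
#' non-tumoral brain locations; each location yields `n_repeats` CCD frames of
#' `response x (fluorescence baseline + class-dependent Gaussian band mixture)
#' + dark counts`, with shot noise and cosmic-ray spikes, plus one dark frame.
#' Ground truth (noiseless baseline and Raman signal per location) is returned
#' for validation.
#'
#' @param config a [cohort_config()].
#' @param frames if `FALSE`, skip frame simulation and return metadata plus
#'   truth only (fast mode for large effect-size studies).
#' @return A `raman_cohort` list: `acquisitions` (tibble, one row per
#'   location, with `frames` and `dark` list-columns), `truth` (tibble with
#'   `baseline` and `signal` list-columns on the raw axis), `references`
#'   (see [generate_references()]), `axis`, `config`.
#' @export
generate_cohort <- function(config, frames = TRUE) {
  cfg <- validate_cohort_config(config)
  axis <- cfg$axis
  nu <- axis$wavenumber
  n_pix <- length(nu)
  bt <- cfg$band_table

  meta <- withr::with_seed(derive_seed(cfg$seed, 1L), {
    patients <- tidyr::expand_grid(
      site = cfg$sites,
      pathology = names(cfg$pathologies),
      idx = seq_len(cfg$n_patients_per_site)
    )
    patients$patient_id <- sprintf("%s_%s_p%02d", patients$site,
                                   substr(patients$pathology, 1, 3),
                                   patients$idx)
    # per-patient multiplicative effect, one factor per biochemical band group
    groups <- unique(band_group(bt$band))
    pef <- matrix(
      rlnorm(nrow(patients) * length(groups), 0, cfg$patient_effect_sd),
      nrow = nrow(patients), dimnames = list(patients$patient_id, groups)
    )
    locs <- purrr::map_dfr(seq_len(nrow(patients)), function(i) {
      n_loc <- cfg$n_locations_per_patient
      n_tum <- n_loc %/% 2L + (i %% 2L) * (n_loc %% 2L)
      label <- sample(c(rep("tumor", n_tum), rep("brain", n_loc - n_tum)))
      tibble(patient_id = patients$patient_id[i], site = patients$site[i],
             pathology = patients$pathology[i], label = label)
    })
    locs$location_id <- sprintf("loc_%04d", seq_len(nrow(locs)))
    locs$lowq <- runif(nrow(locs)) < cfg$lowq_fraction
    list(patients = patients, patient_effects = pef, locations = locs)
  })

  locs <- meta$locations
  pef <- meta$patient_effects
  grp <- band_group(bt$band)
  mid <- (bt$brain + bt$tumor) / 2

  sim <- withr::with_seed(derive_seed(cfg$seed, 2L), {
    purrr::map(seq_len(nrow(locs)), function(i) {
      cls <- locs$label[i]
      mult <- cfg$pathologies[[locs$pathology[i]]]
      base_amp <- mid + mult * (bt[[cls]] - mid)
      amp <- base_amp * pef[locs$patient_id[i], grp] *
        exp(rnorm(nrow(bt), 0, cfg$amp_jitter_sdlog[[cls]]))
      signal <- gaussian_mixture(nu, bt$band, amp, bt$sigma)
      baseline <- cfg$baseline_amplitude * exp(rnorm(1L, 0, 0.15)) *
        exp(-(nu - 400) / cfg$baseline_decay)
      if (locs$lowq[i]) {
        # poor probe-tissue coupling dims the whole photon budget, so the
        # fixed dark/read noise floor dominates the averaged spectrum
        signal <- signal * cfg$lowq_scale
        baseline <- baseline * cfg$lowq_scale
      }
      out <- list(baseline = baseline, signal = signal)
      if (frames) {
        resp <- site_response(cfg, locs$site[i], nu)
        lambda <- resp * (baseline + signal) + cfg$dark_mean
        fr <- matrix(draw_counts(rep(lambda, each = cfg$n_repeats),
                                 cfg$noise),
                     nrow = cfg$n_repeats, ncol = n_pix)
        if (cfg$noise != "none" && cfg$read_noise > 0) {
          fr <- fr + rnorm(length(fr), 0, cfg$read_noise)
        }
        if (cfg$cosmic_rate > 0) {
          for (r in seq_len(cfg$n_repeats)) {
            fr[r, ] <- add_cosmic_spikes(fr[r, ], lambda, cfg$cosmic_rate)
          }
        }
        out$frames <- fr
        out$dark <- draw_counts(rep(cfg$dark_mean, n_pix), cfg$noise)
      }
      out
    })
  })

  acquisitions <- locs[, c("location_id", "patient_id", "site", "pathology",
                           "label", "lowq")]
  if (frames) {
    acquisitions$frames <- purrr::map(sim, "frames")
    acquisitions$dark <- purrr::map(sim, "dark")
  }
  truth <- tibble(
    location_id = locs$location_id,
    label = locs$label,
    baseline = purrr::map(sim, "baseline"),
    signal = purrr::map(sim, "signal")
  )

  structure(
    list(acquisitions = acquisitions, truth = truth,
         references = generate_references(cfg), axis = axis, config = cfg),
    class = "raman_cohort"
  )
}

#' Generate calibration reference measurements
#'
#' Produces the two calibration inputs the preprocessing chain expects:
#' a wavenumber reference (a polycarbonate-like material with known Raman peak
#' positions, measured on the pixel axis) for x-axis calibration, and a
#' per-site response reference (a standard with known smooth emission curve)
#' for instrument response correction.
#'
#' @param config a [cohort_config()].
#' @return A list: `wavenumber_reference` (tibble `pixel`, `counts`),
#'   `known_peaks` (cm^-1), `response_reference` (tibble `site`, `pixel`,
#'   `wavenumber`, `measured`, `known`), `nominal_coefficients` (the factory
#'   pixel -> cm^-1 map).
#' @export
generate_references <- function(config) {
  cfg <- validate_cohort_config(config)
  nu <- cfg$axis$wavenumber
  pixel <- seq_along(nu) - 1L
  coefs <- cfg$axis$coefficients
  known_peaks <- c(635, 705, 888, 1114, 1235, 1602)

  withr::with_seed(derive_seed(cfg$seed, 3L), {
    peak_pixels <- (known_peaks - coefs[["intercept"]]) / coefs[["slope"]]
    lam <- 50 + gaussian_mixture(pixel, peak_pixels,
                                 rep(1000, length(peak_pixels)),
                                 rep(2, length(peak_pixels)))
    wavenumber_reference <- tibble(
      pixel = pixel, counts = draw_counts(lam, cfg$noise)
    )
    known <- known_standard_curve(nu)
    response_reference <- purrr::map_dfr(cfg$sites, function(s) {
      lam_r <- site_response(cfg, s, nu) * known * 2000
      tibble(site = s, pixel = pixel, wavenumber = nu,
             measured = draw_counts(lam_r, cfg$noise), known = known)
    })
    list(
      wavenumber_reference = wavenumber_reference,
      known_peaks = known_peaks,
      response_reference = response_reference,
      nominal_coefficients = coefs
    )
  })
}

#' @export
print.raman_cohort <- function(x, ...) {
  acq <- x$acquisitions
  cat("<raman_cohort>\n")
  cat(sprintf("  %d locations, %d patients, sites: %s\n", nrow(acq),
              dplyr::n_distinct(acq$patient_id),
              paste(unique(acq$site), collapse = ", ")))
  cat(sprintf("  labels: %s\n",
              paste(sprintf("%s=%d", names(table(acq$label)),
                            as.integer(table(acq$label))), collapse = ", ")))
  invisible(x)
}
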