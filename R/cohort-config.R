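#' Default class-dependent Raman band table
#'
#' Mean band amplitudes (arbitrary photon-count scale, per 100 ms frame) for
#' non-tumoral brain and tumor tissue at the five diagnostic bands used
#' throughout the pipeline: phenylalanine (1004 cm^-1), lipid C-C (1299),
#' tryptophan (1340), the lipid/protein CH2 deformation band (1441) and the
#' amide-I / C=C band (1659). Tumor tissue carries more protein signal (higher
#' 1004 and 1340) and less lipid (lower 1299 and 1441); the 1659 band is
#' configured with equal class means (a known non-discriminating band).
#'
#' The 1441 band is given a full width at half maximum of ~60 cm^-1, the width
#' that motivates the default minimum bubble diameter of the baseline-removal
#' step; the remaining bands have sigmas in the 3-10 cm^-1 range typical of
#' tissue Raman features.
#'
#' @return A tibble with columns `band` (cm^-1), `sigma` (Gaussian sigma,
#'   cm^-1), `brain` and `tumor` (mean amplitudes).
#' @export
default_band_table <- function() {
  tibble(
    band  = c(1004, 1299, 1340, 1441, 1659),
    sigma = c(5, 8, 9, 60 / (2 * sqrt(2 * log(2))), 12),
    brain = c(200, 600, 200, 1000, 500),
    tumor = c(500, 350, 450, 550, 500)
  )
}

#' Configuration for the synthetic Raman cohort generator
#'
#' Defines the statistical structure of an emulated two-site neurosurgical
#' Raman study: per-patient repeated probe measurements, class-dependent band
#' amplitudes, fluorescence baselines, shot noise, cosmic-ray events, patient
#' and site random effects, and a fraction of low-signal (low-quality)
#' acquisitions.
#'
#' @param n_patients_per_site patients per pathology per site.
#' @param n_locations_per_patient probed locations per patient (tumor and
#'   non-tumoral brain locations balanced within each patient).
#' @param n_repeats successive CCD frames per location (averaged downstream).
#' @param band_table tibble with columns `band`, `sigma`, `brain`, `tumor`;
#'   must contain rows for 1004, 1299, 1340, 1441 and 1659 cm^-1.
#' @param amp_jitter_sdlog named numeric `c(brain=, tumor=)`: per-location
#'   log-normal sd of band amplitudes. Tumor must not exceed brain (tumor
#'   spectra show lower variance).
#' @param patient_effect_sd log-normal sd of the per-patient multiplicative
#'   effect, applied per biochemical band group (protein / lipid / amide).
#' @param site_gain_amplitude relative amplitude of the smooth per-site gain
#'   distortion of the instrument response (0.1 = +/-10 percent).
#' @param baseline_amplitude fluorescence baseline counts at 400 cm^-1.
#' @param baseline_decay exponential decay constant of the baseline (cm^-1).
#' @param dark_mean mean dark counts per frame.
#' @param cosmic_rate expected cosmic-ray spikes per frame.
#' @param noise `"poisson"` for shot noise, `"none"` for noiseless output.
#' @param read_noise Gaussian CCD read noise (counts per frame per bin,
#'   added when `noise = "poisson"`).
#' @param lowq_fraction fraction of locations acquired at reduced signal
#'   (weak tissue coupling), yielding low spectral quality.
#' @param lowq_scale photon-throughput multiplier for low-quality
#'   locations (scales signal and fluorescence baseline jointly, so the
#'   dark/read noise floor dominates).
#' @param pathologies named numeric vector of pathology contrast multipliers;
#'   1 reproduces the band table contrast exactly.
#' @param seed integer seed controlling all randomness.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_patients_per_site = 4L,
                          n_locations_per_patient = 30L,
                          n_repeats = 20L,
                          band_table = default_band_table(),
                          amp_jitter_sdlog = c(brain = 0.20, tumor = 0.12),
                          patient_effect_sd = 0.10,
                          site_gain_amplitude = 0.10,
                          baseline_amplitude = 4000,
                          baseline_decay = 700,
                          dark_mean = 100,
                          cosmic_rate = 0.2,
                          noise = c("poisson", "none"),
                          read_noise = 5,
                          lowq_fraction = 0.26,
                          lowq_scale = 0.01,
                          pathologies = c(glioblastoma = 1.00,
                                          metastasis = 1.05,
                                          meningioma = 0.95),
                          seed = 1L) {
  noise <- match.arg(noise)
  cfg <- list(
    n_patients_per_site = as.integer(n_patients_per_site),
    n_locations_per_patient = as.integer(n_locations_per_patient),
    n_repeats = as.integer(n_repeats),
    band_table = as_tibble(band_table),
    amp_jitter_sdlog = amp_jitter_sdlog,
    patient_effect_sd = patient_effect_sd,
    site_gain_amplitude = site_gain_amplitude,
    baseline_amplitude = baseline_amplitude,
    baseline_decay = baseline_decay,
    dark_mean = dark_mean,
    cosmic_rate = cosmic_rate,
    noise = noise,
    read_noise = read_noise,
    lowq_fraction = lowq_fraction,
    lowq_scale = lowq_scale,
    pathologies = pathologies,
    sites = c("site_a", "site_b"),
    axis = factory_axis(),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

required_bands <- function() c(1004, 1299, 1340, 1441, 1659)

validate_cohort_config <- function(cfg) {
  counts <- c(cfg$n_patients_per_site, cfg$n_locations_per_patient,
              cfg$n_repeats)
  if (any(counts < 1L)) abort("all counts must be positive")
  if (cfg$cosmic_rate < 0) abort("cosmic_rate must be >= 0")
  if (cfg$lowq_fraction < 0 || cfg$lowq_fraction > 1) {
    abort("lowq_fraction must lie in [0, 1]")
  }
  bt <- cfg$band_table
  if (!all(c("band", "sigma", "brain", "tumor") %in% names(bt))) {
    abort("band_table needs columns band, sigma, brain, tumor")
  }
  missing <- setdiff(required_bands(), bt$band)
  if (length(missing) > 0) {
    abort(sprintf("band_table omits required band(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (!all(c("brain", "tumor") %in% names(cfg$amp_jitter_sdlog))) {
    abort("amp_jitter_sdlog needs named entries brain and tumor")
  }
  if (cfg$amp_jitter_sdlog[["tumor"]] > cfg$amp_jitter_sdlog[["brain"]]) {
    abort("tumor amplitude variance must not exceed brain variance")
  }
  cfg
}

band_group <- function(band) {
  dplyr::case_when(
    band %in% c(1004, 1340) ~ "protein",
    band %in% c(1299, 1441) ~ "lipid",
    TRUE ~ "amide"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  n_pat <- x$n_patients_per_site * length(x$sites) * length(x$pathologies)
  cat("<cohort_config>\n")
  cat(sprintf("  %d patients (%d per pathology per site), %d locations each, %d repeats\n",
              n_pat, x$n_patients_per_site, x$n_locations_per_patient,
              x$n_repeats))
  cat(sprintf("  noise: %s; cosmic rate %.2f/frame; low-quality fraction %.2f\n",
              x$noise, x$cosmic_rate, x$lowq_fraction))
  cat(sprintf("  bands: %s cm-1\n", paste(x$band_table$band, collapse = ", ")))
  invisible(x)
}
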