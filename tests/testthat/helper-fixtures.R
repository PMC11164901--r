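# --- independent oracles -----------------------------------------------------

# population-sd z-scoring, written independently of the package's snv code
snv_oracle <- function(x) {
  m <- mean(x)
  (x - m) / sqrt(mean((x - m)^2))
}

# QF by direct transcription of its definition
qf_oracle <- function(r) sum(sign(r) * r^2) / length(r)

# closed-form Gaussian mixture evaluation
mixture_oracle <- function(nu, pos, amp, sigma) {
  out <- numeric(length(nu))
  for (k in seq_along(pos)) {
    out <- out + amp[k] * exp(-(nu - pos[k])^2 / (2 * sigma[k]^2))
  }
  out
}

# Monte-Carlo recomputation of the between-class effect size at a band from
# the generator's configured amplitude distributions (iid draws; no use of
# the generator's code path)
effect_size_oracle <- function(cfg, band, n = 4000, seed = 123) {
  withr::with_seed(seed, {
    bt <- cfg$band_table
    nu <- cfg$axis$wavenumber
    keep <- nu >= 800 & nu <= 1750
    j <- which.min(abs(nu[keep] - band))
    grp <- c("1004" = "protein", "1340" = "protein",
             "1299" = "lipid", "1441" = "lipid")[as.character(bt$band)]
    grp[is.na(grp)] <- "amide"
    mid <- (bt$brain + bt$tumor) / 2
    mult <- mean(cfg$pathologies)
    draw_class <- function(cls) {
      replicate(n, {
        pe <- stats::rlnorm(3, 0, cfg$patient_effect_sd)
        names(pe) <- c("protein", "lipid", "amide")
        amp <- (mid + mult * (bt[[cls]] - mid)) * pe[grp] *
          exp(stats::rnorm(nrow(bt), 0, cfg$amp_jitter_sdlog[[cls]]))
        s <- mixture_oracle(nu[keep], bt$band, amp, bt$sigma)
        snv_oracle(s)[j]
      })
    }
    a <- draw_class("tumor")
    b <- draw_class("brain")
    sp <- sqrt(((n - 1) * stats::var(a) + (n - 1) * stats::var(b)) /
                 (2 * n - 2))
    abs(mean(a) - mean(b)) / sp
  })
}

# --- fixture configurations --------------------------------------------------

zero_noise_config <- function(...) {
  cohort_config(
    n_patients_per_site = 1L, n_locations_per_patient = 4L,
    noise = "none", read_noise = 0, cosmic_rate = 0,
    patient_effect_sd = 0, amp_jitter_sdlog = c(brain = 0, tumor = 0),
    site_gain_amplitude = 0, lowq_fraction = 0, seed = 5L, ...
  )
}

small_config <- function(seed = 31L, ...) {
  cohort_config(n_patients_per_site = 2L, n_locations_per_patient = 12L,
                seed = seed, ...)
}

# shared mid-sized processed cohort, built once per test run
.shared <- new.env(parent = emptyenv())

shared_spectra <- function() {
  if (is.null(.shared$spectra)) {
    coh <- generate_cohort(small_config())
    .shared$spectra <- add_quality(preprocess_cohort(coh))
    .shared$cohort <- coh
  }
  .shared$spectra
}

shared_cohort <- function() {
  shared_spectra()
  .shared$cohort
}

# subset a raman_spectra tibble, keeping its axis attributes
take_spectra <- function(spectra, idx) {
  out <- spectra[idx, , drop = FALSE]
  attr(out, "wavenumber") <- attr(spectra, "wavenumber")
  class(out) <- class(spectra)
  out
}

fingerprint_axis <- function() {
  ax <- factory_axis()
  ax$wavenumber[ax$wavenumber >= 800 & ax$wavenumber <= 1750]
}
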