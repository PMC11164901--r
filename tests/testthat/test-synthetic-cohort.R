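test_that("zero-noise acquisitions reproduce the planted band mixture exactly", {
  cfg <- zero_noise_config()
  coh <- generate_cohort(cfg)
  nu <- coh$axis$wavenumber
  for (i in seq_len(nrow(coh$acquisitions))) {
    fr <- coh$acquisitions$frames[[i]]
    expect_equal(max(apply(fr, 2L, function(x) diff(range(x)))), 0)
    recovered <- fr[1L, ] - coh$acquisitions$dark[[i]] -
      coh$truth$baseline[[i]]
    expect_equal(recovered, coh$truth$signal[[i]], tolerance = 1e-12)
  }
  bt <- cfg$band_table
  i_tum <- which(coh$acquisitions$label == "tumor")[1]
  planted <- mixture_oracle(nu, bt$band, bt$tumor *
                              cfg$pathologies[[coh$acquisitions$pathology[i_tum]]] * 0 +
                              {
                                mid <- (bt$brain + bt$tumor) / 2
                                mid + cfg$pathologies[[coh$acquisitions$pathology[i_tum]]] *
                                  (bt$tumor - mid)
                              },
                            bt$sigma)
  expect_equal(coh$truth$signal[[i_tum]], planted, tolerance = 1e-10)
})

test_that("generation is bit-identical under a seed and varies across seeds", {
  cfg <- cohort_config(n_patients_per_site = 1L, n_locations_per_patient = 3L,
                       seed = 9L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c <- generate_cohort(cohort_config(n_patients_per_site = 1L,
                                     n_locations_per_patient = 3L,
                                     seed = 10L))
  expect_false(identical(a$acquisitions$frames[[1]],
                         c$acquisitions$frames[[1]]))
  # structural fields do not depend on the seed
  expect_identical(a$acquisitions$patient_id, c$acquisitions$patient_id)
})

test_that("invalid generator configurations are rejected", {
  expect_error(cohort_config(band_table = default_band_table()[-1, ]),
               "omits required band")
  expect_error(cohort_config(amp_jitter_sdlog = c(brain = 0.1, tumor = 0.3)),
               "variance")
  expect_error(cohort_config(lowq_fraction = 1.4), "lowq_fraction")
  expect_error(cohort_config(cosmic_rate = -1), "cosmic_rate")
  expect_error(cohort_config(n_repeats = 0L), "positive")
})

test_that("patients map to one site and pathology; classes are balanced", {
  coh <- shared_cohort()
  acq <- coh$acquisitions
  map <- unique(acq[, c("patient_id", "site", "pathology")])
  expect_equal(nrow(map), dplyr::n_distinct(acq$patient_id))
  tab <- table(acq$label)
  expect_lte(abs(tab[["tumor"]] - tab[["brain"]]),
             dplyr::n_distinct(acq$patient_id))
  per_pat <- tapply(acq$label, acq$patient_id,
                    function(l) abs(sum(l == "tumor") - sum(l == "brain")))
  expect_lte(max(per_pat), 1L)
})

test_that("class contrast has the configured direction at the five bands", {
  cfg <- cohort_config(n_patients_per_site = 10L, seed = 21L,
                       lowq_fraction = 0)
  coh <- generate_cohort(cfg, frames = FALSE)
  nu <- cfg$axis$wavenumber
  at_band <- function(b) {
    j <- which.min(abs(nu - b))
    vapply(coh$truth$signal, `[[`, numeric(1), j)
  }
  tum <- coh$truth$label == "tumor"
  for (b in c(1004, 1340)) {
    expect_gt(mean(at_band(b)[tum]), mean(at_band(b)[!tum]))
  }
  for (b in c(1299, 1441)) {
    expect_lt(mean(at_band(b)[tum]), mean(at_band(b)[!tum]))
  }
  v <- at_band(1659)
  expect_lt(abs(mean(v[tum]) - mean(v[!tum])) / mean(v), 0.05)
  # tumor amplitudes vary less than brain amplitudes
  expect_lt(sd(log(at_band(1441)[tum])), sd(log(at_band(1441)[!tum])))
})

test_that("per-class means converge to the configured amplitudes", {
  cfg <- cohort_config(n_patients_per_site = 10L, seed = 22L,
                       lowq_fraction = 0)
  coh <- generate_cohort(cfg, frames = FALSE)
  nu <- cfg$axis$wavenumber
  j <- which.min(abs(nu - 1441))
  v <- vapply(coh$truth$signal, `[[`, numeric(1), j)
  bt <- cfg$band_table
  mid <- (bt$brain + bt$tumor) / 2
  lognorm_mean <- exp((cfg$patient_effect_sd^2 +
                         cfg$amp_jitter_sdlog[["brain"]]^2) / 2)
  expected <- mean(vapply(cfg$pathologies,
                          function(m) (mid + m * (bt$brain - mid))[bt$band == 1441],
                          numeric(1))) * lognorm_mean
  x <- v[coh$truth$label == "brain"]
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - expected), 3 * se + 0.01 * expected)
})

test_that("sample effect size at 1441 matches the closed-form oracle", {
  cfg <- cohort_config(n_patients_per_site = 12L, seed = 23L,
                       lowq_fraction = 0)
  coh <- generate_cohort(cfg, frames = FALSE)
  nu <- cfg$axis$wavenumber
  keep <- nu >= 800 & nu <= 1750
  j <- which.min(abs(nu[keep] - 1441))
  v <- vapply(coh$truth$signal, function(s) snv_oracle(s[keep])[j], numeric(1))
  d_gen <- cohens_d(v[coh$truth$label == "tumor"],
                    v[coh$truth$label == "brain"])
  d_oracle <- effect_size_oracle(cfg, 1441, n = 4000)
  expect_lt(abs(d_gen - d_oracle), 0.15)
})

test_that("noiseless calibration references invert the pixel map exactly", {
  cfg <- zero_noise_config()
  refs <- generate_references(cfg)
  coefs <- cfg$axis$coefficients
  y <- refs$wavenumber_reference$counts
  apex_pixels <- refs$wavenumber_reference$pixel[local_maxima(y)[
    y[local_maxima(y)] > 500]]
  expected <- (refs$known_peaks - coefs[["intercept"]]) / coefs[["slope"]]
  expect_equal(length(apex_pixels), length(expected))
  expect_lt(max(abs(sort(apex_pixels) - sort(expected))), 1)
})
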