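test_that("dark subtraction is exact elementwise", {
  dark <- c(5, 10, 15)
  frames <- rbind(dark, dark + 2)
  out <- subtract_dark(frames, dark)
  expect_equal(out[1, ], c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(out[2, ], c(2, 2, 2), ignore_attr = TRUE)
  expect_error(subtract_dark(frames, c(1, 2)), "length")
})

test_that("cosmic-ray removal only touches spiked bins", {
  withr::local_seed(101)
  lambda <- 1000
  frames <- matrix(rpois(20 * 500, lambda), nrow = 20)
  clean <- remove_cosmic_rays(frames, k = 8)
  expect_gt(mean(clean == frames), 0.999)

  spiked <- frames
  spiked[7, 123] <- spiked[7, 123] + 50 * lambda
  fixed <- remove_cosmic_rays(spiked, k = 8)
  med <- median(spiked[, 123])
  expect_lt(abs(fixed[7, 123] - med), 3 * mad(spiked[-7, 123]))
  # all other bins untouched
  expect_equal(fixed[, -123], spiked[, -123])

  const <- matrix(5, nrow = 20, ncol = 10)
  expect_identical(remove_cosmic_rays(const), const)
  two <- matrix(1:10, nrow = 2)
  expect_warning(out <- remove_cosmic_rays(two), "fewer than 3")
  expect_identical(out, two)
})

test_that("repeat averaging reduces noise variance about 20-fold", {
  withr::local_seed(102)
  frames <- matrix(rnorm(20 * 500), nrow = 20)
  m <- average_repeats(frames)
  expect_lt(abs(var(m) * 20 - 1), 0.2)
  one <- rnorm(50)
  expect_equal(average_repeats(matrix(one, nrow = 1)), one)
  same <- matrix(rep(one, each = 20), nrow = 20)
  expect_equal(average_repeats(same), one)
})

test_that("fingerprint truncation keeps the closed interval and 521 bins", {
  ax <- factory_axis()
  sp <- spectrum_tbl(ax$wavenumber, seq_along(ax$wavenumber))
  tr <- truncate_spectrum(sp)
  expect_equal(nrow(tr), 521L)
  expect_equal(min(tr$wavenumber), 800)
  expect_equal(max(tr$wavenumber), 1750)
  inside <- spectrum_tbl(seq(900, 1500, by = 2), 1)
  expect_equal(nrow(truncate_spectrum(inside)), nrow(inside))
  edge <- spectrum_tbl(c(799.99, 800, 1200, 1750, 1750.01), 1:5)
  expect_equal(truncate_spectrum(edge)$wavenumber, c(800, 1200, 1750))
  outside <- spectrum_tbl(c(100, 200), 1:2)
  expect_error(truncate_spectrum(outside), "every spectral bin")
})

test_that("Savitzky-Golay filter is exact on cubics and shrinks noise", {
  x <- seq_len(200)
  cubic <- 2 + 0.5 * x - 0.01 * x^2 + 1e-4 * x^3
  sm <- savgol_smooth(cubic)
  expect_equal(sm[6:195], cubic[6:195], tolerance = 1e-8)
  withr::local_seed(103)
  noise <- rnorm(500)
  expect_lt(var(savgol_smooth(noise)), var(noise))
  expect_equal(savgol_smooth(rep(3, 50)), rep(3, 50))
  expect_error(savgol_smooth(rnorm(5)), "window")
})

test_that("SNV normalization matches the population-sd definition", {
  expect_equal(snv_normalize(c(1, -1)), c(1, -1))
  expect_equal(snv_normalize(c(1, 2, 3)),
               c(-1.22474487, 0, 1.22474487), tolerance = 1e-8)
  withr::local_seed(104)
  for (i in 1:5) {
    z <- snv_normalize(runif(100) * 10 + rnorm(100))
    expect_lt(abs(mean(z)), 1e-9)
    expect_lt(abs(sqrt(mean(z^2)) - 1), 1e-9)
  }
  expect_error(snv_normalize(rep(2, 10)), "zero dispersion")
  df <- snv_normalize(spectrum_tbl(1:3, c(1, 2, 3)))
  expect_identical(attr(df, "stage"), "snv")
})

test_that("the noiseless chain equals the composition of its public stages", {
  cfg <- zero_noise_config(baseline_amplitude = 0)
  coh <- generate_cohort(cfg)
  i <- 1L
  out <- preprocess_acquisition(coh$acquisitions[i, ], coh$references)
  expect_equal(nrow(out), 521L)
  expect_identical(attr(out, "stage"), "snv")
  nu <- coh$axis$wavenumber
  keep <- nu >= 800 & nu <= 1750
  # with no noise, baseline, cosmic rays or response distortion, the chain
  # reduces to bubblefill + smoothing + SNV applied to the planted mixture
  truth <- spectrum_tbl(out$wavenumber, coh$truth$signal[[i]][keep])
  manual <- snv_normalize(savgol_smooth(
    spectrum_tbl(out$wavenumber, bubblefill(truth)$raman)))
  expect_equal(out$intensity, manual$intensity, tolerance = 1e-9)
  # the planted band positions survive as local maxima of the final spectrum
  found <- out$wavenumber[local_maxima(out$intensity)]
  for (b in cfg$band_table$band) {
    expect_lt(min(abs(found - b)), 2)
  }
  expect_gt(cor(out$intensity, snv_oracle(truth$intensity)), 0.85)
})

test_that("preprocessing a cohort is deterministic and 521 bins wide", {
  cfg <- cohort_config(n_patients_per_site = 1L,
                       n_locations_per_patient = 2L, seed = 77L)
  a <- preprocess_cohort(generate_cohort(cfg))
  b <- preprocess_cohort(generate_cohort(cfg))
  expect_identical(a$spectrum, b$spectrum)
  expect_true(all(lengths(a$spectrum) == 521L))
})
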