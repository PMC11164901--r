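test_that("peak fitting recovers planted Gaussians and rejects small bumps", {
  nu <- fingerprint_axis()
  flat <- spectrum_tbl(nu, rep(0, length(nu)), "snv")
  expect_equal(nrow(fit_peaks(flat)), 0L)

  planted <- spectrum_tbl(nu, mixture_oracle(nu, 1004, 2.0, 5), "snv")
  pk <- fit_peaks(planted)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$position - 1004), 2)
  expect_lt(abs(pk$height - 2.0) / 2.0, 0.05)
  expect_lt(abs(pk$width - 2 * sqrt(2 * log(2)) * 5) /
              (2 * sqrt(2 * log(2)) * 5), 0.10)

  small <- spectrum_tbl(nu, mixture_oracle(nu, 1200, 0.05, 5), "snv")
  expect_equal(nrow(fit_peaks(small)), 0L)
})

test_that("peak positions are translation-consistent", {
  nu <- fingerprint_axis()
  base <- mixture_oracle(nu, c(1004, 1441), c(2, 3), c(5, 12))
  p0 <- fit_peaks(spectrum_tbl(nu, base, "snv"))
  p1 <- fit_peaks(spectrum_tbl(nu + 1, base, "snv"))
  expect_equal(p1$position - p0$position, rep(1, nrow(p0)), tolerance = 0.2)
})

test_that("consensus retention follows the 50 percent rule inclusively", {
  mk <- function(ids, pos) {
    tibble::tibble(location_id = sprintf("m%02d", ids), position = pos,
                   height = 1, width = 10)
  }
  # peak near 1004 in 6/10, near 1200 in 4/10, near 1441 in exactly 5/10
  pk <- dplyr::bind_rows(
    mk(1:6, 1004 + runif(6, -1, 1)),
    mk(1:4, 1200 + runif(4, -1, 1)),
    mk(1:5, 1441 + runif(5, -1, 1))
  )
  cons <- consensus_peaks(pk, n_measurements = 10)
  expect_setequal(round(cons$position, -1), c(1000, 1440))
  expect_false(any(abs(cons$position - 1200) < 5))
})

test_that("haemoglobin-region peaks are excluded from the consensus", {
  pk <- tibble::tibble(location_id = sprintf("m%d", 1:8),
                       position = 1550 + runif(8, -1, 1),
                       height = 2, width = 10)
  expect_equal(nrow(consensus_peaks(pk, 8)), 0L)
})

test_that("the feature matrix carries bands minus haemoglobin plus 2 columns per peak", {
  spectra <- shared_spectra()
  pk <- dataset_peaks(take_spectra(spectra, 1:20))
  sub <- take_spectra(spectra, 1:20)
  cons <- consensus_peaks(pk, 20)
  fm <- build_feature_matrix(sub, cons, peaks = pk)
  nu <- attr(spectra, "wavenumber")
  n_band_expected <- sum(nu < 1500 | nu > 1620)
  bands <- grep("^band_", names(fm), value = TRUE)
  expect_equal(length(bands), n_band_expected)
  band_nu <- as.numeric(sub("band_", "", bands))
  expect_false(any(band_nu >= 1500 & band_nu <= 1620))
  expect_equal(sum(startsWith(names(fm), "peak_")), 2L * nrow(cons))
  expect_false(anyNA(fm))
})

test_that("unmatched consensus peaks are imputed with zero height", {
  nu <- fingerprint_axis()
  spectra <- tibble::tibble(
    location_id = c("a", "b"),
    label = c("tumor", "brain"),
    spectrum = list(mixture_oracle(nu, 1004, 2, 5),
                    rep(0, length(nu)))
  )
  attr(spectra, "wavenumber") <- nu
  class(spectra) <- c("raman_spectra", class(spectra))
  pk <- dataset_peaks(spectra)
  cons <- consensus_peaks(pk, 2, config = peak_config(consensus_fraction = 0.5))
  fm <- build_feature_matrix(spectra, cons, peaks = pk)
  hcol <- grep("_height$", names(fm), value = TRUE)
  wcol <- grep("_width$", names(fm), value = TRUE)
  expect_equal(fm[[hcol]][2], 0)
  expect_equal(fm[[wcol]][2], cons$median_width[1])
})

test_that("random-forest selection finds the informative bands", {
  withr::local_seed(501)
  n <- 120
  nu <- fingerprint_axis()
  informative <- c(1004, 1299, 1340, 1441)
  labels <- rep(c("tumor", "brain"), each = n / 2)
  cols <- lapply(nu[seq(1, length(nu), by = 4)], function(v) rnorm(n))
  names(cols) <- band_col_name(nu[seq(1, length(nu), by = 4)])
  for (b in informative) {
    cn <- band_col_name(nu[which.min(abs(nu - b))])
    cols[[cn]] <- rnorm(n) + ifelse(labels == "tumor", 1.5, 0) *
      sign(b %in% c(1004, 1340) - 0.5)
  }
  fm <- dplyr::bind_cols(
    tibble::tibble(location_id = sprintf("m%03d", 1:n),
                   patient_id = sprintf("p%02d", rep(1:12, length.out = n)),
                   label = labels),
    tibble::as_tibble(cols),
    tibble::tibble(peak_1004_height = rnorm(n), peak_1004_width = rnorm(n),
                   peak_1441_height = rnorm(n), peak_1441_width = rnorm(n))
  )
  class(fm) <- c("raman_features", class(fm))
  hits <- 0L
  for (s in 1:20) {
    sel <- attr(select_features(fm, n_band = 10L, n_peak = 2L, seed = s),
                "selected")
    got <- vapply(informative, function(b) {
      any(abs(as.numeric(sub("band_", "", grep("^band_", sel, value = TRUE))) -
                b) <= 2)
    }, logical(1))
    hits <- hits + all(got)
  }
  expect_gte(hits, 19L)

  expect_warning(select_features(fm, n_band = 5000L, n_peak = 2L, seed = 1L),
                 "clipped")
  sel7 <- select_features(fm, n_band = 5L, n_peak = 2L, seed = 1L)
  expect_equal(sum(grepl("^(band|peak)_", names(sel7))), 7L)
})
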