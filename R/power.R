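#' Cohen's d (pooled-standard-deviation effect size)
#'
#' Absolute mean difference divided by the pooled standard deviation,
#' as used to size two-class spectral comparisons at diagnostic bands.
#'
#' @param group_a,group_b numeric vectors (each of length >= 2).
#' @return The effect size d >= 0.
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  stopifnot(na >= 2, nb >= 2)
  sp2 <- ((na - 1) * var(group_a) + (nb - 1) * var(group_b)) / (na + nb - 2)
  if (sp2 == 0) abort("zero pooled standard deviation")
  abs(mean(group_a) - mean(group_b)) / sqrt(sp2)
}

#' Effect size between classes at a diagnostic band
#'
#' Cohen's d of the SNV intensity at the spectral bin nearest to `band`
#' between tumor and non-tumoral brain measurements.
#'
#' @param spectra a `raman_spectra` tibble.
#' @param band Raman shift of interest (cm^-1).
#' @return Cohen's d.
#' @export
band_effect_size <- function(spectra, band) {
  nu <- attr(spectra, "wavenumber")
  j <- which.min(abs(nu - band))
  v <- vapply(spectra$spectrum, `[[`, numeric(1), j)
  cohens_d(v[spectra$label == "tumor"], v[spectra$label == "brain"])
}

two_sample_t_power <- function(n, d, alpha, tails) {
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  if (tails == "two") {
    tc <- qt(1 - alpha / 2, df)
    1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
  } else {
    tc <- qt(1 - alpha, df)
    1 - pt(tc, df, ncp)
  }
}

#' Per-group sample size for a two-sample t-test
#'
#' Smallest n per group such that a two-sample t-test at level `alpha`
#' reaches the target power for effect size `d`, computed by exact
#' noncentral-t iteration from a normal-approximation starting value.
#'
#' @param d Cohen's effect size (> 0).
#' @param alpha type-I error rate.
#' @param power target power (1 - beta).
#' @param tails `"two"` (default) or `"one"`.
#' @return Integer sample size per group (floor 2).
#' @export
power_sample_size <- function(d, alpha = 0.05, power = 0.95,
                              tails = c("two", "one")) {
  tails <- match.arg(tails)
  stopifnot(d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  a <- if (tails == "two") alpha / 2 else alpha
  n <- max(2, ceiling(2 * ((qnorm(1 - a) + qnorm(power)) / d)^2))
  while (n > 2 && two_sample_t_power(n - 1, d, alpha, tails) >= power) {
    n <- n - 1
  }
  while (two_sample_t_power(n, d, alpha, tails) < power) {
    n <- n + 1
  }
  as.integer(n)
}
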