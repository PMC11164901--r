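#' Spectral quality factor (QF)
#'
#' The average signed squared intensity of an SNV-normalized spectrum,
#' `QF = (1/N) sum sgn(r_i) r_i^2`. Because an SNV spectrum has unit
#' population variance, QF is bounded in \[-1, 1\]; pure noise gives QF near
#' 0 while spectra carrying genuine Raman peaks (a few strongly positive
#' bins, many mildly negative ones) give QF > 0. Equivalently
#' `QF = 1 - 2 E^-` where `E^-` is the mean squared negative part.
#'
#' @param spectrum numeric vector of SNV intensities, or a spectrum data
#'   frame at stage `"snv"`.
#' @return The QF value.
#' @export
quality_factor <- function(spectrum) {
  if (is_spectrum_df(spectrum)) {
    stage <- spectrum_stage(spectrum)
    if (!is.null(stage) && !identical(stage, "snv")) {
      abort(sprintf("quality factor requires an snv-stage spectrum, got %s",
                    stage))
    }
    spectrum <- spectrum$intensity
  }
  mean(sign(spectrum) * spectrum^2)
}

#' Add quality records to a spectra table
#'
#' Computes the QF of each spectrum and, when a threshold is given, the
#' pass/fail decision `qf > threshold`.
#'
#' @param spectra a `raman_spectra` tibble.
#' @param threshold optional QF cutoff.
#' @return The input with `qf` (and `passes`) columns added.
#' @export
add_quality <- function(spectra, threshold = NULL) {
  spectra$qf <- vapply(spectra$spectrum, quality_factor, numeric(1))
  if (!is.null(threshold)) spectra$passes <- spectra$qf > threshold
  spectra
}

#' Filter a spectra table by quality factor
#'
#' Retains the spectra with `qf > threshold` (strict), recording the
#' rejection fraction and per-class retained counts as attributes.
#'
#' @param spectra a `raman_spectra` tibble (QF computed on demand).
#' @param threshold QF cutoff.
#' @return Filtered spectra table with attributes `rejection_fraction` and
#'   `retained_by_class`.
#' @export
apply_qf_filter <- function(spectra, threshold) {
  if (!"qf" %in% names(spectra)) spectra <- add_quality(spectra)
  keep <- spectra$qf > threshold
  if (!any(keep)) abort("quality filter rejected every spectrum")
  out <- spectra[keep, , drop = FALSE]
  for (a in c("wavenumber", "calibration")) {
    attr(out, a) <- attr(spectra, a, exact = TRUE)
  }
  class(out) <- class(spectra)
  attr(out, "rejection_fraction") <- mean(!keep)
  attr(out, "retained_by_class") <- table(out$label)
  out
}

#' Select the QF cutoff by ROC analysis under a class-balance constraint
#'
#' For each candidate cutoff, the classification workflow (feature
#' engineering plus a class-weighted linear SVM at fixed default
#' hyperparameters) is evaluated by patient-grouped cross-validation on the
#' retained spectra and the pooled validation AUC is recorded. Among the
#' cutoffs whose retained dataset keeps the minority-class fraction at or
#' above `balance_min`, the cutoff with the best AUC is returned (ties go to
#' the smaller cutoff). If every cutoff violates the balance bound, 0 is
#' returned with a warning.
#'
#' @param spectra a `raman_spectra` tibble with labels.
#' @param candidate_thresholds QF cutoffs to score.
#' @param balance_min minimum retained minority-class fraction.
#' @param n_folds cross-validation folds.
#' @param hyper fixed hyperparameters used during the search
#'   (`n_band`, `n_peak`, `C`).
#' @param seed integer seed for folds and forests.
#' @return List with `threshold` and `candidates` (tibble of cutoff, AUC,
#'   minority fraction, retained count).
#' @export
select_qf_threshold <- function(spectra,
                                candidate_thresholds = seq(0, 0.9, by = 0.1),
                                balance_min = 0.4,
                                n_folds = 5L,
                                hyper = list(n_band = 15L, n_peak = 5L, C = 1),
                                seed = 1L) {
  if (!"qf" %in% names(spectra)) spectra <- add_quality(spectra)
  all_peaks <- dataset_peaks(spectra)
  cand <- sort(candidate_thresholds)
  rows <- purrr::map_dfr(cand, function(th) {
    keep <- spectra$qf > th
    retained <- spectra[keep, , drop = FALSE]
    for (a in c("wavenumber", "calibration")) {
      attr(retained, a) <- attr(spectra, a, exact = TRUE)
    }
    class(retained) <- class(spectra)
    tab <- table(factor(retained$label, levels = c("brain", "tumor")))
    minority <- if (sum(tab) == 0) 0 else min(tab) / sum(tab)
    auc <- NA_real_
    if (all(tab >= n_folds) && dplyr::n_distinct(retained$patient_id) >= n_folds) {
      pk <- all_peaks[all_peaks$location_id %in% retained$location_id, ]
      auc <- tryCatch(
        workflow_cv_auc(retained, peaks = pk, hyper = hyper,
                        n_folds = n_folds, seed = seed),
        error = function(e) NA_real_
      )
    }
    tibble(threshold = th, auc = auc, minority_fraction = minority,
           n_retained = sum(keep))
  })
  ok <- !is.na(rows$auc) & rows$minority_fraction >= balance_min
  if (!any(ok)) {
    warn("no candidate cutoff satisfies the class-balance bound; returning 0")
    return(list(threshold = 0, candidates = rows))
  }
  best <- rows[ok, ]
  best <- best[order(-best$auc, best$threshold), ]
  list(threshold = best$threshold[[1]], candidates = rows)
}
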