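meta_columns <- function(x) {
  intersect(c("location_id", "patient_id", "site", "pathology", "label",
              "lowq", "qf", "passes"), names(x))
}

feature_columns <- function(x) {
  grep("^(band|peak)_", names(x), value = TRUE)
}

band_col_name <- function(wavenumber) sprintf("band_%.2f", wavenumber)

#' Build the feature matrix for classification
#'
#' Per measurement: the SNV intensity of every retained spectral band
#' (columns labelled with their Raman shift, with the haemoglobin region
#' \[1500, 1620\] cm^-1 removed) plus, for each consensus peak, the height
#' and width of the matched Gaussian fit (two columns per consensus peak).
#' Measurements with no fitted peak within the matching tolerance of a
#' consensus position are imputed with height 0 and the consensus median
#' width.
#'
#' @param spectra a `raman_spectra` tibble.
#' @param consensus consensus peaks from [consensus_peaks()].
#' @param peaks per-measurement fitted peaks ([dataset_peaks()]); computed
#'   on demand when `NULL`.
#' @param config a [peak_config()].
#' @return A `raman_features` tibble: metadata columns plus `band_*` and
#'   `peak_*` feature columns; `attr(, "feature_info")` maps columns to
#'   their type and wavenumber.
#' @export
build_feature_matrix <- function(spectra, consensus, peaks = NULL,
                                 config = peak_config()) {
  nu <- attr(spectra, "wavenumber")
  keep_band <- nu < 1500 | nu > 1620
  bands <- do.call(rbind, spectra$spectrum)[, keep_band, drop = FALSE]
  colnames(bands) <- band_col_name(nu[keep_band])

  if (is.null(peaks)) peaks <- dataset_peaks(spectra, config)
  peak_cols <- NULL
  if (nrow(consensus) > 0L) {
    pk_by_loc <- if (nrow(peaks) > 0L) split(peaks, peaks$location_id) else
      list()
    peak_cols <- purrr::map(seq_len(nrow(consensus)), function(k) {
      pos <- consensus$position[k]
      hw <- t(vapply(spectra$location_id, function(id) {
        pk <- pk_by_loc[[id]]
        if (!is.null(pk) && nrow(pk) > 0L) {
          d <- abs(pk$position - pos)
          j <- which.min(d)
          if (d[j] <= config$position_tolerance) {
            return(c(pk$height[j], pk$width[j]))
          }
        }
        c(0, consensus$median_width[k])  # imputation for unmatched peaks
      }, numeric(2)))
      colnames(hw) <- sprintf("peak_%d_%s", round(pos), c("height", "width"))
      hw
    })
    peak_cols <- do.call(cbind, peak_cols)
  }

  out <- dplyr::bind_cols(
    spectra[, meta_columns(spectra)],
    as_tibble(bands),
    if (!is.null(peak_cols)) as_tibble(peak_cols)
  )
  info <- tibble(
    column = c(colnames(bands), colnames(peak_cols)),
    type = c(rep("band", ncol(bands)),
             rep("peak", length(colnames(peak_cols)))),
    wavenumber = c(nu[keep_band],
                   if (!is.null(peak_cols))
                     rep(consensus$position, each = 2))
  )
  attr(out, "feature_info") <- info
  attr(out, "consensus") <- consensus
  class(out) <- c("raman_features", class(out))
  out
}

# impurity-importance ranking of band and peak columns (200-tree forest)
rank_features <- function(features, seed = 1L, num_trees = 200L) {
  cols <- feature_columns(features)
  x <- as.data.frame(features[, cols, drop = FALSE])
  y <- factor(features$label)
  fit <- ranger::ranger(x = x, y = y, num.trees = num_trees,
                        importance = "impurity", seed = seed,
                        num.threads = 1L)
  imp <- sort(fit$variable.importance, decreasing = TRUE)
  list(
    band = names(imp)[startsWith(names(imp), "band_")],
    peak = names(imp)[startsWith(names(imp), "peak_")],
    importance = imp
  )
}

#' Reduce the feature matrix by random-forest importance
#'
#' Fits a 200-tree random forest on the supplied (training) measurements,
#' ranks band and peak columns separately by impurity importance, and keeps
#' the top `n_band` band columns and top `n_peak` peak columns. Quotas
#' exceeding the available columns are clipped with a warning. Deterministic
#' for a fixed seed.
#'
#' @param features a `raman_features` tibble (training portion only; fitting
#'   this on data containing holdout measurements would leak).
#' @param n_band number of band columns to keep.
#' @param n_peak number of peak columns to keep.
#' @param seed forest seed.
#' @return The reduced tibble (metadata plus selected features);
#'   `attr(, "selected")` lists the kept columns in rank order.
#' @export
select_features <- function(features, n_band = 15L, n_peak = 5L, seed = 1L) {
  ranks <- rank_features(features, seed = seed)
  if (n_band > length(ranks$band) || n_peak > length(ranks$peak)) {
    warn(sprintf("feature quota clipped to available columns (%d band, %d peak)",
                 length(ranks$band), length(ranks$peak)))
  }
  sel <- c(utils::head(ranks$band, n_band), utils::head(ranks$peak, n_peak))
  out <- features[, c(meta_columns(features), sel)]
  attr(out, "selected") <- sel
  class(out) <- class(features)
  out
}
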