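#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon geom_abline
#'   geom_point labs theme_minimal
#' @export
ggplot2::autoplot

#' Mean class spectra with variability band
#'
#' Mean SNV spectrum per class with a +/- 1 sd ribbon, the standard summary
#' view for comparing tumor and non-tumoral brain fingerprints.
#'
#' @param spectra a `raman_spectra` tibble.
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra) {
  long <- spectra_long(spectra)
  summ <- long |>
    dplyr::group_by(.data$label, .data$wavenumber) |>
    dplyr::summarise(mean = mean(.data$intensity),
                     sd = sd(.data$intensity), .groups = "drop")
  ggplot(summ, aes(x = .data$wavenumber, y = .data$mean,
                   colour = .data$label, fill = .data$label)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sd,
                    ymax = .data$mean + .data$sd),
                alpha = 0.2, colour = NA) +
    geom_line() +
    labs(x = "Raman shift (cm⁻¹)", y = "SNV intensity",
         colour = NULL, fill = NULL) +
    theme_minimal()
}

#' @export
autoplot.raman_spectra <- function(object, ...) plot_spectra(object)

#' @export
autoplot.raman_eval <- function(object, ...) {
  ggplot(object$roc, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line() +
    labs(x = "False positive rate", y = "True positive rate",
         title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    theme_minimal()
}

#' @export
autoplot.bubblefill_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("wavenumber", "intensity", "baseline", "raman")],
    cols = c("intensity", "baseline", "raman"),
    names_to = "component", values_to = "value"
  )
  ggplot(long, aes(x = .data$wavenumber, y = .data$value,
                   colour = .data$component)) +
    geom_line() +
    labs(x = "Raman shift (cm⁻¹)", y = "Intensity (counts)",
         colour = NULL) +
    theme_minimal()
}

#' Quality-factor distribution by class
#'
#' @param spectra a quality-scored `raman_spectra` tibble (see
#'   [add_quality()]).
#' @param threshold optional cutoff drawn as a vertical line.
#' @return A ggplot object.
#' @export
plot_quality <- function(spectra, threshold = NULL) {
  if (!"qf" %in% names(spectra)) spectra <- add_quality(spectra)
  p <- ggplot(spectra, aes(x = .data$qf, fill = .data$label)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 40) +
    labs(x = "Quality factor", y = "Measurements", fill = NULL) +
    theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = "dashed")
  }
  p
}
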