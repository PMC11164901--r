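#' Default hyperparameter grid
#'
#' Regularization `C` spans 0.01 to 5; band quotas 5 to 25; peak quotas 2 to
#' 20, so the total feature count N ranges from 7 to 45.
#'
#' @return List with numeric vectors `C`, `n_band`, `n_peak`.
#' @export
default_grid <- function() {
  list(C = c(0.01, 0.05, 0.1, 0.5, 1, 2, 5),
       n_band = c(5L, 10L, 15L, 20L, 25L),
       n_peak = c(2L, 5L, 10L, 15L, 20L))
}

class_levels <- function() c("brain", "tumor")

# class weights reflecting the class ratio (inverse class frequencies)
ratio_class_weights <- function(y) {
  tab <- table(y)
  w <- sum(tab) / (length(tab) * tab)
  setNames(as.numeric(w), names(tab))
}

svm_fit <- function(x, y, C) {
  y <- factor(y, levels = class_levels())
  e1071::svm(x = as.matrix(x), y = y, kernel = "linear", cost = C,
             class.weights = ratio_class_weights(y), scale = TRUE)
}

# decision scores oriented so larger = more tumor-like
decision_scores <- function(fit, x) {
  pr <- predict(fit, as.matrix(x), decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  s <- as.numeric(dv[, 1L])
  if (!startsWith(colnames(dv)[1L], "tumor")) s <- -s
  s
}

count_errors <- function(scores, labels, threshold = 0) {
  pred <- ifelse(scores > threshold, "tumor", "brain")
  sum(pred != as.character(labels))
}

#' Hyperparameter grid search with patient-grouped five-fold CV
#'
#' For every combination of band quota, peak quota and SVM cost, the
#' training data are split into five patient-grouped folds; in each fold the
#' feature ranking (200-tree random forest) is fit on the four training
#' folds only, the class-weighted linear SVM is trained on the reduced
#' features, and false positives plus false negatives are counted on the
#' validation fold. The combination minimizing the total error over the five
#' folds wins; ties go to the smaller total feature count N, then the
#' smaller C. Quotas exceeding the available columns are clipped and
#' duplicate effective combinations dropped.
#'
#' @param features training `raman_features` tibble (with `label` and
#'   `patient_id`).
#' @param grid hyperparameter grid, see [default_grid()].
#' @param n_folds number of folds.
#' @param seed integer seed (folds and forests).
#' @return List with `best` (n_band, n_peak, C, N, cv_errors) and `table`
#'   (tibble of all combinations with their summed CV errors).
#' @export
grid_search_cv <- function(features, grid = default_grid(), n_folds = 5L,
                           seed = 1L) {
  labels <- factor(features$label, levels = class_levels())
  n_band_avail <- sum(startsWith(names(features), "band_"))
  n_peak_avail <- sum(startsWith(names(features), "peak_"))
  combos <- tidyr::expand_grid(
    n_band = unique(pmin(as.integer(grid$n_band), n_band_avail)),
    n_peak = unique(pmin(as.integer(grid$n_peak), n_peak_avail)),
    C = grid$C
  )

  run_folds <- function(fold_seed) {
    folds <- make_patient_folds(features, n_folds, fold_seed)
    fold_of <- folds[features$patient_id]
    err <- matrix(0, nrow = nrow(combos), ncol = n_folds)
    for (f in seq_len(n_folds)) {
      tr <- which(fold_of != f)
      va <- which(fold_of == f)
      if (length(va) == 0L ||
          dplyr::n_distinct(labels[tr]) < 2L ||
          dplyr::n_distinct(labels[va]) < 2L) {
        return(NULL)  # degenerate fold
      }
      ranks <- rank_features(features[tr, ],
                             seed = derive_seed(seed, 100L + f))
      quotas <- dplyr::distinct(combos[, c("n_band", "n_peak")])
      for (qi in seq_len(nrow(quotas))) {
        sel <- c(utils::head(ranks$band, quotas$n_band[qi]),
                 utils::head(ranks$peak, quotas$n_peak[qi]))
        xtr <- features[tr, sel, drop = FALSE]
        xva <- features[va, sel, drop = FALSE]
        rows <- which(combos$n_band == quotas$n_band[qi] &
                        combos$n_peak == quotas$n_peak[qi])
        for (r in rows) {
          fit <- svm_fit(xtr, labels[tr], combos$C[r])
          err[r, f] <- count_errors(decision_scores(fit, xva), labels[va])
        }
      }
    }
    err
  }

  err <- run_folds(seed)
  if (is.null(err)) {
    err <- run_folds(derive_seed(seed, 1L))  # re-draw folds once
    if (is.null(err)) abort("degenerate cross-validation fold (single class)")
  }
  tab <- dplyr::mutate(combos, N = .data$n_band + .data$n_peak,
                       cv_errors = rowSums(err))
  ord <- order(tab$cv_errors, tab$N, tab$C)
  best <- as.list(tab[ord[1L], ])
  list(best = best, table = tab)
}

#' Train the final classifier on the full training set
#'
#' Re-runs feature selection (random-forest ranking at the chosen quotas) on
#' the complete training set and fits the class-weighted linear SVM at the
#' chosen cost. Refitting with the same seed reproduces identical weights.
#'
#' @param features training `raman_features` tibble.
#' @param params chosen hyperparameters (list with `n_band`, `n_peak`, `C`).
#' @param seed integer seed for the selection forest.
#' @param qf_threshold QF cutoff recorded with the model (metadata).
#' @return A `raman_svm` model object with elements `fit`, `selected`,
#'   `weights` (length-N linear weight vector), `bias`, `class_weights`,
#'   `params`, `qf_threshold`.
#' @export
train_final <- function(features, params, seed = 1L, qf_threshold = NA_real_) {
  ranks <- rank_features(features, seed = derive_seed(seed, 200L))
  sel <- c(utils::head(ranks$band, params$n_band),
           utils::head(ranks$peak, params$n_peak))
  labels <- factor(features$label, levels = class_levels())
  fit <- svm_fit(features[, sel, drop = FALSE], labels, params$C)
  w <- drop(crossprod(fit$coefs, fit$SV))
  if (!startsWith(colnames(attr(predict(fit, fit$SV[1, , drop = FALSE],
                                        decision.values = TRUE),
                                "decision.values"))[1L], "tumor")) {
    w <- -w
  }
  structure(
    list(fit = fit, selected = sel, weights = setNames(as.numeric(w), sel),
         bias = -fit$rho, class_weights = ratio_class_weights(labels),
         params = params, qf_threshold = qf_threshold,
         n_train = nrow(features)),
    class = "raman_svm"
  )
}

#' Decision scores of a trained model
#'
#' @param object a `raman_svm`.
#' @param newdata a `raman_features` tibble containing the model's selected
#'   columns.
#' @param ... unused.
#' @return Tibble with `location_id` (when present), `label` (when
#'   present), `score` (larger = more tumor-like) and `predicted` at the
#'   default score threshold 0.
#' @export
predict.raman_svm <- function(object, newdata, ...) {
  s <- decision_scores(object$fit, newdata[, object$selected, drop = FALSE])
  out <- tibble(score = s,
                predicted = ifelse(s > 0, "tumor", "brain"))
  if ("label" %in% names(newdata)) {
    out <- dplyr::bind_cols(tibble(label = newdata$label), out)
  }
  if ("location_id" %in% names(newdata)) {
    out <- dplyr::bind_cols(tibble(location_id = newdata$location_id), out)
  }
  out
}

#' @export
print.raman_svm <- function(x, ...) {
  cat("<raman_svm>\n")
  cat(sprintf("  linear SVM, C = %g, N = %d features (%d band + %d peak)\n",
              x$params$C, length(x$selected), x$params$n_band,
              x$params$n_peak))
  cat(sprintf("  trained on %d measurements; class weights %s\n", x$n_train,
              paste(sprintf("%s=%.2f", names(x$class_weights),
                            x$class_weights), collapse = ", ")))
  invisible(x)
}
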