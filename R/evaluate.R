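#' ROC points from decision scores
#'
#' Sweeps the decision threshold over the observed scores (tumor = positive
#' class) and returns the ROC operating points, collapsing tied scores.
#'
#' @param scores numeric decision scores, larger = more tumor-like.
#' @param labels class labels (`"brain"`/`"tumor"`).
#' @return Tibble with `threshold`, `tp`, `fp`, `tn`, `fn`, `tpr`, `fpr`,
#'   ordered from the strictest to the most permissive threshold.
#' @export
roc_points <- function(scores, labels) {
  labels <- factor(labels, levels = class_levels())
  pos <- labels == "tumor"
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  keep <- c(s[-length(s)] != s[-1L], TRUE)  # last index of each tied block
  tp <- c(0L, cumsum(p)[keep])
  fp <- c(0L, cumsum(!p)[keep])
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  tibble(
    threshold = c(Inf, s[keep]),
    tp = tp, fp = fp, tn = n_neg - fp, fn = n_pos - tp,
    tpr = tp / n_pos, fpr = fp / n_neg
  )
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Evaluate a trained model on the holdout set
#'
#' Computes the ROC curve of the model's decision scores on the
#' patient-disjoint holdout measurements, the trapezoidal AUC, and accuracy,
#' sensitivity and specificity at the operating point that minimizes false
#' positives plus false negatives (ties resolved towards higher
#' sensitivity).
#'
#' @param model a `raman_svm`.
#' @param holdout holdout `raman_features` tibble (must contain both
#'   classes).
#' @return A `raman_eval` object: `auc`, `accuracy`, `sensitivity`,
#'   `specificity`, `roc` (tibble), `confusion` (counts at the operating
#'   point), `operating_threshold`, `n`.
#' @export
evaluate_holdout <- function(model, holdout) {
  scores <- decision_scores(model$fit,
                            holdout[, model$selected, drop = FALSE])
  evaluate_scores(scores, holdout$label)
}

#' Evaluate raw decision scores against labels
#'
#' Same ROC analysis as [evaluate_holdout()] but starting from
#' already-computed scores (useful for pooled cross-validation predictions
#' and negative controls).
#'
#' @param scores numeric decision scores.
#' @param labels class labels (`"brain"`/`"tumor"`, both present).
#' @return A `raman_eval` object.
#' @export
evaluate_scores <- function(scores, labels) {
  labels <- factor(labels, levels = class_levels())
  if (dplyr::n_distinct(labels) < 2L) {
    abort("evaluation requires both classes in the holdout set")
  }
  roc <- roc_points(scores, labels)
  auc <- trapezoid_auc(roc$fpr, roc$tpr)
  errs <- roc$fp + roc$fn
  cand <- which(errs == min(errs))
  op <- cand[which.max(roc$tpr[cand])]  # ties -> higher sensitivity
  sens <- roc$tp[op] / (roc$tp[op] + roc$fn[op])
  spec <- roc$tn[op] / (roc$tn[op] + roc$fp[op])
  acc <- (roc$tp[op] + roc$tn[op]) / length(labels)
  structure(
    list(auc = auc, accuracy = acc, sensitivity = sens, specificity = spec,
         roc = roc,
         confusion = tibble(tp = roc$tp[op], fp = roc$fp[op],
                            tn = roc$tn[op], fn = roc$fn[op]),
         operating_threshold = roc$threshold[op], n = length(labels)),
    class = "raman_eval"
  )
}

#' @export
print.raman_eval <- function(x, ...) {
  cat("<raman_eval>\n")
  cat(sprintf("  AUC %.3f | accuracy %.3f | sensitivity %.3f | specificity %.3f (n = %d)\n",
              x$auc, x$accuracy, x$sensitivity, x$specificity, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.raman_eval <- function(x, ...) x$roc

#' @export
glance.raman_eval <- function(x, ...) {
  tibble(auc = x$auc, accuracy = x$accuracy, sensitivity = x$sensitivity,
         specificity = x$specificity,
         operating_threshold = x$operating_threshold, n = x$n)
}

#' @export
tidy.raman_svm <- function(x, ...) {
  tibble(term = names(x$weights), estimate = as.numeric(x$weights),
         type = ifelse(startsWith(names(x$weights), "band_"), "band", "peak"))
}

#' @export
glance.raman_svm <- function(x, ...) {
  tibble(C = x$params$C, n_band = x$params$n_band, n_peak = x$params$n_peak,
         n_features = length(x$selected), n_support = nrow(x$fit$SV),
         n_train = x$n_train, qf_threshold = x$qf_threshold)
}

# patient-grouped CV AUC of the standard workflow at fixed hyperparameters
# (used by the QF threshold search and as a negative control). Decision
# scores from different folds are not on a common scale (each fold fits its
# own feature set), so the AUC is computed per validation fold and averaged
# rather than pooled.
workflow_cv_auc <- function(spectra, peaks = NULL,
                            hyper = list(n_band = 15L, n_peak = 5L, C = 1),
                            n_folds = 5L, seed = 1L,
                            permute_labels = FALSE) {
  if (is.null(peaks)) peaks <- dataset_peaks(spectra)
  cons <- consensus_peaks(peaks, nrow(spectra))
  features <- build_feature_matrix(spectra, cons, peaks = peaks)
  if (permute_labels) {
    features$label <- withr::with_seed(derive_seed(seed, 77L),
                                       sample(features$label))
  }
  folds <- make_patient_folds(features, n_folds, seed)
  fold_of <- folds[features$patient_id]
  labels <- factor(features$label, levels = class_levels())
  aucs <- c()
  for (f in seq_len(n_folds)) {
    tr <- which(fold_of != f)
    va <- which(fold_of == f)
    if (length(va) == 0L || dplyr::n_distinct(labels[va]) < 2L) next
    if (dplyr::n_distinct(labels[tr]) < 2L) {
      abort("degenerate fold during workflow cross-validation")
    }
    ranks <- rank_features(features[tr, ], seed = derive_seed(seed, 300L + f))
    sel <- c(utils::head(ranks$band, hyper$n_band),
             utils::head(ranks$peak, hyper$n_peak))
    fit <- svm_fit(features[tr, sel, drop = FALSE], labels[tr], hyper$C)
    scores <- decision_scores(fit, features[va, sel, drop = FALSE])
    roc <- roc_points(scores, labels[va])
    aucs <- c(aucs, trapezoid_auc(roc$fpr, roc$tpr))
  }
  if (length(aucs) == 0L) abort("no usable validation fold")
  mean(aucs)
}
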