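preset_qf_thresholds <- function() {
  c(glioblastoma = 0.5, metastasis = 0.5, meningioma = 0.3)
}

# subset a raman_spectra tibble preserving its axis attributes
subset_spectra <- function(spectra, idx) {
  out <- spectra[idx, , drop = FALSE]
  for (a in c("wavenumber", "calibration")) {
    attr(out, a) <- attr(spectra, a, exact = TRUE)
  }
  class(out) <- class(spectra)
  out
}

#' Pipeline run configuration
#'
#' Bundles every setting of an end-to-end run: the synthetic cohort, the
#' quality-factor policy, the models to train, the hyperparameter grid and
#' the seed (taken from the cohort config).
#'
#' @param cohort a [cohort_config()].
#' @param models model targets: any of `"glioblastoma"`, `"metastasis"`,
#'   `"meningioma"`, `"all"`.
#' @param qf quality policy: `"preset"` (0.5 for glioblastoma and metastasis
#'   runs, 0.3 for meningioma; the all-tumor model applies each patient's
#'   pathology preset), `"none"`, `"auto"` (ROC-guided search per model), or
#'   a single numeric cutoff.
#' @param grid hyperparameter grid ([default_grid()]).
#' @param holdout_fraction measurement fraction held out by patient.
#' @param min_bubble_width baseline-removal minimum bubble diameter (cm^-1).
#' @param n_folds cross-validation folds.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            models = c("glioblastoma", "metastasis",
                                       "meningioma", "all"),
                            qf = "preset",
                            grid = default_grid(),
                            holdout_fraction = 0.2,
                            min_bubble_width = 60,
                            n_folds = 5L) {
  structure(list(cohort = cohort, models = models, qf = qf, grid = grid,
                 holdout_fraction = holdout_fraction,
                 min_bubble_width = min_bubble_width,
                 n_folds = as.integer(n_folds), seed = cohort$seed),
            class = "pipeline_config")
}

stage_run <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[%s] %s", stage, conditionMessage(e)))
  })
}

#' Run the full pipeline: simulate, preprocess, filter, train, evaluate
#'
#' Executes every stage in order - cohort simulation, nine-step spectral
#' preprocessing, quality scoring and filtering, peak-feature engineering
#' with training-set consensus, patient-grouped 80/20 split, (N, C) grid
#' search with five-fold patient-grouped cross-validation, final
#' class-weighted linear-SVM training, and holdout ROC evaluation - for each
#' requested model. Every stochastic stage consumes a seed derived from the
#' config seed, so rerunning with the same config reproduces the reports
#' exactly; the manifest records the config hash, seed and per-stage
#' summaries.
#'
#' @param config a [pipeline_config()].
#' @return A `raman_run` list: `reports` (per-model tibble of holdout
#'   metrics), `evals` (named `raman_eval` objects), `models` (named
#'   `raman_svm` objects), `spectra` (quality-scored spectra table),
#'   `manifest`.
#' @export
run_raman_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  cohort <- stage_run("simulate", generate_cohort(config$cohort))
  spectra <- stage_run("preprocess",
                       preprocess_cohort(cohort, config$min_bubble_width))
  spectra <- stage_run("qc", add_quality(spectra))
  peaks <- stage_run("features", dataset_peaks(spectra))

  evals <- list()
  models <- list()
  model_meta <- list()
  for (i in seq_along(config$models)) {
    m <- config$models[[i]]
    sub_idx <- if (m == "all") seq_len(nrow(spectra)) else
      which(spectra$pathology == m)
    if (length(sub_idx) == 0L) {
      abort(sprintf("[qc] no measurements for model %s", m))
    }
    sub <- subset_spectra(spectra, sub_idx)

    th <- stage_run("qc", {
      if (identical(config$qf, "none")) {
        rep(-Inf, nrow(sub))
      } else if (is.numeric(config$qf)) {
        rep(config$qf, nrow(sub))
      } else if (identical(config$qf, "auto")) {
        rep(select_qf_threshold(sub, seed = derive_seed(seed, 40L + i)
        )$threshold, nrow(sub))
      } else {
        if (m == "all") unname(preset_qf_thresholds()[sub$pathology]) else
          rep(preset_qf_thresholds()[[m]], nrow(sub))
      }
    })
    keep <- sub$qf > th
    if (!any(keep)) abort(sprintf("[qc] quality filter emptied model %s", m))
    retained <- subset_spectra(sub, which(keep))

    plan <- stage_run("split",
                      split_train_holdout(retained, config$holdout_fraction,
                                          seed = derive_seed(seed, 20L + i)))
    tr_idx <- which(retained$patient_id %in% plan$training_patients)
    ho_idx <- which(retained$patient_id %in% plan$holdout_patients)
    train_sp <- subset_spectra(retained, tr_idx)
    hold_sp <- subset_spectra(retained, ho_idx)

    fe <- stage_run("features", {
      pk_train <- peaks[peaks$location_id %in% train_sp$location_id, ]
      pk_hold <- peaks[peaks$location_id %in% hold_sp$location_id, ]
      cons <- consensus_peaks(pk_train, nrow(train_sp))
      list(train = build_feature_matrix(train_sp, cons, peaks = pk_train),
           hold = build_feature_matrix(hold_sp, cons, peaks = pk_hold),
           consensus = cons)
    })

    gs <- stage_run("train",
                    grid_search_cv(fe$train, config$grid, config$n_folds,
                                   seed = derive_seed(seed, 30L + i)))
    model <- stage_run("train",
                       train_final(fe$train, gs$best,
                                   seed = derive_seed(seed, 30L + i),
                                   qf_threshold = th[[1]]))
    ev <- stage_run("evaluate", evaluate_holdout(model, fe$hold))

    evals[[m]] <- ev
    models[[m]] <- model
    model_meta[[m]] <- list(
      qf_threshold = if (identical(config$qf, "preset") && m == "all")
        "per-pathology preset" else th[[1]],
      n_retained = nrow(retained), n_rejected = sum(!keep),
      n_train = nrow(fe$train), n_holdout = nrow(fe$hold),
      consensus_positions = round(fe$consensus$position, 1),
      best = gs$best[c("n_band", "n_peak", "C", "N", "cv_errors")],
      split = plan$summary
    )
  }

  reports <- purrr::map_dfr(names(evals), function(m) {
    dplyr::bind_cols(tibble(model = m), glance(evals[[m]]))
  })
  manifest <- list(
    config_hash = rlang::hash(config),
    seed = seed,
    n_locations = nrow(spectra),
    n_patients = dplyr::n_distinct(spectra$patient_id),
    models = model_meta
  )
  structure(list(reports = reports, evals = evals, models = models,
                 spectra = spectra, manifest = manifest, config = config),
            class = "raman_run")
}

#' @export
print.raman_run <- function(x, ...) {
  cat("<raman_run>\n")
  print(x$reports)
  invisible(x)
}
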