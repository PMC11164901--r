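#' Patient-grouped train/holdout split
#'
#' Assigns whole patients to the holdout set so that no patient contributes
#' measurements to both sides, targeting `holdout_fraction` of the
#' measurements within each site (so the holdout has approximately the same
#' site mix as the training set). Assignment is greedy over a seeded random
#' patient order: a patient is added to the holdout while that moves the
#' held-out measurement count closer to the site target. Deterministic per
#' seed.
#'
#' @param data tibble with one row per measurement and columns `patient_id`
#'   and `site`.
#' @param holdout_fraction target fraction of measurements held out.
#' @param seed integer seed.
#' @return A `split_plan`: list with `training_patients`,
#'   `holdout_patients` and a per-site `summary` tibble.
#' @export
split_train_holdout <- function(data, holdout_fraction = 0.2, seed = 1L) {
  stopifnot(all(c("patient_id", "site") %in% names(data)))
  if (dplyr::n_distinct(data$patient_id) < 2L) {
    abort("split requires at least 2 patients")
  }
  counts <- data |>
    dplyr::count(.data$site, .data$patient_id, name = "n")
  holdout <- withr::with_seed(derive_seed(seed, 11L), {
    unlist(lapply(split(counts, counts$site), function(sc) {
      sc <- sc[sample.int(nrow(sc)), ]
      target <- holdout_fraction * sum(sc$n)
      cur <- 0
      take <- logical(nrow(sc))
      for (i in seq_len(nrow(sc))) {
        if (abs(cur + sc$n[i] - target) < abs(cur - target)) {
          take[i] <- TRUE
          cur <- cur + sc$n[i]
        }
      }
      if (!any(take) && nrow(sc) > 1L) take[which.min(sc$n)] <- TRUE
      if (all(take)) take[which.max(sc$n)] <- FALSE
      sc$patient_id[take]
    }), use.names = FALSE)
  })
  training <- setdiff(unique(data$patient_id), holdout)
  if (length(holdout) == 0L || length(training) == 0L) {
    warn("degenerate split: one side is empty; best-effort assignment kept")
  }
  summary <- counts |>
    dplyr::mutate(set = ifelse(.data$patient_id %in% holdout,
                               "holdout", "training")) |>
    dplyr::group_by(.data$site, .data$set) |>
    dplyr::summarise(patients = dplyr::n(), measurements = sum(.data$n),
                     .groups = "drop")
  structure(list(training_patients = training, holdout_patients = holdout,
                 summary = summary),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan>\n")
  cat(sprintf("  training: %d patients; holdout: %d patients\n",
              length(x$training_patients), length(x$holdout_patients)))
  print(x$summary)
  invisible(x)
}

# patient-grouped fold assignment balancing measurement counts
make_patient_folds <- function(data, n_folds = 5L, seed = 1L) {
  counts <- data |>
    dplyr::count(.data$patient_id, name = "n")
  withr::with_seed(derive_seed(seed, 12L), {
    counts <- counts[sample.int(nrow(counts)), ]
    counts <- counts[order(-counts$n), ]
    totals <- numeric(n_folds)
    fold <- integer(nrow(counts))
    for (i in seq_len(nrow(counts))) {
      f <- which.min(totals)
      fold[i] <- f
      totals[f] <- totals[f] + counts$n[i]
    }
    setNames(fold, counts$patient_id)
  })
}
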