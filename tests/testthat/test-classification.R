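fake_features <- function(n = 100, n_informative = 4, sep = 3, seed = 601,
                          n_patients = 10) {
  withr::with_seed(seed, {
    labels <- rep(c("tumor", "brain"), each = n / 2)
    x <- matrix(rnorm(n * 20), nrow = n)
    x[, seq_len(n_informative)] <- x[, seq_len(n_informative)] +
      sep * (labels == "tumor")
    colnames(x) <- c(sprintf("band_%d.00", 1000 + seq_len(15)),
                     "peak_1004_height", "peak_1004_width",
                     "peak_1441_height", "peak_1441_width",
                     "peak_1659_height")
    fm <- dplyr::bind_cols(
      tibble::tibble(location_id = sprintf("m%03d", seq_len(n)),
                     patient_id = sample(sprintf("p%02d", seq_len(n_patients)),
                                         n, replace = TRUE),
                     site = "site_a",
                     label = labels),
      tibble::as_tibble(x)
    )
    class(fm) <- c("raman_features", class(fm))
    fm
  })
}

test_that("patient-grouped splits are disjoint and hit the target fraction", {
  data <- tibble::tibble(
    patient_id = rep(sprintf("p%02d", 1:10), each = 10),
    site = "site_a"
  )
  plan <- split_train_holdout(data, 0.2, seed = 1L)
  expect_length(plan$holdout_patients, 2L)
  expect_length(intersect(plan$training_patients, plan$holdout_patients), 0L)

  single <- tibble::tibble(patient_id = "p1", site = "site_a")
  expect_error(split_train_holdout(single), "2 patients")
})

test_that("holdout site mix tracks the cohort site mix across seeds", {
  data <- tibble::tibble(
    patient_id = rep(sprintf("p%02d", 1:50), each = 10),
    site = rep(c(rep("site_a", 40), rep("site_b", 10)), each = 10)
  )
  shares <- vapply(1:100, function(s) {
    plan <- split_train_holdout(data, 0.2, seed = s)
    ho <- data[data$patient_id %in% plan$holdout_patients, ]
    mean(ho$site == "site_a")
  }, numeric(1))
  expect_true(all(abs(shares - 0.8) <= 0.10))
})

test_that("grid search prefers smaller models on ties and separable data", {
  fm <- fake_features(n = 100, sep = 4)
  grid <- list(C = c(0.1, 1), n_band = c(5L, 10L), n_peak = c(2L, 5L))
  gs <- grid_search_cv(fm, grid, n_folds = 5L, seed = 2L)
  expect_equal(min(gs$table$cv_errors), gs$best$cv_errors)
  expect_equal(gs$best$cv_errors, 0)
  # among the zero-error combinations the tie-break picks smallest N then C
  zero <- gs$table[gs$table$cv_errors == 0, ]
  expect_equal(gs$best$N, min(zero$N))
  expect_equal(gs$best$C,
               min(zero$C[zero$N == gs$best$N]))
})

test_that("permuted labels yield chance-level cross-validation error", {
  fm <- fake_features(n = 200, sep = 3, seed = 602, n_patients = 20)
  fm$label <- withr::with_seed(603, sample(fm$label))
  grid <- list(C = c(0.1, 1), n_band = c(5L, 10L), n_peak = c(2L, 5L))
  gs <- grid_search_cv(fm, grid, n_folds = 5L, seed = 3L)
  expect_gt(gs$best$cv_errors, 0.4 * nrow(fm))
  expect_lt(gs$best$cv_errors, 0.6 * nrow(fm))
})

test_that("the final model is deterministic with ratio class weights", {
  fm <- fake_features(n = 90, sep = 3, seed = 604)
  fm <- fm[c(which(fm$label == "tumor"), which(fm$label == "brain")[1:30]), ]
  params <- list(n_band = 8L, n_peak = 3L, C = 1)
  m1 <- train_final(fm, params, seed = 7L)
  m2 <- train_final(fm, params, seed = 7L)
  expect_identical(m1$weights, m2$weights)
  expect_length(m1$weights, params$n_band + params$n_peak)
  tab <- table(fm$label)
  expected_w <- sum(tab) / (2 * tab)
  expect_equal(m1$class_weights[names(expected_w)],
               setNames(as.numeric(expected_w), names(expected_w)))
})

test_that("holdout patients cannot influence the trained model", {
  fm <- fake_features(n = 100, sep = 3, seed = 605)
  plan <- split_train_holdout(fm, 0.2, seed = 9L)
  train <- fm[fm$patient_id %in% plan$training_patients, ]
  hold <- fm[fm$patient_id %in% plan$holdout_patients, ]
  m1 <- train_final(train, list(n_band = 5L, n_peak = 2L, C = 1), seed = 1L)
  hold$label <- rev(hold$label)  # corrupt holdout labels
  m2 <- train_final(train, list(n_band = 5L, n_peak = 2L, C = 1), seed = 1L)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$bias, m2$bias)
})

test_that("ROC evaluation matches hand values and an independent oracle", {
  ev <- evaluate_scores(c(0.9, 0.8, 0.4, 0.2),
                        c("tumor", "tumor", "brain", "brain"))
  expect_equal(ev$auc, 1)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)

  withr::local_seed(606)
  scores <- rnorm(500)
  labels <- sample(c("tumor", "brain"), 500, replace = TRUE)
  ev2 <- evaluate_scores(scores, labels)
  oracle <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("brain", "tumor"),
    direction = "<", quiet = TRUE)))
  expect_equal(ev2$auc, oracle, tolerance = 1e-10)

  big <- evaluate_scores(rnorm(2000),
                         sample(c("tumor", "brain"), 2000, replace = TRUE))
  expect_lt(abs(big$auc - 0.5), 0.03)
  expect_error(evaluate_scores(1:3, c("tumor", "tumor", "tumor")),
               "both classes")
})

test_that("tidy and glance methods expose model and evaluation summaries", {
  fm <- fake_features(n = 80, sep = 3, seed = 607)
  m <- train_final(fm, list(n_band = 5L, n_peak = 2L, C = 1), seed = 1L)
  td <- generics::tidy(m)
  expect_equal(nrow(td), 7L)
  expect_true(all(c("term", "estimate", "type") %in% names(td)))
  ev <- evaluate_holdout(m, fm)
  gl <- generics::glance(ev)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("auc", "sensitivity", "specificity") %in% names(gl)))
})

test_that("power computation reproduces the noncentral-t oracle", {
  expect_equal(power_sample_size(0.5, 0.05, 0.80), 64L)
  n95 <- power_sample_size(0.5, 0.05, 0.95)
  oracle <- ceiling(stats::power.t.test(delta = 0.5, sd = 1, power = 0.95,
                                        sig.level = 0.05)$n)
  expect_equal(n95, as.integer(oracle))
  expect_gte(n95, 100L)
  expect_equal(power_sample_size(50, 0.05, 0.95), 2L)
  # returned n achieves the power, n - 1 does not
  expect_gte(two_sample_t_power(n95, 0.5, 0.05, "two"), 0.95)
  expect_lt(two_sample_t_power(n95 - 1L, 0.5, 0.05, "two"), 0.95)
})

test_that("Cohen's d follows the pooled-sd definition", {
  x <- c(1, 2, 3, 4)
  expect_equal(cohens_d(x, x), 0)
  withr::local_seed(608)
  a <- rnorm(5000, 0, 1)
  b <- rnorm(5000, 1, 1)
  expect_equal(cohens_d(a, b), 1, tolerance = 0.05)
  expect_error(cohens_d(rep(1, 5), rep(1, 5)), "pooled")
})
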