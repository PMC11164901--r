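#' Write a synthetic cohort to plain-text files
#'
#' Persists a cohort in a documented directory layout: `acquisitions.csv`
#' (long format: location_id, frame_index, pixel, counts; frame_index 0 is
#' the dark frame), `metadata.json` (locations, patients, sites, labels,
#' axis and generator settings), `references.csv` (both calibration
#' references, long format) and `truth.csv` (per-location true baseline and
#' noiseless Raman signal).
#'
#' @param cohort a `raman_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "raman_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  acq <- cohort$acquisitions
  if (!"frames" %in% names(acq)) {
    abort("cohort was generated with frames = FALSE; nothing to write")
  }
  long <- purrr::map_dfr(seq_len(nrow(acq)), function(i) {
    fr <- rbind(acq$dark[[i]], acq$frames[[i]])
    tibble(
      location_id = acq$location_id[i],
      frame_index = rep(seq_len(nrow(fr)) - 1L, times = ncol(fr)),
      pixel = rep(seq_len(ncol(fr)) - 1L, each = nrow(fr)),
      counts = as.vector(fr)
    )
  })
  readr::write_csv(long, file.path(dir, "acquisitions.csv"))

  meta <- list(
    locations = acq[, c("location_id", "patient_id", "site", "pathology",
                        "label", "lowq")],
    axis_coefficients = as.list(cohort$axis$coefficients),
    known_peaks = cohort$references$known_peaks,
    n_repeats = cohort$config$n_repeats,
    seed = cohort$config$seed
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  refs <- dplyr::bind_rows(
    dplyr::mutate(cohort$references$wavenumber_reference,
                  reference = "wavenumber", site = NA_character_,
                  wavenumber = NA_real_, measured = .data$counts,
                  known = NA_real_, counts = NULL),
    dplyr::mutate(cohort$references$response_reference,
                  reference = "response")
  )
  readr::write_csv(refs, file.path(dir, "references.csv"))

  truth_long <- purrr::map_dfr(seq_len(nrow(cohort$truth)), function(i) {
    tibble(
      location_id = cohort$truth$location_id[i],
      pixel = seq_along(cohort$truth$baseline[[i]]) - 1L,
      baseline = cohort$truth$baseline[[i]],
      signal = cohort$truth$signal[[i]]
    )
  })
  readr::write_csv(truth_long, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return A `raman_cohort` (without generator config; axis reconstructed
#'   from the stored calibration coefficients).
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  long <- readr::read_csv(file.path(dir, "acquisitions.csv"),
                          show_col_types = FALSE)
  locs <- as_tibble(meta$locations)
  acq_split <- split(long, long$location_id)
  frames <- purrr::map(locs$location_id, function(id) {
    d <- acq_split[[id]]
    m <- matrix(d$counts[order(d$frame_index, d$pixel)],
                nrow = max(d$frame_index) + 1L, byrow = TRUE)
    m
  })
  locs$dark <- purrr::map(frames, ~ .x[1L, ])
  locs$frames <- purrr::map(frames, ~ .x[-1L, , drop = FALSE])

  refs_long <- readr::read_csv(file.path(dir, "references.csv"),
                               show_col_types = FALSE)
  wref <- dplyr::filter(refs_long, .data$reference == "wavenumber")
  rref <- dplyr::filter(refs_long, .data$reference == "response")
  references <- list(
    wavenumber_reference = tibble(pixel = wref$pixel,
                                  counts = wref$measured),
    known_peaks = as.numeric(meta$known_peaks),
    response_reference = rref[, c("site", "pixel", "wavenumber", "measured",
                                  "known")],
    nominal_coefficients = unlist(meta$axis_coefficients)
  )
  coefs <- references$nominal_coefficients
  n_pix <- length(locs$dark[[1]])
  axis <- list(
    wavenumber = coefs[["intercept"]] + coefs[["slope"]] *
      (seq_len(n_pix) - 1L),
    coefficients = c(intercept = coefs[["intercept"]],
                     slope = coefs[["slope"]]),
    spacing = coefs[["slope"]]
  )

  truth_long <- readr::read_csv(file.path(dir, "truth.csv"),
                                show_col_types = FALSE)
  tsplit <- split(truth_long, truth_long$location_id)
  truth <- tibble(
    location_id = locs$location_id,
    label = locs$label,
    baseline = purrr::map(locs$location_id,
                          ~ tsplit[[.x]]$baseline[order(tsplit[[.x]]$pixel)]),
    signal = purrr::map(locs$location_id,
                        ~ tsplit[[.x]]$signal[order(tsplit[[.x]]$pixel)])
  )

  structure(
    list(acquisitions = locs, truth = truth, references = references,
         axis = axis, config = NULL),
    class = "raman_cohort"
  )
}
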