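#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median mad sd rnorm rpois runif rlnorm qnorm qt pt lm coef
#'   predict var quantile setNames
NULL

# population (divide-by-n) standard deviation
pop_sd <- function(x) {
  n <- length(x)
  sqrt(sum((x - mean(x))^2) / n)
}

# derive a stream seed from a base seed; keeps results < 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1009L * as.integer(offset)) %% 2147483647L
}

stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) {
    abort(sprintf("non-finite values in %s", what))
  }
  invisible(x)
}

is_spectrum_df <- function(x) {
  is.data.frame(x) && all(c("wavenumber", "intensity") %in% names(x))
}

spectrum_tbl <- function(wavenumber, intensity, stage = NULL) {
  out <- tibble(wavenumber = as.numeric(wavenumber),
                intensity = as.numeric(intensity))
  if (!is.null(stage)) attr(out, "stage") <- stage
  out
}

spectrum_stage <- function(x) attr(x, "stage", exact = TRUE)
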