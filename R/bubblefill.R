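#' BubbleFill baseline removal
#'
#' Iterative baseline estimator for fluorescence backgrounds under Raman
#' peaks. Working on a copy of the spectrum normalized to the unit square
#' (wavenumber span and intensity range both mapped to \[0, 1\]), the
#' procedure grows a circular-arc "bubble" under the current segment - chord
#' equal to the segment width, raised from below until it first touches the
#' spectrum (leftmost touching bin on ties). The arc is recorded as baseline
#' over the segment, the segment is split at the touch point, and the
#' procedure recurses on both sides, stopping when a segment becomes narrower
#' than `min_bubble_width`. Segments at the spectrum edges grow half-bubbles
#' (apex at the edge) so the baseline can reach the boundary bins. The
#' accumulated baseline is lightly smoothed (moving average of width
#' `min_bubble_width`) and subtracted in original units.
#'
#' The minimum bubble width acts as a feature-size cutoff: structures
#' narrower than it (Raman bands) are left in the residual, broader
#' structures (fluorescence) are absorbed into the baseline. The default of
#' 60 cm^-1 corresponds to the width of the ubiquitous lipid/protein band
#' near 1441 cm^-1.
#'
#' @param spectrum spectrum data frame (`wavenumber`, `intensity`) with
#'   finite intensities.
#' @param min_bubble_width minimum bubble diameter, in cm^-1.
#' @param aspect height of the normalized intensity range relative to the
#'   normalized wavenumber span (1 = unit square). Larger values make the
#'   arcs effectively taller and narrower near their contact point (tighter
#'   hugging of smooth backgrounds but more intrusion under narrow bands);
#'   smaller values flatten them.
#' @param smooth apply the final light smoothing of the accumulated
#'   baseline. Disabling it exposes the raw arc envelope, whose residual is
#'   pointwise monotone in the minimum bubble width.
#' @return A `bubblefill_result` tibble with columns `wavenumber`,
#'   `intensity` (input), `baseline` and `raman` (residual); the baseline
#'   never exceeds the spectrum.
#' @export
bubblefill <- function(spectrum, min_bubble_width = 60, aspect = 1,
                       smooth = TRUE) {
  stopifnot(is_spectrum_df(spectrum))
  y <- spectrum$intensity
  nu <- spectrum$wavenumber
  stopifnot_finite(y, "spectrum intensities")
  n <- length(y)
  span <- nu[n] - nu[1]
  spacing <- span / (n - 1L)
  if (min_bubble_width <= spacing) {
    abort("min_bubble_width must exceed the axis spacing")
  }

  yr <- diff(range(y))
  if (yr == 0) {
    base <- y
  } else {
    tx <- (nu - nu[1]) / span
    yn <- (y - min(y)) / yr * aspect
    wmin <- min_bubble_width / span
    base_n <- rep(min(yn) - 1, n)
    queue <- list(c(1L, n))
    while (length(queue) > 0L) {
      seg <- queue[[1L]]
      queue <- queue[-1L]
      l <- seg[1L]; r <- seg[2L]
      if (r - l < 2L) next
      width <- tx[r] - tx[l]
      idx <- l:r
      # edge segments keep recursing below the minimum width so the
      # baseline can climb to the boundary bins (features narrower than
      # the minimum bubble sitting on a spectrum edge are not protected)
      if (width < wmin && l != 1L && r != n) next
      if (l == 1L && r < n) {            # left-edge half bubble
        radius <- width; centre <- tx[l]
      } else if (r == n && l > 1L) {     # right-edge half bubble
        radius <- width; centre <- tx[r]
      } else {
        radius <- width / 2; centre <- (tx[l] + tx[r]) / 2
      }
      arc <- sqrt(pmax(radius^2 - (tx[idx] - centre)^2, 0))
      gap <- yn[idx] - arc
      lift <- min(gap)
      base_n[idx] <- pmax(base_n[idx], arc + lift)
      touch <- l - 1L + which.min(gap)   # leftmost touching bin
      if (touch == l) {
        queue <- c(queue, list(c(l + 1L, r)))
      } else if (touch == r) {
        queue <- c(queue, list(c(l, r - 1L)))
      } else {
        queue <- c(queue, list(c(l, touch), c(touch, r)))
      }
    }
    base <- pmin(base_n, yn) / aspect * yr + min(y)
    if (smooth) {
      w_sm <- round(min_bubble_width / spacing)
      w_sm <- min(w_sm + (1L - w_sm %% 2L), n - (1L - n %% 2L))
      if (w_sm >= 5L) base <- savgol_smooth(base, order = 2L, window = w_sm)
      base <- pmin(base, y)
    }
  }

  out <- tibble(wavenumber = nu, intensity = y, baseline = base,
                raman = y - base)
  attr(out, "min_bubble_width") <- min_bubble_width
  class(out) <- c("bubblefill_result", class(out))
  out
}
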