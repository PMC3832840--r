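#' Locate the brain-tissue peak of an ADC histogram
#'
#' The cohort-average ADC histogram shows a single clear peak contributed
#' by gray and white matter, near 0.75e-3 mm2/s. The peak is found as the
#' bin-center argmax of the lightly smoothed percent values within a search
#' window that excludes both the zero-clamp spike at ADC = 0 and the CSF
#' tail. Ties break toward the lowest ADC.
#'
#' @param avg An `adc_histogram` (typically the cohort average).
#' @param window Length-2 ADC interval searched, mm2/s.
#' @param smooth_window Odd moving-average width applied before the argmax
#'   (mass computations elsewhere always use the raw histogram).
#' @return An object of class `peak_descriptor`: list with `peak_adc`
#'   (bin center, mm2/s) and `peak_height` (smoothed percent).
#' @export
find_tissue_peak <- function(avg, window = c(0.3e-3, 1.2e-3),
                             smooth_window = 3L) {
  stopifnot(inherits(avg, "adc_histogram"), length(window) == 2L,
            window[1] < window[2])
  smoothed <- moving_average(avg$percent, smooth_window)
  in_win <- which(avg$mids >= window[1] & avg$mids <= window[2])
  if (length(in_win) == 0L) stop("search window contains no bins", call. = FALSE)
  if (all(smoothed[in_win] == 0)) {
    stop("histogram is empty within the peak search window", call. = FALSE)
  }
  k <- in_win[which.max(smoothed[in_win])]
  structure(
    list(peak_adc = avg$mids[k], peak_height = smoothed[k], bin_index = k,
         smoothed = smoothed),
    class = "peak_descriptor"
  )
}

#' Left basis of the tissue peak
#'
#' Scanning from the peak bin toward ADC = 0, returns the center of the
#' first bin whose smoothed value drops to `level` times the peak height
#' (default 1% of the maximum). This is the visible foot of the tissue peak
#' on its CSF-free side.
#'
#' @param avg The `adc_histogram` the peak was found on.
#' @param peak A `peak_descriptor` from [find_tissue_peak()].
#' @param level Fraction of the peak height defining the basis, in (0, 1).
#' @return The basis ADC (a bin center), mm2/s.
#' @export
find_left_basis <- function(avg, peak, level = 0.01) {
  stopifnot(inherits(avg, "adc_histogram"), inherits(peak, "peak_descriptor"),
            level > 0, level < 1)
  if (peak$bin_index <= 1L) {
    stop("no bins left of the peak to search", call. = FALSE)
  }
  smoothed <- peak$smoothed
  threshold <- level * peak$peak_height
  for (k in seq(peak$bin_index - 1L, 1L)) {
    if (smoothed[k] <= threshold) return(avg$mids[k])
  }
  stop("histogram never descends to the basis level left of the peak",
       call. = FALSE)
}

#' Characteristic ADC value by mirroring the peak basis
#'
#' The partition point between tissue-dominated and CSF-dominated voxels.
#' The tissue peak's right side is buried under the CSF/partial-volume
#' tail, so its clean left basis is mirrored about the peak:
#' `a_char = peak + (peak - basis)`, making
#' `a_char - peak == peak - basis` exactly.
#'
#' @param peak A `peak_descriptor`.
#' @param basis The left-basis ADC from [find_left_basis()], mm2/s.
#' @param level The basis level used, recorded for reporting.
#' @return An object of class `characteristic_value`: list with
#'   `left_basis`, `peak_adc`, `a_char` (mm2/s) and `level`.
#' @export
characteristic_value <- function(peak, basis, level = 0.01) {
  stopifnot(inherits(peak, "peak_descriptor"))
  if (basis >= peak$peak_adc) {
    stop("basis must lie strictly left of the peak", call. = FALSE)
  }
  structure(
    list(left_basis = basis, peak_adc = peak$peak_adc,
         peak_height = peak$peak_height,
         a_char = peak$peak_adc + (peak$peak_adc - basis), level = level),
    class = "characteristic_value"
  )
}

#' @export
print.characteristic_value <- function(x, ...) {
  cat(sprintf(
    "<characteristic_value> peak %.3f, basis %.3f -> a_char %.3f (x1e-3 mm2/s, %g%% level)\n",
    x$peak_adc * 1e3, x$left_basis * 1e3, x$a_char * 1e3, 100 * x$level))
  invisible(x)
}

#' Brain-tissue pixel percentage of one subject
#'
#' The per-subject atrophy statistic: the percentage of masked voxels with
#' ADC at or below the characteristic value, computed as the sum of the
#' (raw, unsmoothed) percent over all bins whose center does not exceed
#' `a_char`. The complement — including overflow mass — is the CSF-dominated
#' share.
#'
#' @param hist An `adc_histogram` (one subject's).
#' @param a_char The characteristic ADC, mm2/s; either a number or a
#'   `characteristic_value`.
#' @return Percent of masked voxels in the brain-tissue part, in [0, 100].
#' @export
brain_fraction <- function(hist, a_char) {
  stopifnot(inherits(hist, "adc_histogram"))
  if (inherits(a_char, "characteristic_value")) a_char <- a_char$a_char
  stopifnot(is.numeric(a_char), length(a_char) == 1L)
  if (a_char < hist$mids[1]) {
    warning("characteristic value below the first bin center; fraction is 0",
            call. = FALSE)
  }
  out <- sum(hist$percent[hist$mids <= a_char + 1e-12])
  # beyond the binned range the overflow mass also lies at or below a_char
  if (a_char > max(hist$bin_edges)) out <- out + hist$overflow_percent
  out
}
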