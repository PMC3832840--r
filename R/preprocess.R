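# Centered moving average with shrinking windows at the edges.
moving_average <- function(x, window) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (window == 1L || length(x) == 1L) return(x)
  h <- (window - 1) / 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Mode of the diffusion-weighted intensity histogram
#'
#' MR signal intensities have no absolute scale, so the pipeline
#' self-calibrates on the most common dw intensity: a histogram of dw values
#' is built above a background floor, smoothed with a centered moving
#' average, and the center of the maximal bin returned. The floor
#' (`floor_fraction` times the 99th-percentile intensity) excludes the
#' large background-noise spike that would otherwise capture the mode.
#'
#' @param dw Numeric array of dw intensities.
#' @param n_bins Number of histogram bins (>= 16).
#' @param smooth_window Odd moving-average width; edge windows shrink.
#' @param floor_fraction Background floor as a fraction of the
#'   99th-percentile intensity, in [0, 1).
#' @return The intensity at the smoothed histogram's maximum (ties broken
#'   toward the lowest bin).
#' @export
dw_intensity_mode <- function(dw, n_bins = 256L, smooth_window = 5L,
                              floor_fraction = 0.05) {
  stopifnot(n_bins >= 16L, smooth_window >= 1L, smooth_window %% 2 == 1,
            floor_fraction >= 0, floor_fraction < 1)
  dw <- as.numeric(dw)
  if (length(dw) == 0L) stop("empty intensity array", call. = FALSE)
  floor_val <- floor_fraction * stats::quantile(dw, 0.99, names = FALSE)
  top <- max(dw)
  keep <- dw > floor_val
  if (!any(keep)) stop("all voxels fall below the background floor", call. = FALSE)
  if (top <= floor_val) stop("degenerate intensity range", call. = FALSE)
  edges <- seq(floor_val, top, length.out = n_bins + 1L)
  # bins (lo, hi]; findInterval on left-open intervals via rightmost.closed
  idx <- findInterval(dw[keep], edges, rightmost.closed = FALSE, left.open = TRUE)
  idx[idx > n_bins] <- n_bins
  counts <- tabulate(idx, nbins = n_bins)
  smoothed <- moving_average(counts, smooth_window)
  k <- which.max(smoothed)  # which.max takes the first (lowest) maximum
  (edges[k] + edges[k + 1L]) / 2
}

#' Self-calibrate a volume pair to a target dw mode
#'
#' Scanner export scaling is arbitrary and varies between subjects; both
#' volumes are therefore multiplied by `target / dw_mode` so that the most
#' common dw intensity maps to `target` (default 250). All later thresholds
#' are expressed in these calibrated units.
#'
#' @param pair A [volume_pair()].
#' @param target Calibrated intensity of the dw mode (> 0).
#' @param ... Passed to [dw_intensity_mode()].
#' @return The pair with rescaled volumes and recorded `scale_factor` and
#'   `dw_mode` fields.
#' @export
rescale <- function(pair, target = 250, ...) {
  stopifnot(inherits(pair, "volume_pair"), target > 0)
  mode_val <- dw_intensity_mode(pair$dw, ...)
  if (mode_val == 0) stop("dw intensity mode is zero", call. = FALSE)
  scale_factor <- target / mode_val
  out <- volume_pair(pair$b0 * scale_factor, pair$dw * scale_factor,
                     b_value = pair$b_value)
  out$scale_factor <- scale_factor
  out$dw_mode <- mode_val
  out
}

#' Combined noise/skull mask from b0 and dw volumes
#'
#' Selects the voxels over which ADC histograms are computed and
#' normalized. Under the default `and` rule a voxel is kept iff
#' `b0 > tau_b0` and `dw > dw_floor`: every in-head voxel — tissue and CSF
#' alike — is bright in b0, while background and skull are dark; the dw
#' floor only guarantees that the ADC logarithm is defined, so CSF (dark in
#' dw) is retained. Thresholds are in calibrated units (dw mode = 250).
#'
#' @param pair A rescaled [volume_pair()] (see [rescale()]).
#' @param tau_b0 b0 inclusion threshold (default 50, i.e. 20% of the
#'   calibrated dw mode).
#' @param dw_floor dw inclusion floor (default 1).
#' @param rule `"and"` (default), `"or"`, or `"sum"` (`b0 + dw > tau_b0`).
#' @return An object of class `voxel_mask`: list with logical array
#'   `included` and integer `count`.
#' @export
combined_mask <- function(pair, tau_b0 = 50, dw_floor = 1,
                          rule = c("and", "or", "sum")) {
  stopifnot(inherits(pair, "volume_pair"), tau_b0 >= 0, dw_floor >= 0)
  rule <- match.arg(rule)
  included <- switch(rule,
    and = pair$b0 > tau_b0 & pair$dw > dw_floor,
    or  = pair$b0 > tau_b0 | pair$dw > dw_floor,
    sum = pair$b0 + pair$dw > tau_b0
  )
  count <- sum(included)
  if (count == 0L) {
    stop("combined threshold excludes every voxel (empty or corrupt input)",
         call. = FALSE)
  }
  structure(list(included = included, count = as.integer(count)),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat("<voxel_mask> ", x$count, " of ", length(x$included),
      " voxels included\n", sep = "")
  invisible(x)
}
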