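#' Per-voxel apparent diffusion coefficient over a mask
#'
#' For each masked voxel the two-point ADC estimate is
#' `ADC = ln(b0/dw) / b` in mm2/s. Voxels where noise pushes `b0 <= dw`
#' would yield negative ADC and are clamped to 0, so that the number of
#' values always equals the mask count — the denominator of every
#' percent-normalized histogram.
#'
#' @param pair A (rescaled) [volume_pair()].
#' @param mask A `voxel_mask` from [combined_mask()].
#' @return An object of class `adc_map`: list with numeric `values`
#'   (mm2/s), `b_value` and `n_voxels`.
#' @export
compute_adc <- function(pair, mask) {
  stopifnot(inherits(pair, "volume_pair"), inherits(mask, "voxel_mask"))
  if (mask$count == 0L) stop("empty mask", call. = FALSE)
  b0 <- pair$b0[mask$included]
  dw <- pair$dw[mask$included]
  if (any(dw <= 0)) {
    stop("non-positive dw intensity inside the mask; check `dw_floor`",
         call. = FALSE)
  }
  adc <- log(b0 / dw) / pair$b_value
  adc[b0 <= dw] <- 0
  structure(list(values = adc, b_value = pair$b_value,
                 n_voxels = mask$count),
            class = "adc_map")
}

#' Default ADC histogram bin edges
#'
#' Uniform bins of width 0.02e-3 mm2/s over [0, 4e-3], fine enough to
#' resolve the 1%-of-maximum basis search left of the tissue peak while
#' keeping per-bin counts stable at typical head-mask sizes.
#'
#' @param max_adc Upper edge, mm2/s.
#' @param bin_width Bin width, mm2/s.
#' @return Numeric vector of bin edges.
#' @export
adc_bin_edges <- function(max_adc = 4e-3, bin_width = 0.02e-3) {
  stopifnot(max_adc > 0, bin_width > 0, max_adc > bin_width)
  seq(0, max_adc, by = bin_width)
}

#' Percent-normalized ADC histogram
#'
#' Bins are half-open `[lo, hi)` with the last bin closed; values above the
#' last edge accumulate in `overflow_percent`. Percentages are taken of the
#' total mask count, so `sum(percent) + overflow_percent == 100`: the
#' normalization that compensates for different head sizes.
#'
#' @param map An [compute_adc()] result.
#' @param edges Uniform bin edges, mm2/s.
#' @return An object of class `adc_histogram`: list with `bin_edges`,
#'   `mids`, `percent`, `overflow_percent`, `total_count`.
#' @export
build_histogram <- function(map, edges = adc_bin_edges()) {
  stopifnot(inherits(map, "adc_map"), length(edges) >= 2L)
  if (map$n_voxels == 0L || length(map$values) == 0L) {
    stop("empty ADC map", call. = FALSE)
  }
  widths <- diff(edges)
  if (max(abs(widths - widths[1])) > 1e-9 * widths[1]) {
    stop("bin edges must be uniform", call. = FALSE)
  }
  n_bins <- length(edges) - 1L
  v <- map$values
  over <- sum(v > edges[length(edges)])
  # [lo, hi) half-open; rightmost.closed puts v == last edge into the last bin
  idx <- findInterval(v[v <= edges[length(edges)]], edges,
                      rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L  # guards values below the first edge (none for ADC >= 0)
  counts <- tabulate(idx, nbins = n_bins)
  total <- map$n_voxels
  structure(
    list(
      bin_edges = edges,
      mids = (edges[-1] + edges[-length(edges)]) / 2,
      percent = 100 * counts / total,
      overflow_percent = 100 * over / total,
      total_count = total
    ),
    class = "adc_histogram"
  )
}

#' @export
print.adc_histogram <- function(x, ...) {
  cat("<adc_histogram> ", length(x$percent), " bins over [",
      format(x$bin_edges[1]), ", ", format(max(x$bin_edges)),
      "] mm2/s, ", x$total_count, " voxels, overflow ",
      sprintf("%.3f%%", x$overflow_percent), "\n", sep = "")
  invisible(x)
}

#' Cohort-average ADC histogram
#'
#' Per-bin arithmetic mean of the percent values, each subject weighted
#' equally — each input is already normalized to its own mask count, so the
#' average is a histogram of the "typical" subject, not of the pooled
#' voxels.
#'
#' @param histograms List of `adc_histogram` objects with identical binning.
#' @return An `adc_histogram` whose `total_count` is the summed input count.
#' @export
average_histogram <- function(histograms) {
  stopifnot(length(histograms) >= 1L,
            all(vapply(histograms, inherits, logical(1), "adc_histogram")))
  ref <- histograms[[1]]
  for (h in histograms[-1]) {
    if (!isTRUE(all.equal(h$bin_edges, ref$bin_edges, tolerance = 1e-12))) {
      stop("histograms have mismatched binning", call. = FALSE)
    }
  }
  pct <- rowMeans(vapply(histograms, `[[`, numeric(length(ref$percent)),
                         "percent"))
  over <- mean(vapply(histograms, `[[`, numeric(1), "overflow_percent"))
  structure(
    list(bin_edges = ref$bin_edges, mids = ref$mids, percent = pct,
         overflow_percent = over,
         total_count = sum(vapply(histograms, `[[`, numeric(1), "total_count"))),
    class = "adc_histogram"
  )
}

#' Tidy an ADC histogram
#'
#' @param x An `adc_histogram`.
#' @param ... Unused.
#' @return A tibble with `bin_lo`, `bin_hi`, `mid`, `percent`; the final
#'   row holds the overflow mass (`bin_hi = Inf`).
#' @export
tidy.adc_histogram <- function(x, ...) {
  tibble::tibble(
    bin_lo = c(x$bin_edges[-length(x$bin_edges)], max(x$bin_edges)),
    bin_hi = c(x$bin_edges[-1], Inf),
    mid = c(x$mids, NA_real_),
    percent = c(x$percent, x$overflow_percent)
  )
}

#' Export an ADC histogram as TSV
#'
#' Columns `bin_lo`, `bin_hi`, `percent`; the final row is the overflow.
#'
#' @param x An `adc_histogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_histogram_tsv <- function(x, path) {
  df <- tidy.adc_histogram(x)[, c("bin_lo", "bin_hi", "percent")]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot an ADC histogram
#'
#' Line plot of percent per bin versus ADC (x-axis in 1e-3 mm2/s), the
#' standard way these distributions are displayed.
#'
#' @param object An `adc_histogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adc_histogram <- function(object, ...) {
  df <- tibble::tibble(adc = object$mids * 1e3, percent = object$percent)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$adc, y = .data$percent)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(ADC ~ (10^-3 ~ mm^2 / s)),
                  y = "voxels per bin (%)") +
    ggplot2::theme_minimal()
}
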