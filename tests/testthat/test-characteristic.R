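# Gaussian-shaped average histogram centred on the tissue peak.
gaussian_histogram <- function(mean = 0.75e-3, sd = 0.13e-3,
                               edges = adc_bin_edges()) {
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  dens <- dnorm(mids, mean, sd)
  histogram_from_percent(100 * dens / sum(dens), edges = edges)
}

test_that("find_tissue_peak locates the tissue mode at the bin center", {
  h <- gaussian_histogram()
  pk <- find_tissue_peak(h)
  expect_equal(pk$peak_adc, 0.75e-3, tolerance = 1e-12)
  expect_gt(pk$peak_height, 0)

  # sampled histogram at 1e6 voxels: within one bin of the analytic argmax
  set.seed(41)
  v <- rnorm(1e6, 0.75e-3, 0.13e-3)
  hs <- build_histogram(adc_map_from_values(v[v > 0]))
  oracle_mid <- hs$mids[which.max(dnorm(hs$mids, 0.75e-3, 0.13e-3))]
  pks <- find_tissue_peak(hs)
  expect_lte(abs(pks$peak_adc - oracle_mid), 0.02e-3 + 1e-12)
})

test_that("peak ties break toward the lowest ADC", {
  edges <- adc_bin_edges()
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  pct <- rep(0, length(mids))
  pct[which.min(abs(mids - 0.61e-3))] <- 10
  pct[which.min(abs(mids - 0.81e-3))] <- 10
  h <- histogram_from_percent(pct)
  pk <- find_tissue_peak(h, smooth_window = 1L)
  expect_equal(pk$peak_adc, 0.61e-3)
})

test_that("find_tissue_peak rejects empty windows", {
  h <- gaussian_histogram()
  expect_error(find_tissue_peak(h, window = c(5e-3, 6e-3)), "no bins")
  flat <- histogram_from_percent(rep(0, 200))
  expect_error(find_tissue_peak(flat), "empty")
})

test_that("find_left_basis scans to the 1%-of-maximum crossing", {
  # construct a peak of height 4% at 0.75e-3 descending to <= 0.04% at 0.35e-3,
  # consistent with the mirror rule placing the characteristic value at 1.15e-3
  h <- gaussian_histogram(0.75e-3, 0.13e-3)
  pk <- find_tissue_peak(h, smooth_window = 1L)
  basis <- find_left_basis(h, pk)
  # analytic oracle: Gaussian density falls to 1% of max at z = sqrt(-2 ln .01)
  z <- sqrt(-2 * log(0.01))
  oracle <- 0.75e-3 - z * 0.13e-3
  expect_lte(abs(basis - oracle), 0.02e-3 + 1e-12)

  cv <- characteristic_value(pk, basis)
  expect_lt(abs(cv$a_char - 1.15e-3), 0.021e-3)

  # immediate crossing: zero mass directly left of the peak
  edges <- adc_bin_edges()
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  pct <- rep(0, length(mids)); pct[mids > 0.74e-3 & mids < 0.76e-3] <- 50
  hz <- histogram_from_percent(pct)
  pkz <- find_tissue_peak(hz, smooth_window = 1L)
  expect_equal(find_left_basis(hz, pkz), pkz$peak_adc - 0.02e-3,
               tolerance = 1e-12)

  # a histogram that never descends signals malformed input
  hflat <- histogram_from_percent(rep(1, 200) / 2)
  pkf <- find_tissue_peak(hflat, smooth_window = 1L)
  expect_error(find_left_basis(hflat, pkf), "never descends")
})

test_that("characteristic_value mirrors the basis about the peak", {
  h <- gaussian_histogram()
  pk <- find_tissue_peak(h)

  cv <- characteristic_value(pk, 0.35e-3)
  expect_equal(cv$a_char, 1.15e-3, tolerance = 1e-12)
  # mirror identity is exact (to the last ulp of the addition)
  expect_lt(abs((cv$a_char - cv$peak_adc) - (cv$peak_adc - cv$left_basis)),
            1e-18)

  eps <- 0.004e-3
  cv2 <- characteristic_value(pk, pk$peak_adc - eps)
  expect_equal(cv2$a_char, pk$peak_adc + eps, tolerance = 1e-15)

  pk1 <- pk; pk1$peak_adc <- 1.0e-3
  expect_equal(characteristic_value(pk1, 0.4e-3)$a_char, 1.6e-3)
  expect_error(characteristic_value(pk, 0.9e-3), "left of the peak")
})

test_that("brain_fraction sums the mass at or below the characteristic value", {
  # saturation: everything below
  h_low <- build_histogram(adc_map_from_values(runif(1000, 0, 1e-3)))
  expect_equal(brain_fraction(h_low, 1.15e-3), 100)

  # two-point mass split
  h2 <- build_histogram(adc_map_from_values(rep(c(0.5e-3, 3.0e-3), 50)))
  expect_equal(brain_fraction(h2, 1.15e-3), 50)

  # monotone non-increasing as a_char decreases; 100 at infinity
  set.seed(51)
  h <- build_histogram(adc_map_from_values(rexp(5000, 1 / 1.0e-3)))
  cuts <- seq(3.9e-3, 0.1e-3, by = -0.2e-3)
  fr <- vapply(cuts, function(a) brain_fraction(h, a), numeric(1))
  expect_true(all(diff(fr) <= 0))
  expect_equal(brain_fraction(h, Inf), 100, tolerance = 1e-9)

  expect_warning(brain_fraction(h, 0.001e-3), "below the first bin center")
})

test_that("noise-free phantom brain fraction matches the label-field count", {
  cfg <- clean_config()
  pair <- synthesize_volumes(test_subject(70), cfg, fast = TRUE)
  labels <- attr(pair, "labels")
  a <- analyze_subject(pair)
  pk <- find_tissue_peak(a$histogram)
  cv <- characteristic_value(pk, find_left_basis(a$histogram, pk))
  truth <- 100 * sum(labels == 1L) / sum(labels > 0L)
  expect_lt(abs(brain_fraction(a$histogram, cv) - truth), 1)
})
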