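AGE_GROUP_BOUNDS <- tibble::tibble(
  group = 1:4,
  lower = c(0, 20, 40, 60),
  upper = c(20, 40, 60, 90)
)

#' Assign ages to the four age groups
#'
#' Groups are the half-open intervals [0,20), [20,40), [40,60) and the
#' closed-ended [60,90].
#'
#' @param age Age(s) in decimal years, within [0, 90].
#' @return Integer group index 1-4 (vectorized).
#' @export
assign_age_group <- function(age) {
  if (any(age < 0 | age > 90)) {
    stop("ages must lie within [0, 90]", call. = FALSE)
  }
  findInterval(age, c(0, 20, 40, 60), rightmost.closed = FALSE)
}

#' Age-group summaries of the brain-tissue percentage
#'
#' @param results Data frame with columns `age` and `brain_fraction`
#'   (percent), one row per subject.
#' @return A tibble with one row per age group: `group`, `lower`, `upper`,
#'   `n`, `mean`, `sd` (sample SD, n-1 denominator; `NA` when undefined).
#'   Empty groups are reported with `n = 0`.
#' @export
group_summary <- function(results) {
  stopifnot(nrow(results) > 0, all(c("age", "brain_fraction") %in% names(results)))
  results |>
    dplyr::mutate(group = assign_age_group(.data$age)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$brain_fraction),
      sd = stats::sd(.data$brain_fraction),
      .groups = "drop"
    ) |>
    dplyr::right_join(AGE_GROUP_BOUNDS, by = "group") |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    dplyr::arrange(.data$group) |>
    dplyr::select("group", "lower", "upper", "n", "mean", "sd")
}

#' Adjacent age-group comparisons
#'
#' Two-sample pooled-variance t-tests (two-sided) between each pair of
#' adjacent age groups — (2 vs 1), (3 vs 2), (4 vs 3) — with Bonferroni
#' correction over the family of 3 tests.
#'
#' @param results Data frame with columns `age` and `brain_fraction`.
#' @return A tibble with columns `group_a`, `group_b`, `n_a`, `n_b`,
#'   `t_statistic`, `df`, `p_raw`, `p_corrected`, `n_tests`.
#' @export
compare_adjacent_groups <- function(results) {
  g <- assign_age_group(results$age)
  y <- results$brain_fraction
  rows <- purrr::map(1:3, function(i) {
    a <- y[g == i + 1]
    b <- y[g == i]
    if (length(a) < 2 || length(b) < 2) {
      stop(sprintf("group %d vs %d: each group needs n >= 2", i + 1, i),
           call. = FALSE)
    }
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      stop(sprintf("group %d vs %d: zero variance in both groups", i + 1, i),
           call. = FALSE)
    }
    tt <- stats::t.test(a, b, var.equal = TRUE)
    tibble::tibble(
      group_a = i + 1L, group_b = i,
      n_a = length(a), n_b = length(b),
      t_statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_raw = tt$p.value
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_corrected <- stats::p.adjust(out$p_raw, method = "bonferroni", n = 3)
  out$n_tests <- 3L
  out
}

#' Quadratic fit of brain-tissue percentage versus age
#'
#' Ordinary least squares of `brain_fraction` on age and age squared,
#' oriented as `y = c0 + c1*x + c2*x^2`. The negative quadratic term found
#' in aging cohorts means tissue loss accelerates with age.
#'
#' @param results Data frame with columns `age`, `brain_fraction` and
#'   (when stratifying) `sex`.
#' @param stratum `"all"`, `"female"` or `"male"`.
#' @return An object of class `adc_quadfit` with fields `c0`, `c1`, `c2`,
#'   `rmse` (percent), `n`, `stratum` and the underlying `lm` fit.
#' @export
fit_quadratic <- function(results, stratum = c("all", "female", "male")) {
  stratum <- match.arg(stratum)
  df <- tibble::as_tibble(results)
  if (stratum != "all") df <- dplyr::filter(df, .data$sex == stratum)
  if (nrow(df) < 3) {
    stop(sprintf("quadratic fit needs n >= 3 subjects (stratum '%s' has %d)",
                 stratum, nrow(df)), call. = FALSE)
  }
  if (length(unique(df$age)) < 3) {
    stop("quadratic fit needs at least 3 distinct ages", call. = FALSE)
  }
  model <- stats::lm(brain_fraction ~ age + I(age^2), data = df)
  cf <- unname(stats::coef(model))
  structure(
    list(c0 = cf[1], c1 = cf[2], c2 = cf[3],
         rmse = sqrt(mean(stats::residuals(model)^2)),
         n = nrow(df), stratum = stratum, model = model),
    class = "adc_quadfit"
  )
}

#' @export
print.adc_quadfit <- function(x, ...) {
  cat(sprintf(
    "<adc_quadfit> [%s, n=%d] y = %.4g %+.4g x %+.5g x^2 (rmse %.3g%%)\n",
    x$stratum, x$n, x$c0, x$c1, x$c2, x$rmse))
  cat(sprintf("  slope: %+.3f (age 20), %+.3f (age 50), %+.3f (age 80) %%/year\n",
              slope_at_age(x, 20), slope_at_age(x, 50), slope_at_age(x, 80)))
  invisible(x)
}

#' Slope of a quadratic age trajectory
#'
#' The instantaneous rate of brain-tissue change, `c1 + 2*c2*age`,
#' in percent per year.
#'
#' @param fit An `adc_quadfit`, or a numeric vector `c(c0, c1, c2)`.
#' @param age Age(s) in years.
#' @return Slope(s) in percent/year.
#' @export
slope_at_age <- function(fit, age) {
  if (inherits(fit, "adc_quadfit")) {
    c1 <- fit$c1; c2 <- fit$c2
  } else {
    stopifnot(is.numeric(fit), length(fit) == 3L)
    c1 <- fit[2]; c2 <- fit[3]
  }
  c1 + 2 * c2 * age
}

#' Tidy a quadratic age-trajectory fit
#'
#' @param x An `adc_quadfit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
tidy.adc_quadfit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble::tibble(
    term = c("c0", "c1", "c2"),
    estimate = unname(sm[, 1]),
    std.error = unname(sm[, 2]),
    statistic = unname(sm[, 3]),
    p.value = unname(sm[, 4])
  )
}

#' One-line summary of a quadratic age-trajectory fit
#'
#' @param x An `adc_quadfit`.
#' @param ... Unused.
#' @return A one-row tibble: `stratum`, `n`, `c0`, `c1`, `c2`, `rmse`,
#'   `r.squared`, and the slopes at ages 20, 50 and 80.
#' @export
glance.adc_quadfit <- function(x, ...) {
  tibble::tibble(
    stratum = x$stratum, n = x$n,
    c0 = x$c0, c1 = x$c1, c2 = x$c2, rmse = x$rmse,
    r.squared = summary(x$model)$r.squared,
    slope_20 = slope_at_age(x, 20),
    slope_50 = slope_at_age(x, 50),
    slope_80 = slope_at_age(x, 80)
  )
}

#' Scatter plot of brain fraction versus age with quadratic fits
#'
#' @param results Per-subject results with `age`, `brain_fraction`, `sex`.
#' @param fits Optional named list of `adc_quadfit` objects to overlay.
#' @return A ggplot object.
#' @export
plot_age_trajectory <- function(results, fits = NULL) {
  p <- ggplot2::ggplot(results,
                       ggplot2::aes(x = .data$age, y = .data$brain_fraction)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$sex), alpha = 0.7) +
    ggplot2::labs(x = "age (years)", y = "brain-tissue pixels (%)") +
    ggplot2::theme_minimal()
  if (!is.null(fits)) {
    ages <- seq(min(results$age), max(results$age), length.out = 200)
    curves <- purrr::imap_dfr(fits, function(f, nm) {
      tibble::tibble(age = ages,
                     brain_fraction = f$c0 + f$c1 * ages + f$c2 * ages^2,
                     stratum = nm)
    })
    p <- p + ggplot2::geom_line(
      data = curves,
      ggplot2::aes(x = .data$age, y = .data$brain_fraction,
                   linetype = .data$stratum)
    )
  }
  p
}
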