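results_df <- function(age, y, sex = rep("female", length(age))) {
  tibble::tibble(subject_id = sprintf("S%03d", seq_along(age)),
                 age = age, sex = sex, brain_fraction = y)
}

test_that("age groups use half-open intervals with a closed end at 90", {
  expect_equal(assign_age_group(c(0, 19.99, 20, 39.9, 40, 59.9, 60, 89.9, 90)),
               c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 4L))
  expect_error(assign_age_group(-0.1), "0, 90")
  expect_error(assign_age_group(90.1), "0, 90")
})

test_that("group_summary computes n, mean and sample sd per group", {
  r <- results_df(age = c(10, 30, 50, 70), y = c(85, 84, 80, 70))
  gs <- group_summary(r)
  expect_equal(gs$group, 1:4)
  expect_equal(gs$n, rep(1L, 4))
  expect_equal(gs$mean, c(85, 84, 80, 70))
  expect_true(all(is.na(gs$sd)))

  r2 <- results_df(age = c(25, 35), y = c(80, 82))
  gs2 <- group_summary(r2)
  expect_equal(gs2$n, c(0L, 2L, 0L, 0L))
  expect_equal(gs2$mean[2], 81)
  expect_equal(gs2$sd[2], sqrt(2))
})

test_that("group means decrease along a simulated declining trajectory", {
  m <- sample_cohort(120, c(5, 85), age_trajectory(), seed = 17)
  r <- results_df(m$age, m$true_brain_fraction)
  gs <- group_summary(r)
  expect_true(all(diff(gs$mean) < 0))
})

test_that("adjacent groups are compared with pooled-variance t-tests", {
  # identical groups: t = 0, p = 1 for the (2 vs 1) comparison
  r <- results_df(age = c(5, 10, 25, 30, 45, 50, 65, 70),
                  y = c(80, 81, 80, 81, 70, 71, 60, 61))
  cmp <- compare_adjacent_groups(r)
  expect_equal(nrow(cmp), 3L)
  expect_equal(cmp$t_statistic[1], 0)
  expect_equal(cmp$p_raw[1], 1)
  expect_equal(cmp$n_tests, rep(3L, 3))
  # Bonferroni: p_corrected = min(1, 3 * p_raw), never below p_raw
  expect_equal(cmp$p_corrected, pmin(1, 3 * cmp$p_raw))
  expect_true(all(cmp$p_corrected >= cmp$p_raw))

  # extreme separation with tiny jitter
  set.seed(61)
  r2 <- results_df(age = c(rep(10, 4), rep(30, 4), rep(50, 4), rep(70, 4)),
                   y = c(rep(10, 8) + rnorm(8, 0, 1e-3),
                         rep(0, 4) + rnorm(4, 0, 1e-3),
                         rep(10, 4) + rnorm(4, 0, 1e-3)))
  cmp2 <- compare_adjacent_groups(r2)
  expect_lt(cmp2$p_corrected[2], 1e-6)

  # textbook pooled-variance oracle on {80,81,82} vs {76,77,78}
  r3 <- results_df(age = c(5, 6, 7, 25, 26, 27),
                   y = c(76, 77, 78, 80, 81, 82))
  cmp3 <- compare_adjacent_groups(
    results_df(age = c(r3$age, 45, 46, 65, 66),
               y = c(r3$brain_fraction, 1, 2, 1, 2)))
  a <- c(80, 81, 82); b <- c(76, 77, 78)
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  t_oracle <- (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
  expect_equal(cmp3$t_statistic[1], t_oracle, tolerance = 1e-12)

  expect_error(
    compare_adjacent_groups(results_df(age = c(10, 30, 30, 50, 50, 70, 70),
                                       y = 1:7)),
    "n >= 2")
})

test_that("fit_quadratic recovers exact generating coefficients", {
  # three exact points determine the parabola: printed female-cohort shape
  ages <- c(10, 40, 70)
  y <- 84.2 - 0.105 * ages - 0.0020 * ages^2
  fit <- fit_quadratic(results_df(ages, y))
  expect_equal(c(fit$c0, fit$c1, fit$c2), c(84.2, -0.105, -0.0020),
               tolerance = 1e-9)
  expect_lt(fit$rmse, 1e-9)

  const <- fit_quadratic(results_df(c(10, 20, 30, 40), rep(50, 4)))
  expect_equal(c(const$c0, const$c1, const$c2), c(50, 0, 0), tolerance = 1e-9)

  expect_error(fit_quadratic(results_df(c(10, 20), c(1, 2))), "n >= 3")
  expect_error(fit_quadratic(results_df(c(10, 10, 10), c(1, 2, 3))),
               "distinct ages")
})

test_that("fit_quadratic equals the closed-form normal-equations solution", {
  set.seed(71)
  for (rep in 1:3) {
    age <- runif(200, 5, 85)
    y <- 83.5 - 0.068 * age - 0.0027 * age^2 + rnorm(200, 0, 1.5)
    fit <- fit_quadratic(results_df(age, y))
    X <- cbind(1, age, age^2)
    beta <- solve(t(X) %*% X, t(X) %*% y)   # independent closed-form oracle
    expect_equal(c(fit$c0, fit$c1, fit$c2), as.vector(beta), tolerance = 1e-9)
  }
  # coefficients within 3 SE of the generating truth
  sm <- summary(fit$model)$coefficients
  expect_true(all(abs(sm[, 1] - c(83.5, -0.068, -0.0027)) < 3 * sm[, 2]))
})

test_that("stratified fits select the requested sex", {
  set.seed(72)
  age <- runif(60, 5, 85)
  sex <- rep(c("female", "male"), 30)
  y <- ifelse(sex == "female", 84.2 - 0.105 * age - 0.0020 * age^2,
              83.5 - 0.071 * age - 0.0029 * age^2)
  r <- results_df(age, y, sex)
  ff <- fit_quadratic(r, "female")
  fm <- fit_quadratic(r, "male")
  expect_equal(ff$n, 30L)
  expect_equal(c(ff$c0, ff$c1, ff$c2), c(84.2, -0.105, -0.0020),
               tolerance = 1e-9)
  expect_equal(c(fm$c0, fm$c1, fm$c2), c(83.5, -0.071, -0.0029),
               tolerance = 1e-9)
})

test_that("slope_at_age evaluates the derivative of the quadratic", {
  expect_equal(slope_at_age(c(83.5, -0.068, -0.0027), 50), -0.338)
  expect_equal(slope_at_age(c(83.5, -0.071, -0.0029), 80),
               -0.071 - 2 * 0.0029 * 80)
  expect_equal(slope_at_age(c(12, 0, 0), 77), 0)
  # linear in age, exactly c1 at age 0
  expect_equal(slope_at_age(c(1, -0.1, -0.002), 0), -0.1)
  ages <- c(10, 30, 50)
  s <- slope_at_age(c(0, -0.1, -0.002), ages)
  expect_equal(diff(s) / diff(ages), rep(2 * -0.002, 2))
})

test_that("tidy and glance summarise a fit", {
  set.seed(73)
  age <- runif(50, 5, 85)
  y <- 83.5 - 0.068 * age - 0.0027 * age^2 + rnorm(50, 0, 1)
  fit <- fit_quadratic(results_df(age, y))
  td <- tidy(fit)
  expect_equal(td$term, c("c0", "c1", "c2"))
  expect_equal(td$estimate, c(fit$c0, fit$c1, fit$c2))
  gl <- glance(fit)
  expect_equal(gl$n, 50L)
  expect_equal(gl$slope_50, slope_at_age(fit, 50))
})
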