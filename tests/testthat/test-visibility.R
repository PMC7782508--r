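test_that("Weibull detection rate matches its closed form", {
  cv <- psychometric_curve(0.08, 2.5)
  expect_equal(weibull_rate(0, cv), 0.5)
  expect_equal(weibull_rate(10, cv), 1.0, tolerance = 1e-12)
  expect_equal(weibull_rate(0.08, cv), 0.5 + 0.5 * (1 - exp(-1)))
  # monotone nondecreasing on any increasing grid
  r <- weibull_rate(seq(0, 0.5, by = 0.01), cv)
  expect_true(all(diff(r) >= 0))
  expect_error(psychometric_curve(-0.1, 2), "positive")
  expect_error(psychometric_curve(0.1, 0), "positive")
})

test_that("Weibull ML fit interpolates two empirical rates exactly", {
  # with two contrast levels the two-parameter family can match both
  # empirical rates, so the MLE reproduces them to optimizer precision
  set.seed(4)
  tab <- data.frame(
    contrast = rep(c(0.05, 0.10), each = 400),
    interval_with_target = rep(c(1L, 2L), 400),
    correct = c(rbinom(400, 1, 0.7), rbinom(400, 1, 0.95)))
  fit <- fit_weibull(tab, which = "all")
  emp <- tapply(tab$correct, tab$contrast, mean)
  pred <- predict(fit, data.frame(contrast = as.numeric(names(emp))))
  expect_equal(unname(pred), unname(as.vector(emp)), tolerance = 1e-6)
})

test_that("Weibull ML fit recovers generating parameters", {
  trials <- make_contrast_trials(psychometric_curve(0.08, 2.5),
                                 contrasts = c(0.04, 0.06, 0.08, 0.10, 0.13),
                                 n_per_level = 1000, seed = 11)
  fit <- fit_weibull(trials, which = "all")
  expect_lt(abs(coef(fit)[["threshold"]] - 0.08) / 0.08, 0.10)
  expect_lt(abs(coef(fit)[["steepness"]] - 2.5) / 2.5, 0.10)
})

test_that("degenerate detection tables are rejected", {
  tab <- data.frame(contrast = rep(0.1, 50), interval_with_target = 1L,
                    correct = rep(1L, 50))
  expect_error(fit_weibull(tab, "all"), "non-identifiable")
  tab2 <- data.frame(contrast = rep(c(0.05, 0.1), 25),
                     interval_with_target = 1L, correct = 1L)
  expect_error(fit_weibull(tab2, "all"), "non-identifiable")
})

test_that("d-prime conversion from 2IFC rates", {
  expect_equal(dprime_from_rates(0.5, 0.5), 0)
  expect_equal(dprime_from_rates(pnorm(2), pnorm(2)), 4 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(dprime_from_rates(0.9, 0.5), qnorm(0.9) / sqrt(2))
  # antisymmetry under f -> 1 - f
  f <- c(0.6, 0.75, 0.9)
  expect_equal(dprime_from_rates(f, f), -dprime_from_rates(1 - f, 1 - f))
  # clamping of boundary rates warns and stays finite and ordered
  expect_warning(d1 <- dprime_from_rates(1, 0.8, n_trials = 200), "clamped")
  d2 <- dprime_from_rates(0.99, 0.8)
  expect_true(is.finite(d1) && d1 > d2)
})

test_that("visibility time course has the right limits and shape", {
  tv <- temporal_visibility(a = 3, k = 8)
  expect_equal(dprime_timecourse(0, tv), 0)
  expect_equal(dprime_timecourse(100, tv), 3 / sqrt(8), tolerance = 1e-9)
  d <- dprime_timecourse(seq(0.01, 1, by = 0.01), tv)
  expect_true(all(diff(d) > 0))
  # perfect-integration limit k -> 0: d'(T) -> a sqrt(T/2)
  tv0 <- temporal_visibility(a = 3, k = 1e-8)
  expect_equal(dprime_timecourse(0.4, tv0), 3 * sqrt(0.4 / 2),
               tolerance = 1e-6)
})

test_that("spatial field evaluates the two exponentials", {
  p <- visibility_field(2, 0.3, 10, 0.2, 1.5)
  at0 <- visibility_params_at(0, 0, p)
  expect_equal(at0$a, 2)
  expect_equal(at0$k, 10)
  # vertical anisotropy: horizontal locations more visible for p5 > 1
  expect_gt(visibility_params_at(3, 0, p)$a, visibility_params_at(0, 3, p)$a)
  # (3, 4) with p5 = 1 has weighted radius 5
  p1 <- visibility_field(2, 0.3, 10, 0.2, 1)
  expect_equal(visibility_params_at(3, 4, p1)$a, 2 * exp(-5 * 0.3))
  expect_error(visibility_field(2, -0.3, 10, 0.2, 1), "positive")
})

test_that("time course equals the signal-detection ratio of evidence moments", {
  set.seed(8)
  for (i in 1:100) {
    a <- runif(1, 0.5, 15); k <- runif(1, 0.5, 40); T <- runif(1, 0.01, 2)
    tv <- temporal_visibility(a, k)
    mo <- evidence_moments(T, tv, target_present = TRUE)
    expect_equal(dprime_timecourse(T, tv), 2 * mo$mean / sqrt(mo$variance),
                 tolerance = 1e-9)
  }
})

test_that("visibility-field fit recovers noiseless generating parameters", {
  true <- visibility_field(6, 0.35, 12, 0.22, 1.4)
  gridpts <- expand.grid(x_deg = c(0, 1.5, 3, 4.5, 6), y_deg = c(0, 2, 4),
                         exposure_s = c(0.05, 0.1, 0.2, 0.4, 0.7))
  samples <- data.frame(gridpts,
                        dprime = dprime_at(gridpts$x_deg, gridpts$y_deg,
                                           gridpts$exposure_s, true, floor = 0),
                        weight = 1)
  fit <- fit_visibility_field(samples, n_starts = 16, seed = 2)
  expect_true(all(abs(coef(fit) - unlist(true)) / unlist(true) < 0.05))
  # achieved objective no worse than the generating parameters' (zero)
  expect_lt(fit$objective, 1e-6)
  # duplicating every sample leaves the optimum unchanged
  fit2 <- fit_visibility_field(rbind(samples, samples), n_starts = 16, seed = 2)
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-4)
})

test_that("visibility-field fit under noise recovers foveal steady d-prime", {
  true <- visibility_field(6, 0.35, 12, 0.22, 1.4)
  gridpts <- expand.grid(x_deg = c(0, 1.5, 3, 4.5, 6), y_deg = c(0, 2, 4),
                         exposure_s = c(0.05, 0.1, 0.2, 0.4, 0.7))
  set.seed(21)
  samples <- data.frame(gridpts,
                        dprime = pmax(dprime_at(gridpts$x_deg, gridpts$y_deg,
                                                gridpts$exposure_s, true,
                                                floor = 0) +
                                        rnorm(nrow(gridpts), 0, 0.2), 0),
                        weight = 1)
  fit <- fit_visibility_field(samples, n_starts = 16, seed = 3)
  steady <- coef(fit)[["p1"]] / sqrt(coef(fit)[["p3"]])
  expect_lt(abs(steady - 6 / sqrt(12)) / (6 / sqrt(12)), 0.10)
})

test_that("two-stage visibility fit agrees with the one-stage fit", {
  true <- visibility_field(6, 0.35, 12, 0.22, 1.4)
  gridpts <- expand.grid(x_deg = c(0, 1.5, 3, 4.5, 6), y_deg = c(0, 2),
                         exposure_s = c(0.05, 0.1, 0.2, 0.4, 0.7))
  samples <- data.frame(gridpts,
                        dprime = dprime_at(gridpts$x_deg, gridpts$y_deg,
                                           gridpts$exposure_s, true, floor = 0),
                        weight = 1)
  fit <- fit_visibility_field(samples, method = "two-stage", n_starts = 16,
                              seed = 2)
  expect_true(all(abs(coef(fit) - unlist(true)) / unlist(true) < 0.05))
})

test_that("insufficient coverage is rejected", {
  s1 <- data.frame(x_deg = c(0, 1), y_deg = 0, exposure_s = 0.2,
                   dprime = c(3, 2), weight = 1)
  expect_error(fit_visibility_field(s1), "exposures")
  s2 <- data.frame(x_deg = 0, y_deg = 0, exposure_s = c(0.1, 0.2),
                   dprime = c(1, 2), weight = 1)
  expect_error(fit_visibility_field(s2), "eccentricities")
})
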