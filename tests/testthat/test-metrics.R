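test_that("Bhattacharyya coefficient axioms and hand value", {
  h <- c(0.2, 0.3, 0.5)
  expect_equal(bhattacharyya(h, h), 1)
  expect_equal(bhattacharyya(c(1, 0), c(0, 1)), 0)
  expect_equal(bhattacharyya(c(0.5, 0.5), c(0.25, 0.75)),
               sqrt(0.125) + sqrt(0.375))
  expect_equal(bhattacharyya(c(0.5, 0.5), c(0.25, 0.75)), 0.9659,
               tolerance = 1e-4)
  # symmetry and bounds
  g <- c(0.7, 0.1, 0.2)
  expect_equal(bhattacharyya(h, g), bhattacharyya(g, h))
  expect_true(bhattacharyya(h, g) > 0 && bhattacharyya(h, g) < 1)
  expect_equal(bhattacharyya_distance(h, h), 0)
  expect_error(bhattacharyya(c(0.5, 0.5), c(1)), "same bins")
  expect_error(bhattacharyya(c(2, 1), c(0.5, 0.5)), "normalized")
})

test_that("fixation-noise statistics", {
  s <- data.frame(x = c(0, 1), y = c(0, 0))
  fn <- fixation_noise(s)
  expect_equal(fn$sd_fix, 0.5)
  expect_equal(fn$rms_fix, 1.0)
  const <- data.frame(x = rep(2, 5), y = rep(-1, 5))
  expect_equal(unlist(fixation_noise(const)), c(sd_fix = 0, rms_fix = 0))
  # translation invariance
  set.seed(3)
  s2 <- data.frame(x = rnorm(20), y = rnorm(20))
  s3 <- data.frame(x = s2$x + 5, y = s2$y - 2)
  expect_equal(unlist(fixation_noise(s2)), unlist(fixation_noise(s3)))
  expect_error(fixation_noise(data.frame(x = 1, y = 1)), "2 samples")
})

test_that("summary exclusion rules", {
  # a single two-fixation trial: both fixations excluded from durations
  fx <- data.frame(trial = 1, fix_index = 1:2, x = c(0, 1), y = c(0, 0),
                   onset = c(0, 0.25), duration = c(0.25, 0.3),
                   sacc_type = c(NA, "normal"),
                   amplitude = c(NA, 1), direction = c(NA, 0))
  tr <- data.frame(trial = 1, n_fix = 2)
  s <- summarize_trials(list(fixations = fx, trials = tr))
  expect_equal(sum(s$duration_counts), 0)
  # but the second fixation counts for distance and amplitude
  expect_equal(sum(s$distance_counts), 1)
  expect_equal(sum(s$amplitude_counts), 1)
})

test_that("summaries merge additively across sub-batches", {
  m <- search_model("elm", grid = grid100)
  st <- simulate(m, nsim = 30, seed = 41)
  ids <- st$trials$trial
  pick <- function(sel) list(
    fixations = st$fixations[st$fixations$trial %in% sel, ],
    trials = st$trials[st$trials$trial %in% sel, ])
  s_all <- summarize_trials(pick(ids))
  s_merge <- merge_summaries(summarize_trials(pick(ids[1:15])),
                             summarize_trials(pick(ids[16:30])))
  expect_equal(s_all$duration, s_merge$duration, tolerance = 1e-12)
  expect_equal(s_all$amplitude, s_merge$amplitude, tolerance = 1e-12)
  expect_equal(s_all$duration_by_ordinal, s_merge$duration_by_ordinal)
})

test_that("identical trials give per-ordinal delta histograms", {
  fx <- do.call(rbind, lapply(1:5, function(tr)
    data.frame(trial = tr, fix_index = 1:4, x = c(0, 1, 2, 3), y = 0,
               onset = (0:3) * 0.25, duration = 0.25,
               sacc_type = c(NA, rep("normal", 3)),
               amplitude = c(NA, 1, 1, 1), direction = c(NA, 0, 0, 0))))
  s <- summarize_trials(list(fixations = fx,
                             trials = data.frame(trial = 1:5, n_fix = 4)))
  for (j in 1:2) {  # ordinals with duration data (2nd and 3rd fixations)
    h <- s$duration_by_ordinal[, j]
    expect_equal(sum(h > 0), 1)
  }
})

test_that("timing loss separates duration and amplitude components", {
  m <- search_model("ctelm", grid = grid100)
  st <- simulate(m, nsim = 25, seed = 9)
  s <- summarize_trials(st)
  expect_equal(loss_timing(s, s, "ctelm"), 0)
  expect_equal(loss_timing(s, s, "cctelm"), 0)
  s2 <- s
  s2$amplitude <- rev(s2$amplitude)
  expect_equal(loss_timing(s2, s, "ctelm"), 0)
  expect_gt(loss_timing(s2, s, "cctelm"), 0)
  expect_gte(loss_timing(s2, s, "cctelm"), 0)
})

test_that("bootstrap confidence interval of the overlap coefficient", {
  m <- search_model("elm", grid = grid100)
  st <- simulate(m, nsim = 40, seed = 51)
  b <- bootstrap_bc(st, st, metric = "amplitude", n_boot = 50, seed = 1)
  expect_true(all(b$bc == 1))
  expect_equal(diff(b$ci), 0)
  # determinism
  st2 <- simulate(m, nsim = 40, seed = 52)
  b1 <- bootstrap_bc(st, st2, metric = "amplitude", n_boot = 100, seed = 4)
  b2 <- bootstrap_bc(st, st2, metric = "amplitude", n_boot = 100, seed = 4)
  expect_identical(b1$bc, b2$bc)
  expect_error(bootstrap_bc(st, st2, n_boot = 1), "n_boot")
})

test_that("bootstrap interval narrows with more trials", {
  m <- search_model("elm", grid = grid100)
  a1 <- simulate(m, nsim = 50, seed = 61)
  b1 <- simulate(m, nsim = 50, seed = 62)
  a4 <- simulate(m, nsim = 200, seed = 61)
  b4 <- simulate(m, nsim = 200, seed = 62)
  w1 <- diff(bootstrap_bc(a1, b1, metric = "amplitude", n_boot = 200,
                          seed = 3)$ci)
  w4 <- diff(bootstrap_bc(a4, b4, metric = "amplitude", n_boot = 200,
                          seed = 3)$ci)
  expect_lt(w4, 0.75 * w1)
})

test_that("memory capacities beyond the fixation cap behave as unlimited", {
  m <- search_model("cctelm", grid = grid100, max_fixations = 100)
  target <- summarize_trials(simulate(m, nsim = 30, seed = 71))
  sw <- memory_sweep(m, target, capacities = c(1000, Inf), n_trials = 15,
                     seed = 5)
  expect_equal(sw$scores$score[1], sw$scores$score[2])
  expect_true(all(sw$scores$score >= 0 & sw$scores$score <= 1))
})

test_that("genetic-algorithm fit improves over its initial population", {
  m <- search_model("ctelm", grid = grid100)
  target <- summarize_trials(simulate(m, nsim = 60, seed = 81))
  ga0 <- ga_config(pop_size = 6, generations = 0, n_trials = 25)
  f0 <- fit_timing_params(m, target, ga = ga0, seed = 2)
  expect_length(f0$trace, 1)
  expect_true(is.finite(f0$loss))
  ga2 <- ga_config(pop_size = 6, generations = 2, n_trials = 25)
  f2 <- fit_timing_params(m, target, ga = ga2, seed = 2)
  expect_length(f2$trace, 3)
  # elitist best-so-far never worsens within a run's trace resolution
  expect_lte(f2$loss, max(f2$trace) + 1e-12)
  expect_named(f2$par, c("q1", "q2", "q3"))
  mcc <- search_model("cctelm", grid = grid100)
  expect_error(fit_timing_params(search_model("elm", grid = grid100), target),
               "timing")
})

test_that("summary histograms serialize losslessly to JSON", {
  m <- search_model("ctelm", grid = grid100)
  s <- summarize_trials(simulate(m, nsim = 10, seed = 91),
                        bins = histogram_bins(px_per_deg = 10))
  path <- tempfile(fileext = ".json")
  summary_to_json(s, path)
  back <- summary_from_json(path)
  expect_equal(back$duration, s$duration, tolerance = 1e-12)
  expect_equal(back$amplitude_by_ordinal, s$amplitude_by_ordinal,
               ignore_attr = TRUE)
  expect_equal(loss_timing(back, s, "cctelm"), 0, tolerance = 1e-10)
})
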