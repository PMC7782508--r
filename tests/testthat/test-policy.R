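test_that("collapsing bound evaluates and has the right limits", {
  q <- saccade_timing_params(-4, 0.1, -1)
  expect_equal(saccade_threshold(0.1, q), 10^(-4 * exp(-1)), tolerance = 1e-12)
  expect_equal(saccade_threshold(0, q), 1)
  expect_equal(saccade_threshold(1e6, q), 1e-4, tolerance = 1e-6)
  expect_error(saccade_timing_params(1, 0.1, -1), "q1")
  expect_error(saccade_timing_params(-1, -0.1, -1), "q2")
  expect_error(saccade_timing_params(-1, 0.1, 1), "q3")
})

test_that("bound is decreasing and confined to [10^q1, 1)", {
  set.seed(2)
  for (i in 1:25) {
    q <- saccade_timing_params(runif(1, -8, -0.5), runif(1, 0.01, 0.5),
                               runif(1, -4, -0.3))
    t <- seq(1e-4, 5, length.out = 300)
    th <- saccade_threshold(t, q)
    expect_true(all(diff(th) <= 0))
    expect_true(all(th >= 10^q$q1 & th <= 1))
    # strictly decreasing wherever neither limit has saturated numerically
    live <- th > 10^q$q1 * (1 + 1e-9) & th < 1 - 1e-12
    if (sum(live) > 2) expect_true(all(diff(th[live]) < 0))
  }
})

test_that("saccade trigger of a declining probability matches the crossing", {
  # the attended probability decays while the bound collapses; the stepped
  # 1-ms rule must fire within one step of the exact crossing time
  q <- saccade_timing_params(-4, 0.02, -1.2)
  for (par in list(c(p0 = 2.5e-3, rate = 15), c(p0 = 1e-2, rate = 25),
                   c(p0 = 5e-3, rate = 8))) {
    pfun <- function(t) par[["p0"]] * exp(-par[["rate"]] * t)
    root <- uniroot(function(t) pfun(t) - saccade_threshold(t, q),
                    c(0.06, 50), tol = 1e-12)$root
    tg <- seq(0.06, 50, by = 0.001)  # evaluation deferred to the lag
    stepped <- tg[which(should_saccade(pfun(tg), tg, q))[1]]
    expect_lt(abs(stepped - root), 0.001 + 1e-9)
  }
  # a probability already below the bound at evaluation onset fires there
  expect_true(should_saccade(1e-6, 0.06, q))
  expect_false(any(should_saccade(1, seq(0.001, 10, 0.001), q)))
  expect_true(should_saccade(0, 0.5, q))
})

test_that("saccade-type sampling: first normal, express fraction 3%", {
  q <- saccade_timing_params(-4, 0.1, -1)
  set.seed(3)
  first <- replicate(300, sample_saccade_type(2, q, first = TRUE)[1])
  expect_true(all(first == "normal"))
  set.seed(4)
  frac <- mean(sample_saccade_type(1e5, q, first = FALSE) == "express")
  expect_lt(abs(frac - 0.03), 0.002)
  q0 <- saccade_timing_params(-4, 0.1, -1, express_fraction = 0)
  expect_true(all(sample_saccade_type(1000, q0, first = FALSE) == "normal"))
})

test_that("express latency distribution", {
  q <- saccade_timing_params(-4, 0.1, -1)
  set.seed(5)
  lat <- sample_express_latency(1e5, q)
  expect_true(all(lat > 0.03))
  expect_lt(abs(mean(lat) - 0.099), 0.0015)
})

test_that("expected information gain formula", {
  dead <- visibility_field(1e-10, 0.3, 10, 0.2, 1)
  P <- uniform_posterior(grid100$n)
  expect_lt(expected_info_gain(P, c(0, 0), grid100, dead), 1e-6)
  # delta posterior: gain is half the squared visibility of that location,
  # maximized by fixating it for a radially decreasing field
  j <- which.max(rowSums(grid100$xy^2) * -1)  # a central node
  Pd <- numeric(grid100$n); Pd[j] <- 1
  gains <- vapply(seq_len(grid100$n), function(c)
    expected_info_gain(Pd, grid100$xy[c, ], grid100, default_field), 0)
  expect_equal(which.max(gains), j)
  d2 <- dprime_at(0, 0, 0.25, default_field)^2
  expect_equal(gains[j], 0.5 * d2, tolerance = 1e-9)
})

test_that("fixation selection agrees with exhaustive search", {
  set.seed(6)
  sel <- selection_params(mode = "elm")
  for (rep in 1:25) {
    lp <- rnorm(grid100$n, 0, 3)
    P <- exp(lp - max(lp)); P <- P / sum(P)
    pick <- select_next_fixation(P, c(0, 0), grid100, default_field, sel)
    gains <- vapply(seq_len(grid100$n), function(c)
      expected_info_gain(P, grid100$xy[c, ], grid100, default_field), 0)
    expect_equal(gains[pick], max(gains), tolerance = 1e-9)
  }
  # uniform posterior on a symmetric field: the most central node wins
  fld <- visibility_field(default_field$p1, default_field$p2,
                          default_field$p3, default_field$p4, 1)
  P <- uniform_posterior(grid100$n)
  pick <- select_next_fixation(P, c(3, 3), grid100, fld, sel)
  gains <- vapply(seq_len(grid100$n), function(c)
    expected_info_gain(P, grid100$xy[c, ], grid100, fld), 0)
  expect_equal(gains[pick], max(gains), tolerance = 1e-9)
})

test_that("amplitude penalty reweights the selection", {
  # three candidates with gains 1.0/0.9/0.5 at distances 8/2/1 deg and c = 4:
  # penalized scores e^-2, 0.9 e^-0.5, 0.5 e^-0.25 -> second candidate wins
  g <- grid100
  g$xy <- rbind(c(8, 0), c(2, 0), c(1, 0))
  g$n <- 3
  gm <- 2 * rbind(c(1.0, 0.9, 0.5), 0, 0)  # gains via P = (1,0,0)
  P <- c(1, 0, 0)
  pick <- select_next_fixation(P, c(0, 0), g, default_field,
                               selection_params(c = 4, mode = "penalized"),
                               gain_matrix = gm)
  expect_equal(pick, 2L)
  # c -> Inf restores the unpenalized choice
  pick2 <- select_next_fixation(P, c(0, 0), g, default_field,
                                selection_params(c = Inf, mode = "penalized"),
                                gain_matrix = gm)
  expect_equal(pick2, 1L)
  # within 1 deg the penalty is flat: all-close candidates follow the gain
  g2 <- g; g2$xy <- rbind(c(0.9, 0), c(0.5, 0.3), c(0, 0.8))
  pick3 <- select_next_fixation(P, c(0, 0), g2, default_field,
                                selection_params(c = 2, mode = "penalized"),
                                gain_matrix = gm)
  expect_equal(pick3, 1L)
})

test_that("stopping rule is a strict threshold", {
  st <- stopping_params(0.952)
  expect_true(check_stop(0.96, st))
  expect_false(check_stop(0.952, st))
  expect_false(check_stop(0.3, st))
  expect_error(stopping_params(1.2), "theta_T")
})
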