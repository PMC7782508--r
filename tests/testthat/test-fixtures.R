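test_that("synthetic 2IFC detection trials follow the generating accuracy", {
  # a near-zero visibility field produces chance performance
  dead <- visibility_field(1e-8, 0.3, 10, 0.2, 1)
  cfg <- detection_config(field = dead,
                          locations = data.frame(x_deg = 0, y_deg = 0),
                          exposures = 0.25, n_per_cond = 2000, seed = 2)
  det <- make_detection_trials(cfg)
  p <- mean(det$trials$correct)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 2000))
  # foveal steady d' = 3 gives the closed-form 2IFC accuracy Phi(3/sqrt(2))
  cfg3 <- detection_config(locations = data.frame(x_deg = 0, y_deg = 0),
                           exposures = 1.0, n_per_cond = 2000, seed = 3)
  det3 <- make_detection_trials(cfg3)
  p3 <- mean(det3$trials$correct)
  expect_lt(abs(p3 - pnorm(3 / sqrt(2))), 3 * sqrt(0.017 / 2000) + 0.005)
})

test_that("aggregated d-prime samples recover the generating time course", {
  cfg <- detection_config(n_per_cond = 5000, seed = 5)
  det <- make_detection_trials(cfg)
  s <- det$samples
  truth <- dprime_at(s$x_deg, s$y_deg, s$exposure_s, cfg$field, floor = 0)
  keep <- truth < 3.2  # near-ceiling accuracy saturates the estimate
  expect_true(all(abs(s$dprime[keep] - truth[keep]) < 0.15))
})

test_that("detection samples support the visibility-field fitting path", {
  cfg <- detection_config(n_per_cond = 2500, seed = 6)
  det <- make_detection_trials(cfg)
  fit <- fit_visibility_field(det$samples, n_starts = 12, seed = 1)
  steady_true <- cfg$field$p1 / sqrt(cfg$field$p3)
  steady_fit <- coef(fit)[["p1"]] / sqrt(coef(fit)[["p3"]])
  expect_lt(abs(steady_fit - steady_true) / steady_true, 0.15)
})

test_that("presets carry the printed constants and provenance flags", {
  pre <- default_presets(grid = grid100)
  cc <- pre[["cctelm-default"]]
  expect_equal(cc$stopping$theta_T, 0.952)
  expect_equal(cc$stopping$provenance, "published")
  expect_equal(cc$memory$M, 8)
  expect_equal(cc$memory$provenance, "published")
  expect_equal(cc$landing$sd_slope, 0.0453)
  expect_equal(cc$landing$bias_slope, 0.1195)
  expect_equal(cc$timing$express_fraction, 0.03)
  expect_equal(cc$timing$eye_brain_lag, 0.06)
  expect_equal(cc$visibility$provenance, "placeholder")
  expect_equal(cc$timing$provenance, "placeholder")
  # placeholder visibility realizes the foveal design point d' = 3.0
  expect_equal(cc$visibility$p1 / sqrt(cc$visibility$p3), 3.0,
               tolerance = 1e-9)
  expect_false(pre[["elm-default"]]$landing$enabled)
})

test_that("model configurations round-trip through YAML", {
  m <- search_model("cctelm", grid = grid100)
  path <- tempfile(fileext = ".yaml")
  write_model_config(m, path)
  cfg <- read_model_config(path)
  m2 <- as_search_model(cfg)
  expect_equal(m2$field, m$field)
  expect_equal(m2$timing, m$timing)
  expect_equal(m2$stopping$theta_T, m$stopping$theta_T)
  expect_equal(m2$memory, m$memory)
  expect_equal(m2$selection$c, m$selection$c)
  # simulations from the reloaded model are identical
  expect_identical(simulate(m, nsim = 2, seed = 4)$trials,
                   simulate(m2, nsim = 2, seed = 4)$trials)
})

test_that("config validation names the failing field", {
  m <- search_model("ctelm", grid = grid100)
  cfg <- as_model_config(m)
  path <- tempfile(fileext = ".yaml")
  bad <- cfg; bad$timing$q2 <- -1
  write_model_config(bad, path)
  expect_error(read_model_config(path), "timing\\$q2")
  bad2 <- cfg; bad2$visibility$p3 <- 0
  write_model_config(bad2, path)
  expect_error(read_model_config(path), "visibility\\$p3")
  bad3 <- cfg; bad3$stopping$theta_T <- 1.5
  write_model_config(bad3, path)
  expect_error(read_model_config(path), "theta_T")
})

test_that("command-line simulate runs are byte-identical and summarizable", {
  d1 <- tempfile(); d2 <- tempfile()
  dir.create(d1); dir.create(d2)
  run <- function(d) cli_main(c("simulate", "--model", "elm",
                                "--trials", "6", "--seed", "7",
                                "--events", file.path(d, "ev.csv"),
                                "--trials-out", file.path(d, "tr.csv")))
  expect_equal(run(d1), 0L, ignore_attr = TRUE)
  expect_equal(run(d2), 0L, ignore_attr = TRUE)
  expect_identical(readBin(file.path(d1, "ev.csv"), "raw", 1e6),
                   readBin(file.path(d2, "ev.csv"), "raw", 1e6))
  out <- file.path(d1, "hist.json")
  expect_equal(suppressMessages(
    cli_main(c("summarize", "--events", file.path(d1, "ev.csv"),
               "--out", out))), 0L, ignore_attr = TRUE)
  s <- summary_from_json(out)
  expect_equal(sum(s$duration), 1, tolerance = 1e-9)
  expect_equal(sum(s$amplitude), 1, tolerance = 1e-9)
})

test_that("command-line fixture generation and visibility fit", {
  d <- tempfile(); dir.create(d)
  expect_equal(suppressMessages(
    cli_main(c("make-fixtures", "--out-dir", d, "--seed", "3"))), 0L,
    ignore_attr = TRUE)
  expect_true(file.exists(file.path(d, "visibility_samples.csv")))
  expect_true(file.exists(file.path(d, "cctelm-default.yaml")))
  cfg <- read_model_config(file.path(d, "cctelm-default.yaml"))
  expect_equal(cfg$model, "cctelm")
  out <- file.path(d, "visfit.yaml")
  expect_equal(suppressMessages(
    cli_main(c("fit-visibility", "--samples",
               file.path(d, "visibility_samples.csv"),
               "--out", out, "--starts", "6"))), 0L, ignore_attr = TRUE)
  fitpar <- yaml::read_yaml(out)
  expect_true(all(c("p1", "p2", "p3", "p4", "p5") %in% names(fitpar)))
  # malformed input gives a nonzero exit with a diagnostic
  expect_message(
    bad <- cli_main(c("simulate", "--trials", "2", "--seed", "1",
                      "--events", file.path(d, "x.csv"))), "error")
  expect_equal(bad, 1L, ignore_attr = TRUE)
})
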