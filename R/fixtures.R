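#' Configuration of a synthetic detection experiment
#'
#' Describes the 2IFC detection task used to measure the visibility map: a
#' grid of retinal locations and exposure durations, with `n_per_cond`
#' Bernoulli trials per condition whose correct-response probability follows
#' the equal-variance signal-detection prediction
#' \eqn{P(correct) = \Phi(d'/\sqrt2)} at the generating d-prime.
#'
#' @param field generating [visibility_field()].
#' @param locations data frame with `x_deg`, `y_deg` and optional `weight`.
#' @param exposures exposure durations (s).
#' @param n_per_cond trials per location-exposure condition.
#' @param seed integer seed.
#' @return list of class `detection_config`.
#' @export
detection_config <- function(field = default_visibility_field(),
                             locations = data.frame(
                               x_deg = c(0, 1, 2.5, 4, 6, 0, 0),
                               y_deg = c(0, 0, 0, 0, 0, 2.5, -4),
                               weight = c(4, 4, 4, 3, 2, 3, 2)),
                             exposures = c(0.05, 0.1, 0.2, 0.4, 0.7),
                             n_per_cond = 200, seed = 1) {
  stopifnot(n_per_cond >= 1)
  structure(list(field = field, locations = locations, exposures = exposures,
                 n_per_cond = n_per_cond, seed = seed),
            class = "detection_config")
}

#' Generate synthetic 2IFC detection trials and aggregated d-prime samples
#'
#' @param cfg a [detection_config()].
#' @return list with `trials` (one row per trial: `x_deg`, `y_deg`,
#'   `exposure_s`, `interval_with_target`, `response_interval`, `correct`)
#'   and `samples` (aggregated per condition: `x_deg`, `y_deg`, `exposure_s`,
#'   `dprime`, `weight`), the latter directly usable by
#'   [fit_visibility_field()].
#' @export
make_detection_trials <- function(cfg = detection_config()) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  conds <- merge(cfg$locations, data.frame(exposure_s = cfg$exposures))
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    cd <- conds[i, ]
    dp <- dprime_at(cd$x_deg, cd$y_deg, cd$exposure_s, cfg$field, floor = 0)
    p <- pnorm(dp / sqrt(2))
    tgt <- sample(c(1L, 2L), cfg$n_per_cond, replace = TRUE)
    ok <- runif(cfg$n_per_cond) < p
    resp <- ifelse(ok, tgt, 3L - tgt)
    data.frame(x_deg = cd$x_deg, y_deg = cd$y_deg, exposure_s = cd$exposure_s,
               interval_with_target = tgt, response_interval = resp,
               correct = as.integer(ok),
               weight = cd$weight %||% 1)
  })
  trials <- do.call(rbind, rows)
  agg <- aggregate(correct ~ x_deg + y_deg + exposure_s + weight,
                   data = trials, FUN = mean)
  n <- cfg$n_per_cond
  pc <- pmin(pmax(agg$correct, 1 / (2 * n)), 1 - 1 / (2 * n))
  samples <- data.frame(x_deg = agg$x_deg, y_deg = agg$y_deg,
                        exposure_s = agg$exposure_s,
                        dprime = pmax(sqrt(2) * qnorm(pc), 0),
                        weight = agg$weight)
  list(trials = trials, samples = samples)
}

#' Generate synthetic contrast-threshold (psychometric) trials
#'
#' 2IFC trials whose correct-response probability follows a Weibull
#' psychometric curve of target RMS contrast; used to exercise
#' [fit_weibull()] offline.
#'
#' @param curve generating [psychometric_curve()].
#' @param contrasts contrast levels.
#' @param n_per_level trials per level.
#' @param seed integer seed.
#' @return data frame with `contrast`, `interval_with_target`,
#'   `response_interval`, `correct`.
#' @export
make_contrast_trials <- function(curve = psychometric_curve(0.08, 2.5),
                                 contrasts = c(0.03, 0.05, 0.07, 0.09, 0.12),
                                 n_per_level = 200, seed = 1) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  rows <- lapply(contrasts, function(C) {
    p <- weibull_rate(C, curve)
    tgt <- sample(c(1L, 2L), n_per_level, replace = TRUE)
    ok <- runif(n_per_level) < p
    data.frame(contrast = C, interval_with_target = tgt,
               response_interval = ifelse(ok, tgt, 3L - tgt),
               correct = as.integer(ok))
  })
  do.call(rbind, rows)
}

# ---- model configuration files --------------------------------------------

#' Serialize a search model to a validated configuration list
#'
#' Every parameter block carries a `provenance` field: `"published"` for printed
#' constants of the model family (express-saccade mixture, neural lags,
#' landing coefficients, the constrained variant's `theta_T` and memory) and
#' `"placeholder"` for values this package ships in lieu of fitted ones
#' (visibility field, bound parameters, penalty scale, the grid searchers'
#' `theta_T`), so simulation results are never silently attributed to fitted
#' values.
#'
#' @param model a `search_model`.
#' @param seed default simulation seed stored in the file.
#' @return a list of class `model_config`, ready for [write_model_config()].
#' @export
as_model_config <- function(model, seed = 1) {
  structure(list(
    model = model$kind,
    seed = seed,
    grid = list(n = model$grid$n, radius = model$grid$radius,
                layout = model$grid$layout, seed = 1,
                provenance = "published"),
    visibility = c(model$field[c("p1", "p2", "p3", "p4", "p5")],
                   list(dprime_floor = model$dprime_floor,
                        provenance = "placeholder")),
    timing = c(model$timing[c("q1", "q2", "q3")],
               list(provenance = "placeholder"),
               model$timing[c("express_fraction", "express_shape",
                              "express_scale", "express_delay",
                              "eye_brain_lag", "saccade_lag")],
               list(constants_provenance = "published")),
    selection = list(mode = model$selection$mode,
                     c = if (is.finite(model$selection$c)) model$selection$c
                     else "Inf",
                     expected_duration = model$selection$expected_duration,
                     provenance = "placeholder"),
    stopping = list(theta_T = model$stopping$theta_T,
                    provenance = if (model$kind == "cctelm") "published"
                    else "placeholder"),
    landing = c(model$landing[c("sd_slope", "sd_intercept", "bias_slope",
                                "bias_onset", "enabled")],
                list(provenance = "published")),
    memory = list(M = if (is.infinite(model$memory)) "Inf" else model$memory,
                  provenance = if (model$kind == "cctelm") "published"
                  else "placeholder"),
    limits = list(max_fixations = model$max_fixations, dt = model$dt)
  ), class = "model_config")
}

#' Write / read a model configuration as YAML
#'
#' `read_model_config()` validates every block on load (parameter signs,
#' ranges, required fields) and errors with the failing field's name.
#' Round-trips are lossless.
#'
#' @param cfg a `model_config` (or `search_model`, converted automatically).
#' @param path file path.
#' @return `write_model_config()`: the path, invisibly;
#'   `read_model_config()`: a validated `model_config`.
#' @export
write_model_config <- function(cfg, path) {
  if (inherits(cfg, "search_model")) cfg <- as_model_config(cfg)
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("model", "grid", "visibility", "timing", "selection", "stopping",
            "landing", "memory")
  for (f in need) if (is.null(cfg[[f]]))
    stop("config is missing required block: ", f)
  if (!cfg$model %in% c("elm", "ctelm", "cctelm"))
    stop("invalid field `model`: ", cfg$model)
  v <- cfg$visibility
  for (f in c("p1", "p2", "p3", "p4", "p5")) {
    if (is.null(v[[f]]) || !is.numeric(v[[f]]) || v[[f]] <= 0)
      stop("invalid field `visibility$", f, "`: must be a positive number")
  }
  tm <- cfg$timing
  if (is.null(tm$q1) || tm$q1 >= 0) stop("invalid field `timing$q1`: must be negative")
  if (is.null(tm$q2) || tm$q2 <= 0) stop("invalid field `timing$q2`: must be positive")
  if (is.null(tm$q3) || tm$q3 >= 0) stop("invalid field `timing$q3`: must be negative")
  th <- cfg$stopping$theta_T
  if (is.null(th) || th <= 0 || th >= 1)
    stop("invalid field `stopping$theta_T`: must be in (0, 1)")
  M <- cfg$memory$M
  if (!identical(M, "Inf") && (!is.numeric(M) || M < 1))
    stop("invalid field `memory$M`: must be a positive integer or \"Inf\"")
  structure(cfg, class = "model_config")
}

#' Instantiate a search model from a configuration
#'
#' @param cfg a `model_config` (from [read_model_config()]).
#' @return a `search_model`.
#' @export
as_search_model <- function(cfg) {
  v <- cfg$visibility
  tm <- cfg$timing
  sel_c <- cfg$selection$c
  if (identical(sel_c, "Inf")) sel_c <- Inf
  M <- cfg$memory$M
  if (identical(M, "Inf")) M <- Inf
  search_model(
    kind = cfg$model,
    field = visibility_field(v$p1, v$p2, v$p3, v$p4, v$p5),
    timing = saccade_timing_params(tm$q1, tm$q2, tm$q3,
                                   express_fraction = tm$express_fraction %||% 0.03,
                                   express_shape = tm$express_shape %||% 10,
                                   express_scale = tm$express_scale %||% 6.9e-3,
                                   express_delay = tm$express_delay %||% 0.03,
                                   eye_brain_lag = tm$eye_brain_lag %||% 0.06,
                                   saccade_lag = tm$saccade_lag %||% 0.03),
    selection = selection_params(c = sel_c,
                                 expected_duration =
                                   cfg$selection$expected_duration %||% 0.25,
                                 mode = cfg$selection$mode %||% "elm"),
    stopping = stopping_params(cfg$stopping$theta_T),
    landing = landing_model(sd_slope = cfg$landing$sd_slope %||% 0.0453,
                            sd_intercept = cfg$landing$sd_intercept %||% 0.364,
                            bias_slope = cfg$landing$bias_slope %||% 0.1195,
                            bias_onset = cfg$landing$bias_onset %||% 10,
                            enabled = isTRUE(cfg$landing$enabled)),
    memory = M,
    grid = generate_grid(cfg$grid$n %||% 400, cfg$grid$radius %||% 7.5,
                         seed = cfg$grid$seed %||% 1,
                         layout = cfg$grid$layout %||% "farthest-point"),
    dprime_floor = v$dprime_floor %||% 1e-4,
    max_fixations = cfg$limits$max_fixations %||% 600,
    dt = cfg$limits$dt %||% 1e-3)
}

#' Built-in model presets
#'
#' Three ready-to-simulate configurations (`elm-default`, `ctelm-default`,
#' `cctelm-default`).  Printed constants of the model family carry
#' `provenance = "published"`; every parameter that would require the original
#' fitted values carries `provenance = "placeholder"` and is tuned only to
#' the documented design points (foveal steady-state d' = 3.0, mean fixation
#' duration near 250 ms).
#'
#' @param grid optional shared `search_grid` (speeds up construction).
#' @return named list of `model_config` objects.
#' @export
default_presets <- function(grid = NULL) {
  g <- grid %||% generate_grid(400, 7.5, seed = 1)
  list(
    `elm-default` = as_model_config(search_model("elm", grid = g)),
    `ctelm-default` = as_model_config(search_model("ctelm", grid = g)),
    `cctelm-default` = as_model_config(search_model("cctelm", grid = g))
  )
}

# ---- histogram JSON --------------------------------------------------------

#' Serialize / load summary histograms as JSON
#'
#' Stores bin edges with each histogram so comparisons across files can check
#' bin compatibility.
#'
#' @param s a `search_summary`.
#' @param path file path.
#' @return `summary_to_json()`: the path, invisibly; `summary_from_json()`:
#'   a `search_summary` (histogram components).
#' @export
summary_to_json <- function(s, path) {
  obj <- list(
    n_trials = s$n_trials,
    duration = list(edges = s$bins$duration_edges, p = s$duration,
                    counts = s$duration_counts),
    amplitude = list(edges = s$bins$amplitude_edges, p = s$amplitude,
                     counts = s$amplitude_counts),
    distance = list(edges = s$bins$distance_edges, p = s$distance,
                    counts = s$distance_counts),
    duration_by_ordinal = s$duration_by_ordinal,
    amplitude_by_ordinal = s$amplitude_by_ordinal,
    distance_by_ordinal = s$distance_by_ordinal,
    location = s$location,
    bins = unclass(s$bins))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname summary_to_json
#' @export
summary_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bins <- do.call(histogram_bins, obj$bins[c("duration_edges",
                                             "amplitude_edges",
                                             "distance_edges", "px_per_deg",
                                             "smooth_sd", "n_ordinal")])
  structure(list(
    bins = bins, n_trials = obj$n_trials,
    duration = obj$duration$p, duration_counts = obj$duration$counts,
    amplitude = obj$amplitude$p, amplitude_counts = obj$amplitude$counts,
    distance = obj$distance$p, distance_counts = obj$distance$counts,
    duration_by_ordinal = as.matrix(obj$duration_by_ordinal),
    amplitude_by_ordinal = as.matrix(obj$amplitude_by_ordinal),
    distance_by_ordinal = as.matrix(obj$distance_by_ordinal),
    location = as.matrix(obj$location)
  ), class = "search_summary")
}
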