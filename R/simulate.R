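#' Simulate search trials
#'
#' Runs `nsim` independent trials of a [search_model()].  Each trial gets its
#' own random rotation of the predefined grid about the field center, a target
#' node drawn uniformly among the rotated locations, and a deterministic pair
#' of per-trial substream seeds derived from `seed` and the global trial
#' index, so a batch can be reproduced in chunks
#' (`simulate(m, 1000, seed)` followed by
#' `simulate(m, 1000, seed, trial_offset = 1000)` equals
#' `simulate(m, 2000, seed)` trial for trial).
#'
#' @param object a `search_model`.
#' @param nsim number of trials.
#' @param seed integer root seed.
#' @param trial_offset index offset of the first trial within the batch.
#' @param targets optional integer vector of target node indices (recycled);
#'   default: uniform random per trial.
#' @param rotate logical; rotate the grid per trial (default `TRUE`).
#' @param ... unused.
#' @return an object of class `search_trials`: a list with `trials` (one row
#'   per trial: target position, fixation count, correctness, truncation, and
#'   for the continuous-time searchers the attended probability and covered
#'   node count at the stopping decision),
#'   `fixations` (one row per fixation: position, onset, duration, incoming
#'   saccade type and amplitude) and the generating `model`.
#' @export
simulate.search_model <- function(object, nsim = 1, seed = 1,
                                  trial_offset = 0, targets = NULL,
                                  rotate = TRUE, ...) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  trial_rows <- vector("list", nsim)
  fix_rows <- vector("list", nsim)
  for (j in seq_len(nsim)) {
    idx <- trial_offset + j
    ts <- trial_seeds(seed, idx)
    set.seed(ts["setup"])
    ang <- if (rotate) runif(1, 0, 2 * pi) else 0
    grid_rot <- rotate_grid(object$grid, ang)
    target <- if (is.null(targets)) sample.int(grid_rot$n, 1)
    else targets[(idx - 1) %% length(targets) + 1]
    res <- if (object$kind == "elm")
      run_trial_elm(object, grid_rot, target, ts["main"])
    else run_trial_ct(object, grid_rot, target, ts)
    res$trial$trial <- idx
    res$fix$trial <- idx
    trial_rows[[j]] <- res$trial
    fix_rows[[j]] <- res$fix
  }
  trials <- do.call(rbind, trial_rows)
  fixations <- do.call(rbind, fix_rows)
  # saccade amplitude/direction into each fixation
  fixations$amplitude <- NA_real_
  fixations$direction <- NA_real_
  same <- c(FALSE, fixations$trial[-1] == fixations$trial[-nrow(fixations)])
  dx <- c(NA, diff(fixations$x))
  dy <- c(NA, diff(fixations$y))
  fixations$amplitude[same] <- sqrt(dx[same]^2 + dy[same]^2)
  fixations$direction[same] <- atan2(dy[same], dx[same])
  structure(list(trials = trials, fixations = fixations, model = object,
                 seed = seed),
            class = "search_trials")
}

# discrete ELM trial: fixed-duration fixations, one evidence draw per
# location per fixation, decisions once per fixation
run_trial_elm <- function(model, grid, target, main_seed) {
  set.seed(main_seed)
  n <- grid$n
  d2mat <- dprime2_matrix(grid, model$field, T = model$elm_fix_duration,
                          floor = model$dprime_floor)
  tgt <- seq_len(n) == target
  logpost <- numeric(n)
  cur_node <- NA_integer_
  cur_xy <- c(0, 0)
  fx <- numeric(0); fy <- numeric(0); fnode <- integer(0)
  stopped <- FALSE; truncated <- FALSE; response <- NA_integer_
  repeat {
    fx <- c(fx, cur_xy[1]); fy <- c(fy, cur_xy[2]); fnode <- c(fnode, cur_node)
    dp2 <- if (!is.na(cur_node)) d2mat[, cur_node]
    else dprime_at(grid$xy[, 1] - cur_xy[1], grid$xy[, 2] - cur_xy[2],
                   model$elm_fix_duration, model$field,
                   floor = model$dprime_floor)^2
    W <- rnorm(n, ifelse(tgt, 0.5, -0.5), 1 / sqrt(dp2))
    logpost <- logpost + dp2 * W
    P <- normalize_log(logpost)
    if (!is.na(cur_node) && P[cur_node] > model$stopping$theta_T) {
      stopped <- TRUE; response <- cur_node
      break
    }
    if (length(fx) >= model$max_fixations) {
      truncated <- TRUE
      break
    }
    cur_node <- select_next_fixation(P, cur_xy, grid, model$field,
                                     model$selection, gain_matrix = d2mat)
    cur_xy <- grid$xy[cur_node, ]
  }
  nf <- length(fx)
  fix <- data.frame(fix_index = seq_len(nf), x = fx, y = fy,
                    node = fnode,
                    onset = (seq_len(nf) - 1) * model$elm_fix_duration,
                    duration = model$elm_fix_duration,
                    sacc_type = c(NA_character_,
                                  rep("normal", max(nf - 1, 0))),
                    stringsAsFactors = FALSE)
  trial <- data.frame(target_node = target,
                      target_x = grid$xy[target, 1],
                      target_y = grid$xy[target, 2],
                      response_node = response,
                      n_fix = nf,
                      correct = isTRUE(stopped) && !is.na(response) &&
                        response == target,
                      truncated = truncated,
                      stop_p_att = if (stopped) P[response] else NA_real_,
                      stop_att_nodes = NA_integer_)
  list(trial = trial, fix = fix)
}

# continuous-time trial: setup stream draws the express-saccade schedule,
# main stream feeds the compiled event loop
run_trial_ct <- function(model, grid, target, ts) {
  q <- model$timing
  nmax <- model$max_fixations + 2L
  set.seed(ts["setup"])
  ex <- as.integer(runif(nmax) < q$express_fraction)
  ex[1] <- 0L  # the first saccade of a trial is always normal
  lat <- sample_express_latency(nmax, q)
  if (!is.null(model$fixed_duration)) ex[] <- 0L
  set.seed(ts["main"])
  res <- run_ct_trial_cpp(
    grid_xy = grid$xy, target = as.integer(target),
    field = unlist(model$field[c("p1", "p2", "p3", "p4", "p5")]),
    dprime_floor = model$dprime_floor,
    qpar = c(q$q1, q$q2, q$q3),
    eye_brain_lag = q$eye_brain_lag, saccade_lag = q$saccade_lag,
    theta_T = model$stopping$theta_T,
    sel_c = model$selection$c,
    penalized = model$selection$mode == "penalized",
    expected_T = model$selection$expected_duration,
    memory_M = if (is.infinite(model$memory)) -1L else as.integer(model$memory),
    landing_enabled = isTRUE(model$landing$enabled),
    landing_par = c(model$landing$sd_slope, model$landing$sd_intercept,
                    model$landing$bias_slope, model$landing$bias_onset),
    field_radius = grid$radius,
    disc_attention = model$kind == "cctelm",
    window_radius = 0.5,
    sacc_express = ex, express_latency = lat,
    max_fixations = as.integer(model$max_fixations),
    dt = model$dt,
    max_time = 600,
    fixed_duration = model$fixed_duration %||% -1)
  nf <- res$n_fix
  type <- c(NA_character_, c("normal", "express")[res$fix_node_type[-1, 2] + 1])
  fix <- data.frame(fix_index = seq_len(nf),
                    x = res$fix[, 1], y = res$fix[, 2],
                    node = res$fix_node_type[, 1],
                    onset = res$fix[, 3], duration = res$fix[, 4],
                    sacc_type = type[seq_len(nf)],
                    stringsAsFactors = FALSE)
  trial <- data.frame(target_node = target,
                      target_x = grid$xy[target, 1],
                      target_y = grid$xy[target, 2],
                      response_node = res$response_node,
                      n_fix = nf,
                      correct = res$correct,
                      truncated = res$truncated,
                      stop_p_att = res$stop_p_att,
                      stop_att_nodes = res$stop_att_nodes)
  list(trial = trial, fix = fix)
}

#' @export
print.search_trials <- function(x, ...) {
  cat(sprintf("%d simulated %s trials (%d fixations)\n",
              nrow(x$trials), toupper(x$model$kind), nrow(x$fixations)))
  print(summary(x))
  invisible(x)
}

#' Batch summary of simulated trials
#'
#' @param object a `search_trials`.
#' @param ... unused.
#' @return a one-row data frame: correct-response rate, median and maximum
#'   fixation counts for correct and error trials, truncation count.
#' @export
summary.search_trials <- function(object, ...) {
  tr <- object$trials
  ok <- tr$correct
  data.frame(
    p_correct = mean(ok),
    median_fix_correct = if (any(ok)) median(tr$n_fix[ok]) else NA_real_,
    median_fix_error = if (any(!ok)) median(tr$n_fix[!ok]) else NA_real_,
    max_fix_correct = if (any(ok)) max(tr$n_fix[ok]) else NA_integer_,
    max_fix_error = if (any(!ok)) max(tr$n_fix[!ok]) else NA_integer_,
    n_truncated = sum(tr$truncated)
  )
}

#' Scan-path plot of one simulated trial
#'
#' @param x a `search_trials`.
#' @param trial trial index to draw.
#' @param ... passed to [plot()].
#' @export
plot.search_trials <- function(x, trial = x$trials$trial[1], ...) {
  f <- x$fixations[x$fixations$trial == trial, ]
  t <- x$trials[x$trials$trial == trial, ]
  R <- x$model$grid$radius
  plot(NA, xlim = c(-R, R), ylim = c(-R, R), asp = 1,
       xlab = "x (deg)", ylab = "y (deg)",
       main = sprintf("trial %d: %d fixations, %s", trial, nrow(f),
                      if (t$correct) "correct" else "error"), ...)
  th <- seq(0, 2 * pi, length.out = 200)
  lines(R * cos(th), R * sin(th), col = "grey50")
  lines(f$x, f$y, col = "steelblue")
  points(f$x, f$y, pch = 3, col = "steelblue")
  points(t$target_x, t$target_y, pch = 1, cex = 2, col = "red")
  points(f$x[nrow(f)], f$y[nrow(f)], pch = 3, col = "red", lwd = 2)
  invisible(x)
}

#' Write simulated trials to CSV files
#'
#' Events file: one row per fixation (`trial_id`, `model`, `fix_index`,
#' `x_deg`, `y_deg`, `onset_ms`, `duration_ms`, `next_saccade_type`).
#' Trials file: one row per trial.  Coordinates are in degrees, origin at the
#' field center, +x right, +y up.
#'
#' @param st a `search_trials`.
#' @param events_file,trials_file output paths.
#' @return invisibly, the two paths.
#' @export
write_events_csv <- function(st, events_file, trials_file = NULL) {
  f <- st$fixations
  nxt <- c(f$sacc_type[-1], NA)
  nxt[c(f$trial[-1] != f$trial[-nrow(f)], TRUE)] <- NA
  ev <- data.frame(trial_id = f$trial, model = st$model$kind,
                   fix_index = f$fix_index,
                   x_deg = f$x, y_deg = f$y,
                   onset_ms = round(f$onset * 1000, 3),
                   duration_ms = round(f$duration * 1000, 3),
                   next_saccade_type = nxt)
  write.csv(ev, events_file, row.names = FALSE)
  if (!is.null(trials_file)) {
    tr <- st$trials
    out <- data.frame(trial_id = tr$trial, target_x = tr$target_x,
                      target_y = tr$target_y, n_fixations = tr$n_fix,
                      correct = tr$correct, truncated = tr$truncated)
    write.csv(out, trials_file, row.names = FALSE)
  }
  invisible(c(events_file, trials_file))
}

#' Read an events CSV back into fixation/trial tables
#'
#' @param events_file path written by [write_events_csv()].
#' @return a list with `fixations` and `trials` data frames compatible with
#'   [summarize_trials()].
#' @export
read_events_csv <- function(events_file) {
  ev <- read.csv(events_file)
  fix <- data.frame(trial = ev$trial_id, fix_index = ev$fix_index,
                    x = ev$x_deg, y = ev$y_deg,
                    onset = ev$onset_ms / 1000,
                    duration = ev$duration_ms / 1000,
                    sacc_type = c(NA, head(ev$next_saccade_type, -1)))
  first <- !duplicated(ev$trial_id)
  fix$sacc_type[first] <- NA
  fix$amplitude <- NA_real_
  fix$direction <- NA_real_
  if (nrow(fix) > 1) {
    same <- c(FALSE, fix$trial[-1] == fix$trial[-nrow(fix)])
    dx <- c(NA, diff(fix$x)); dy <- c(NA, diff(fix$y))
    fix$amplitude[same] <- sqrt(dx[same]^2 + dy[same]^2)
    fix$direction[same] <- atan2(dy[same], dx[same])
  }
  trials <- data.frame(trial = unique(ev$trial_id))
  trials$n_fix <- as.vector(table(factor(ev$trial_id, trials$trial)))
  list(fixations = fix, trials = trials)
}
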