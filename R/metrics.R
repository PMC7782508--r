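#' Bhattacharyya coefficient and distance of two probability histograms
#'
#' \deqn{B_c(H_1, H_2) = \sum_i \sqrt{H_1(i) H_2(i)}, \qquad B_d = -\ln B_c.}
#' Both histograms must be probabilities over the same bins; empty bins
#' contribute zero.
#'
#' @param h1,h2 probability vectors over shared bins.
#' @return `bhattacharyya()`: the coefficient in \[0, 1\];
#'   `bhattacharyya_distance()`: \eqn{-\ln B_c}.
#' @examples
#' bhattacharyya(c(0.5, 0.5), c(0.25, 0.75))  # ~0.9659
#' @export
bhattacharyya <- function(h1, h2) {
  if (length(h1) != length(h2))
    stop("histograms must share the same bins")
  s1 <- sum(h1); s2 <- sum(h2)
  if (s1 <= 0 || s2 <= 0) return(0)
  if (abs(s1 - 1) > 1e-6 || abs(s2 - 1) > 1e-6)
    stop("histograms must be normalized to probabilities")
  min(sum(sqrt(h1 * h2)), 1)
}

#' @rdname bhattacharyya
#' @export
bhattacharyya_distance <- function(h1, h2) -log(bhattacharyya(h1, h2))

#' Fixation-noise metrics of raw gaze samples
#'
#' Two standard data-quality statistics of the gaze samples within one
#' fixation: the dispersion
#' \deqn{SD_{fix} = \sqrt{\sum_i [(x_i-\bar x)^2 + (y_i-\bar y)^2] / N}}
#' (population divisor) and the sample-to-sample jitter
#' \deqn{RMS_{fix} = \sqrt{\sum_i [(x_{i+1}-x_i)^2 + (y_{i+1}-y_i)^2] / (N-1)}.}
#'
#' @param samples data frame or matrix with columns `x`, `y` (deg).
#' @return list with `sd_fix` and `rms_fix`.
#' @export
fixation_noise <- function(samples) {
  x <- if (is.data.frame(samples)) samples$x else samples[, 1]
  y <- if (is.data.frame(samples)) samples$y else samples[, 2]
  n <- length(x)
  if (n < 2) stop("need at least 2 samples for the RMS statistic")
  sd_fix <- sqrt(sum((x - mean(x))^2 + (y - mean(y))^2) / n)
  rms_fix <- sqrt(sum(diff(x)^2 + diff(y)^2) / (n - 1))
  list(sd_fix = sd_fix, rms_fix = rms_fix)
}

#' Histogram binning configuration for eye-movement summaries
#'
#' The bin widths are configurable because any Bhattacharyya-based comparison
#' is bin-sensitive.  Defaults: fixation duration 0–1500 ms in 25-ms bins;
#' saccade amplitude 0–15 deg in 0.5-deg bins; fixation distance to center
#' 0–7.5 deg in 0.25-deg bins; 2-D location raster at `px_per_deg` pixels per
#' degree smoothed by a Gaussian window with SD `smooth_sd` degrees.
#'
#' @param duration_edges,amplitude_edges,distance_edges numeric bin-edge
#'   vectors (seconds / degrees / degrees).
#' @param px_per_deg raster resolution of the 2-D fixation-location density.
#' @param smooth_sd SD of the Gaussian smoothing window (deg).
#' @param n_ordinal number of per-ordinal histograms kept (default 20).
#' @return a list of class `histogram_bins`.
#' @export
histogram_bins <- function(duration_edges = seq(0, 1.5, by = 0.025),
                           amplitude_edges = seq(0, 15, by = 0.5),
                           distance_edges = seq(0, 7.5, by = 0.25),
                           px_per_deg = 42.86, smooth_sd = 0.35,
                           n_ordinal = 20) {
  structure(list(duration_edges = duration_edges,
                 amplitude_edges = amplitude_edges,
                 distance_edges = distance_edges,
                 px_per_deg = px_per_deg, smooth_sd = smooth_sd,
                 n_ordinal = n_ordinal),
            class = "histogram_bins")
}

hist_counts <- function(x, edges) {
  x <- x[is.finite(x) & x >= edges[1] & x <= edges[length(edges)]]
  if (length(x) == 0) return(numeric(length(edges) - 1))
  tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE),
                length(edges) - 1),
           nbins = length(edges) - 1)
}

as_prob <- function(counts) {
  s <- sum(counts)
  if (s > 0) counts / s else counts
}

# 2-D fixation-location density on a raster with separable Gaussian smoothing
location_density <- function(x, y, radius, px_per_deg, smooth_sd) {
  npx <- max(2L, ceiling(2 * radius * px_per_deg))
  edges <- seq(-radius, radius, length.out = npx + 1)
  ix <- pmin(findInterval(x, edges, rightmost.closed = TRUE), npx)
  iy <- pmin(findInterval(y, edges, rightmost.closed = TRUE), npx)
  keep <- ix >= 1 & iy >= 1
  H <- matrix(0, npx, npx)
  if (any(keep)) {
    tab <- table(factor(ix[keep], levels = 1:npx),
                 factor(iy[keep], levels = 1:npx))
    H <- matrix(as.numeric(tab), npx, npx)
  }
  sd_px <- smooth_sd * px_per_deg
  half <- max(1L, ceiling(3 * sd_px))
  kern <- exp(-0.5 * ((-half:half) / sd_px)^2)
  kern <- kern / sum(kern)
  # separable convolution by banded matrix products
  K <- matrix(0, npx, npx)
  for (d in -half:half) {
    idx <- seq_len(npx)
    j <- idx + d
    ok <- j >= 1 & j <= npx
    K[cbind(idx[ok], j[ok])] <- kern[d + half + 1]
  }
  S <- K %*% H %*% t(K)
  s <- sum(S)
  if (s > 0) S / s else S
}

#' Eye-movement summary histograms of simulated (or recorded) trials
#'
#' Computes the probability histograms used for model fitting and comparison,
#' applying the standard exclusion rules: the first fixation (at the field
#' center) and the last fixation (the response) are excluded from duration
#' histograms; the first fixation is excluded from location and distance
#' histograms; no fixation is excluded from per-trial fixation counts.
#' Per-ordinal histograms index fixations (and saccades) by their position
#' after the first saccade.  Also returns the conditional-mean curves linking
#' consecutive saccades (direction change vs amplitude, amplitude vs previous
#' amplitude) and the distance-to-target course over correct trials.
#'
#' @param st a `search_trials` object, or a list with `fixations` and
#'   `trials` data frames (as from [read_events_csv()]).
#' @param bins a [histogram_bins()].
#' @param which_trials `"all"`, `"correct"` or `"error"`.
#' @return an object of class `search_summary`.
#' @export
summarize_trials <- function(st, bins = histogram_bins(),
                             which_trials = c("all", "correct", "error")) {
  which_trials <- match.arg(which_trials)
  fx <- st$fixations
  tr <- st$trials
  if (which_trials != "all" && !is.null(tr$correct)) {
    keep_ids <- tr$trial[if (which_trials == "correct") tr$correct else !tr$correct]
    fx <- fx[fx$trial %in% keep_ids, , drop = FALSE]
    tr <- tr[tr$trial %in% keep_ids, , drop = FALSE]
  }
  nfix <- stats::ave(fx$trial, fx$trial, FUN = length)
  is_first <- fx$fix_index == 1
  is_last <- fx$fix_index == nfix
  ord <- fx$fix_index - 1L  # ordinal position after the first saccade

  dur <- fx$duration[!is_first & !is_last]
  dur_ord <- ord[!is_first & !is_last]
  dist <- sqrt(fx$x^2 + fx$y^2)[!is_first]
  dist_ord <- ord[!is_first]
  amp <- fx$amplitude[!is_first]
  amp_ord <- ord[!is_first]

  K <- bins$n_ordinal
  per_ordinal <- function(vals, ords, edges) {
    counts <- lapply(seq_len(K), function(j) hist_counts(vals[ords == j], edges))
    do.call(cbind, counts)
  }
  dur_counts <- hist_counts(dur, bins$duration_edges)
  amp_counts <- hist_counts(amp, bins$amplitude_edges)
  dist_counts <- hist_counts(dist, bins$distance_edges)

  # conditional-mean curves over consecutive saccades
  sameprev <- c(FALSE, fx$trial[-1] == fx$trial[-nrow(fx)])
  dirchg <- rep(NA_real_, nrow(fx))
  i2 <- which(sameprev & c(FALSE, sameprev[-length(sameprev)]))
  if (length(i2)) {
    d <- fx$direction[i2] - fx$direction[i2 - 1]
    dirchg[i2] <- abs(atan2(sin(d), cos(d)))
  }
  pair <- data.frame(amp1 = fx$amplitude[i2 - 1], amp2 = fx$amplitude[i2],
                     dir_change = dirchg[i2])

  # distance to target by ordinal, correct trials only
  dtt <- NULL
  if (!is.null(st$trials$target_x)) {
    ok_ids <- st$trials$trial[st$trials$correct]
    fo <- st$fixations[st$fixations$trial %in% ok_ids, , drop = FALSE]
    if (nrow(fo)) {
      tmap <- st$trials[match(fo$trial, st$trials$trial), ]
      d2t <- sqrt((fo$x - tmap$target_x)^2 + (fo$y - tmap$target_y)^2)
      o <- pmin(fo$fix_index, K + 1L)
      dtt <- tapply(d2t, factor(o, levels = seq_len(K + 1)), mean)
    }
  }

  structure(list(
    bins = bins,
    n_trials = nrow(tr),
    duration = as_prob(dur_counts), duration_counts = dur_counts,
    amplitude = as_prob(amp_counts), amplitude_counts = amp_counts,
    distance = as_prob(dist_counts), distance_counts = dist_counts,
    duration_by_ordinal = per_ordinal(dur, dur_ord, bins$duration_edges),
    amplitude_by_ordinal = per_ordinal(amp, amp_ord, bins$amplitude_edges),
    distance_by_ordinal = per_ordinal(dist, dist_ord, bins$distance_edges),
    location = location_density(fx$x[!is_first], fx$y[!is_first],
                                radius = 7.5, px_per_deg = bins$px_per_deg,
                                smooth_sd = bins$smooth_sd),
    fix_count = tabulate(pmin(tr$n_fix, 100), 100) /
      max(nrow(tr), 1),
    saccade_pairs = pair,
    dist_to_target_by_ordinal = dtt
  ), class = "search_summary")
}

#' @export
print.search_summary <- function(x, ...) {
  cat(sprintf("eye-movement summary of %d trials\n", x$n_trials))
  cat(sprintf("  durations: %d binned fixations; amplitudes: %d saccades\n",
              sum(x$duration_counts), sum(x$amplitude_counts)))
  invisible(x)
}

#' Count-weighted merge of two summaries
#'
#' Merging the summaries of two batches equals the summary of the pooled
#' batch (over the shared bins).
#'
#' @param s1,s2 `search_summary` objects with identical bins.
#' @return merged `search_summary` (histogram components only).
#' @export
merge_summaries <- function(s1, s2) {
  stopifnot(identical(s1$bins, s2$bins))
  out <- s1
  for (nm in c("duration", "amplitude", "distance")) {
    cc <- s1[[paste0(nm, "_counts")]] + s2[[paste0(nm, "_counts")]]
    out[[paste0(nm, "_counts")]] <- cc
    out[[nm]] <- as_prob(cc)
  }
  for (nm in c("duration_by_ordinal", "amplitude_by_ordinal",
               "distance_by_ordinal")) {
    out[[nm]] <- s1[[nm]] + s2[[nm]]
  }
  w1 <- s1$n_trials; w2 <- s2$n_trials
  out$location <- (s1$location * w1 + s2$location * w2) / (w1 + w2)
  out$fix_count <- (s1$fix_count * w1 + s2$fix_count * w2) / (w1 + w2)
  out$n_trials <- w1 + w2
  out
}

#' Timing-fit loss between a simulated and a target summary
#'
#' The continuous-time model is fitted on the fixation-duration histogram
#' alone (\eqn{Loss = B_d(T_{sim}, T_{target})}); the constrained variant adds
#' the saccade-amplitude term
#' (\eqn{Loss = B_d(T) + B_d(A)}).
#'
#' @param sim,target `search_summary` objects on the same bins.
#' @param kind `"ctelm"` or `"cctelm"`.
#' @return non-negative loss.
#' @export
loss_timing <- function(sim, target, kind = c("ctelm", "cctelm")) {
  kind <- match.arg(kind)
  loss <- bhattacharyya_distance(sim$duration, target$duration)
  if (kind == "cctelm")
    loss <- loss + bhattacharyya_distance(sim$amplitude, target$amplitude)
  loss
}

#' Genetic-algorithm configuration for the timing fit
#'
#' Scaled-down defaults; the full-scale settings of the original procedure
#' (population 150/200, 25 generations, 1000 trials per candidate) can be
#' requested explicitly.
#'
#' @param pop_size population size.
#' @param generations number of generations (0 returns the best of the random
#'   initial population).
#' @param n_trials simulated trials per candidate evaluation.
#' @param elite number of elites copied unchanged.
#' @param p_mutate per-gene mutation probability.
#' @param mutate_sd mutation SD as a fraction of the parameter range.
#' @param bounds matrix with rows `lower`/`upper` and columns
#'   `q1, q2, q3, c`.
#' @return list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 40, generations = 10, n_trials = 300,
                      elite = 2, p_mutate = 0.35, mutate_sd = 0.15,
                      bounds = rbind(lower = c(q1 = -8, q2 = 0.02, q3 = -6, c = 0.3),
                                     upper = c(q1 = -0.5, q2 = 0.4, q3 = -0.2, c = 12))) {
  structure(list(pop_size = pop_size, generations = generations,
                 n_trials = n_trials, elite = elite, p_mutate = p_mutate,
                 mutate_sd = mutate_sd, bounds = bounds),
            class = "ga_config")
}

#' Fit the saccade-timing parameters by a genetic algorithm
#'
#' Minimizes [loss_timing()] between target histograms and histograms
#' simulated with candidate bound parameters `(q1, q2, q3)` (plus the penalty
#' scale `c` for the constrained variant), using tournament selection,
#' uniform crossover and Gaussian mutation.  Each candidate is evaluated by
#' simulating `ga$n_trials` fresh trials.
#'
#' @param model a continuous-time `search_model` (kind `"ctelm"` or
#'   `"cctelm"`); its other components stay fixed.
#' @param target a `search_summary` of the data to fit (simulated or
#'   experimental).
#' @param ga a [ga_config()].
#' @param seed integer root seed.
#' @return object of class `timing_fit`: `par` (named vector), `loss`,
#'   `model` (the refitted model), `trace` (best loss per generation).
#' @export
fit_timing_params <- function(model, target, ga = ga_config(), seed = 1) {
  if (model$kind == "elm") stop("the discrete searcher has no timing parameters")
  npar <- if (model$kind == "cctelm") 4L else 3L
  lo <- ga$bounds["lower", seq_len(npar)]
  hi <- ga$bounds["upper", seq_len(npar)]
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  apply_par <- function(par) {
    m <- model
    m$timing$q1 <- par[1]; m$timing$q2 <- par[2]; m$timing$q3 <- par[3]
    if (npar == 4L) m$selection$c <- par[4]
    m
  }
  eval_seeds <- integer(0)
  evaluate <- function(par, eseed) {
    m <- apply_par(par)
    st <- simulate(m, nsim = ga$n_trials, seed = eseed)
    loss_timing(summarize_trials(st, target$bins), target, kind = model$kind)
  }

  pop <- matrix(runif(ga$pop_size * npar, rep(lo, each = ga$pop_size),
                      rep(hi, each = ga$pop_size)),
                nrow = ga$pop_size)
  gen_seed <- function(g) as.integer((seed * 1000 + g * 131) %% 214748329 + 7)
  fitness <- vapply(seq_len(ga$pop_size),
                    function(i) evaluate(pop[i, ], gen_seed(0) + i), 0)
  trace <- min(fitness)
  for (g in seq_len(ga$generations)) {
    newpop <- matrix(NA_real_, ga$pop_size, npar)
    ord <- order(fitness)
    ne <- min(ga$elite, ga$pop_size)
    newpop[seq_len(ne), ] <- pop[ord[seq_len(ne)], , drop = FALSE]
    for (i in seq(ne + 1, ga$pop_size)) {
      pick <- function() {
        cand <- sample.int(ga$pop_size, 2)
        cand[which.min(fitness[cand])]
      }
      pa <- pop[pick(), ]; pb <- pop[pick(), ]
      child <- ifelse(runif(npar) < 0.5, pa, pb)
      mut <- runif(npar) < ga$p_mutate
      child[mut] <- child[mut] + rnorm(sum(mut), 0,
                                       ga$mutate_sd * (hi - lo)[mut])
      newpop[i, ] <- pmin(pmax(child, lo), hi)
    }
    pop <- newpop
    fitness <- vapply(seq_len(ga$pop_size),
                      function(i) evaluate(pop[i, ], gen_seed(g) + i), 0)
    trace <- c(trace, min(fitness))
  }
  best <- which.min(fitness)
  par <- pop[best, ]
  names(par) <- c("q1", "q2", "q3", "c")[seq_len(npar)]
  structure(list(par = par, loss = fitness[best], model = apply_par(par),
                 trace = trace),
            class = "timing_fit")
}

#' @export
print.timing_fit <- function(x, ...) {
  cat("timing-parameter fit (genetic algorithm)\n")
  cat("  ", paste(sprintf("%s = %.4g", names(x$par), x$par), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  final loss = %.4g after %d generations\n", x$loss,
              length(x$trace) - 1))
  invisible(x)
}

#' @export
coef.timing_fit <- function(object, ...) object$par

#' Goodness-of-fit score of a summary against a target
#'
#' The averaged Bhattacharyya score used by the memory sweep: for duration,
#' distance-to-center and amplitude, the per-ordinal `B_c` values (first
#' `n_ordinal` positions with data on both sides) are averaged within each
#' metric; the 2-D fixation-location `B_c` is added; the final score is the
#' mean of the four metric scores.
#'
#' @param sim,target `search_summary` objects on the same bins.
#' @return list with the four metric scores and the combined `score`.
#' @export
summary_bc_score <- function(sim, target) {
  ord_score <- function(a, b) {
    vals <- vapply(seq_len(ncol(a)), function(j) {
      if (sum(a[, j]) == 0 || sum(b[, j]) == 0) return(NA_real_)
      bhattacharyya(as_prob(a[, j]), as_prob(b[, j]))
    }, 0)
    mean(vals, na.rm = TRUE)
  }
  s_dur <- ord_score(sim$duration_by_ordinal, target$duration_by_ordinal)
  s_dist <- ord_score(sim$distance_by_ordinal, target$distance_by_ordinal)
  s_amp <- ord_score(sim$amplitude_by_ordinal, target$amplitude_by_ordinal)
  s_loc <- bhattacharyya(as.vector(sim$location), as.vector(target$location))
  list(duration = s_dur, distance = s_dist, amplitude = s_amp,
       location = s_loc,
       score = mean(c(s_dur, s_dist, s_amp, s_loc)))
}

#' Memory-capacity sweep
#'
#' Evaluates the constrained model at a series of memory capacities against
#' target histograms and scores each capacity with [summary_bc_score()].
#' On targets generated by the model itself this is a capacity-recovery
#' procedure: the score peaks at the generating capacity.
#'
#' @param model a `"cctelm"` `search_model` (its `memory` field is swept).
#' @param target a `search_summary`.
#' @param capacities capacities to evaluate (default 2, 4, ..., 14, Inf).
#' @param n_trials simulated trials per capacity.
#' @param seed integer root seed.
#' @return object of class `memory_sweep`: data frame of per-capacity scores.
#' @export
memory_sweep <- function(model, target, capacities = c(seq(2, 14, 2), Inf),
                         n_trials = 5000, seed = 1) {
  rows <- lapply(seq_along(capacities), function(i) {
    m <- model
    m$memory <- capacities[i]
    st <- simulate(m, nsim = n_trials, seed = seed)
    sc <- summary_bc_score(summarize_trials(st, target$bins), target)
    data.frame(capacity = capacities[i], duration = sc$duration,
               distance = sc$distance, amplitude = sc$amplitude,
               location = sc$location, score = sc$score)
  })
  out <- do.call(rbind, rows)
  structure(list(scores = out, n_trials = n_trials),
            class = "memory_sweep")
}

#' @export
print.memory_sweep <- function(x, ...) {
  cat(sprintf("memory-capacity sweep (%d trials per capacity)\n", x$n_trials))
  print(x$scores, row.names = FALSE, digits = 4)
  best <- x$scores$capacity[which.max(x$scores$score)]
  cat(sprintf("  best capacity: %s\n", format(best)))
  invisible(x)
}

#' @export
plot.memory_sweep <- function(x, ...) {
  s <- x$scores
  cap <- ifelse(is.finite(s$capacity), s$capacity, max(s$capacity[is.finite(s$capacity)]) + 2)
  plot(cap, s$score, type = "b", xlab = "memory capacity (fixations)",
       ylab = "mean Bhattacharyya score", ...)
  invisible(x)
}

#' Bootstrap confidence interval of a Bhattacharyya coefficient
#'
#' Resamples trials with replacement on both sides, recomputes the overall
#' histogram of the chosen metric and its `B_c` each time, and returns the
#' 99% interval as mean +/- 2.576 x SD of the bootstrap values.
#'
#' @param a,b `search_trials` objects (or lists with `fixations`/`trials`).
#' @param metric `"duration"`, `"amplitude"` or `"distance"`.
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param seed integer seed.
#' @param bins a [histogram_bins()].
#' @return list with `bc` (replicates), `mean`, `sd`, `ci` (length 2).
#' @export
bootstrap_bc <- function(a, b, metric = c("duration", "amplitude", "distance"),
                         n_boot = 2000, seed = 1, bins = histogram_bins()) {
  metric <- match.arg(metric)
  if (n_boot < 2) stop("n_boot must be >= 2")
  edges <- switch(metric, duration = bins$duration_edges,
                  amplitude = bins$amplitude_edges,
                  distance = bins$distance_edges)
  vals_by_trial <- function(st) {
    fx <- st$fixations
    nfix <- stats::ave(fx$trial, fx$trial, FUN = length)
    v <- switch(metric,
      duration = ifelse(fx$fix_index > 1 & fx$fix_index < nfix,
                        fx$duration, NA),
      amplitude = ifelse(fx$fix_index > 1, fx$amplitude, NA),
      distance = ifelse(fx$fix_index > 1, sqrt(fx$x^2 + fx$y^2), NA))
    split(v[!is.na(v)], fx$trial[!is.na(v)])
  }
  va <- vals_by_trial(a); vb <- vals_by_trial(b)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  # common uniform draws index both sides, so two identical inputs give
  # B_c = 1 in every replicate while each side's marginal resampling
  # distribution is the ordinary bootstrap
  nmax <- max(length(va), length(vb))
  bc <- vapply(seq_len(n_boot), function(i) {
    u <- runif(nmax)
    ra <- unlist(va[ceiling(u[seq_along(va)] * length(va))], use.names = FALSE)
    rb <- unlist(vb[ceiling(u[seq_along(vb)] * length(vb))], use.names = FALSE)
    bhattacharyya(as_prob(hist_counts(ra, edges)),
                  as_prob(hist_counts(rb, edges)))
  }, 0)
  list(bc = bc, mean = mean(bc), sd = sd(bc),
       ci = mean(bc) + c(-1, 1) * 2.576 * sd(bc))
}

#' Correlation between approximated and realized information gain
#'
#' The fixation-selection rule scores each candidate with the Gaussian
#' approximation \eqn{\frac12 \sum_i P_i d'^2_{i,cand}} evaluated at the
#' expected fixation duration.  This routine measures, over posterior states
#' produced by the searcher itself, the Pearson correlation across candidate
#' locations between that approximation and the realized expected entropy
#' reduction estimated by Monte Carlo (drawing the hypothetical target from
#' the current posterior and the fixation's evidence from its closed-form
#' distribution).
#'
#' @param model a `search_model` (its visibility field, grid and selection
#'   settings are used).
#' @param n_states number of posterior states.
#' @param n_draws Monte-Carlo draws per candidate.
#' @param n_candidates number of candidate locations scored per state
#'   (sampled without replacement from the grid).
#' @param max_depth posterior states are taken after 1..`max_depth` fixations.
#' @param seed integer seed.
#' @return list with `correlations` (one per state) and their `mean`.
#' @export
info_gain_correlation <- function(model, n_states = 10, n_draws = 60,
                                  n_candidates = 150, max_depth = 8,
                                  seed = 1) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  grid <- model$grid
  n <- grid$n
  Texp <- model$selection$expected_duration
  d2mat <- dprime2_matrix(grid, model$field, T = Texp,
                          floor = model$dprime_floor)
  # per-candidate evidence moments (closed form at T = Texp)
  dx <- outer(grid$xy[, 1], grid$xy[, 1], "-")
  dy <- outer(grid$xy[, 2], grid$xy[, 2], "-")
  r <- sqrt(dx^2 + model$field$p5 * dy^2)
  A <- pmax(model$field$p1 * exp(-model$field$p2 * r), 1e-12)
  K <- model$field$p3 * exp(-model$field$p4 * r)
  Mn <- (1 - exp(-K * Texp)) / K                      # |mean| of W
  Vr <- (8 / A^2) * (1 - exp(-2 * K * Texp)) / (2 * K)  # var of W
  LLR <- A^2 / (2 + 2 * exp(-K * Texp))               # multiplier of W

  cors <- vapply(seq_len(n_states), function(s) {
    target <- sample.int(n, 1)
    depth <- sample.int(max_depth, 1)
    logpost <- numeric(n)
    cur <- sample.int(n, 1)
    for (f in seq_len(depth)) {
      mu <- ifelse(seq_len(n) == target, Mn[, cur], -Mn[, cur])
      W <- rnorm(n, mu, sqrt(Vr[, cur]))
      logpost <- logpost + LLR[, cur] * W
      P <- normalize_log(logpost)
      cur <- select_next_fixation(P, grid$xy[cur, ], grid, model$field,
                                  model$selection, gain_matrix = d2mat)
    }
    P <- normalize_log(logpost)
    H0 <- entropy(P)
    cands <- sample.int(n, min(n_candidates, n))
    approx_gain <- 0.5 * as.vector(crossprod(d2mat[, cands, drop = FALSE], P))
    real_gain <- vapply(cands, function(cc) {
      g <- numeric(n_draws)
      for (d in seq_len(n_draws)) {
        j <- sample.int(n, 1, prob = P)
        mu <- ifelse(seq_len(n) == j, Mn[, cc], -Mn[, cc])
        W <- rnorm(n, mu, sqrt(Vr[, cc]))
        g[d] <- H0 - entropy(normalize_log(logpost + LLR[, cc] * W))
      }
      mean(g)
    }, 0)
    cor(approx_gain, real_gain)
  }, 0)
  list(correlations = cors, mean = mean(cors))
}
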