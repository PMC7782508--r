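#' Saccade-timing parameters
#'
#' Parameters of the saccade-timing decision: the collapsing probability bound
#' \deqn{\log_{10}\theta_S(t) = q_1 \exp[-(t/q_2)^{q_3}]}
#' (with \eqn{q_1, q_3 < 0 < q_2}, so the bound falls monotonically from 1 at
#' t = 0+ to \eqn{10^{q_1}} as t grows), the express-saccade mixture (a fixed
#' fraction of saccades whose latency is drawn from a shifted gamma
#' distribution rather than from the bound process), and the two neural
#' conduction delays.
#'
#' @param q1 bound amplitude in log10 units (< 0).
#' @param q2 bound timescale (s, > 0).
#' @param q3 bound shape (< 0).
#' @param express_fraction fraction of express saccades (default 0.03).
#' @param express_shape,express_scale gamma parameters of the express latency
#'   (defaults 10 and 6.9e-3 s).
#' @param express_delay fixed delay added to the express latency (s, 0.03).
#' @param eye_brain_lag retina-to-cortex delay (s, default 0.06).
#' @param saccade_lag decision-to-eye-movement delay (s, default 0.03).
#' @return object of class `saccade_timing`.
#' @export
saccade_timing_params <- function(q1, q2, q3,
                                  express_fraction = 0.03,
                                  express_shape = 10,
                                  express_scale = 6.9e-3,
                                  express_delay = 0.03,
                                  eye_brain_lag = 0.06,
                                  saccade_lag = 0.03) {
  if (!(q1 < 0)) stop("q1 must be negative")
  if (!(q2 > 0)) stop("q2 must be positive")
  if (!(q3 < 0)) stop("q3 must be negative")
  if (express_fraction < 0 || express_fraction > 1)
    stop("express_fraction must be in [0, 1]")
  structure(list(q1 = q1, q2 = q2, q3 = q3,
                 express_fraction = express_fraction,
                 express_shape = express_shape,
                 express_scale = express_scale,
                 express_delay = express_delay,
                 eye_brain_lag = eye_brain_lag,
                 saccade_lag = saccade_lag),
            class = "saccade_timing")
}

#' Collapsing saccade bound
#'
#' @param t time since the start of the saccade-decision process (s, >= 0,
#'   vectorized).
#' @param q a [saccade_timing_params()].
#' @return probability threshold \eqn{\theta_S(t)} in \eqn{(10^{q_1}, 1]}.
#' @export
saccade_threshold <- function(t, q) {
  if (any(t < 0)) stop("t must be non-negative")
  10^(q$q1 * exp(-(t / q$q2)^q$q3))
}

#' Saccade decision rule
#'
#' A saccade is triggered when the probability of the target being at the
#' attended location has dropped below the collapsing bound.
#'
#' @param p_attend posterior probability at the attention location.
#' @param t time since the decision process started (s).
#' @param q a [saccade_timing_params()].
#' @return logical.
#' @export
should_saccade <- function(p_attend, t, q) {
  p_attend < saccade_threshold(t, q)
}

#' Draw saccade types (normal vs express)
#'
#' Express saccades occur with probability `q$express_fraction`, except that
#' the first saccade of a trial is always normal.
#'
#' @param n number of saccade ordinals to draw (ordinal 1 = first of a trial).
#' @param q a [saccade_timing_params()].
#' @param first is the first element the first saccade of a trial?
#' @return character vector of `"normal"` / `"express"`.
#' @export
sample_saccade_type <- function(n, q, first = TRUE) {
  type <- ifelse(runif(n) < q$express_fraction, "express", "normal")
  if (first && n >= 1) type[1] <- "normal"
  type
}

#' Draw express-saccade latencies
#'
#' Gamma(shape, scale) plus the fixed delay; with the defaults the latency has
#' mean 99 ms and support above 30 ms.
#'
#' @param n number of draws.
#' @param q a [saccade_timing_params()].
#' @return latencies in seconds.
#' @export
sample_express_latency <- function(n, q) {
  rgamma(n, shape = q$express_shape, scale = q$express_scale) + q$express_delay
}

#' Fixation-selection parameters
#'
#' @param c amplitude-penalty scale in degrees (`Inf` disables the penalty;
#'   must be positive).
#' @param expected_duration assumed duration of the next fixation when
#'   evaluating the expected information gain (s, default 0.25).
#' @param mode `"elm"` (pure information-gain maximization) or `"penalized"`.
#' @return object of class `selection_params`.
#' @export
selection_params <- function(c = Inf, expected_duration = 0.25,
                             mode = c("elm", "penalized")) {
  mode <- match.arg(mode)
  if (!(c > 0)) stop("penalty scale c must be positive")
  structure(list(c = c, expected_duration = expected_duration, mode = mode),
            class = "selection_params")
}

#' Stopping parameters
#'
#' @param theta_T target-detection threshold in (0, 1); the searcher reports
#'   the target when the attended probability exceeds it (strict inequality).
#' @return object of class `stopping_params`.
#' @export
stopping_params <- function(theta_T) {
  if (!(theta_T > 0 && theta_T < 1)) stop("theta_T must be in (0, 1)")
  structure(list(theta_T = theta_T), class = "stopping_params")
}

#' Stopping rule
#'
#' @param p_attend posterior probability at the attention location.
#' @param stop a [stopping_params()].
#' @return logical; `TRUE` when `p_attend > theta_T` (strict).
#' @export
check_stop <- function(p_attend, stop) {
  p_attend > stop$theta_T
}

# d'^2 of every grid location as seen from each candidate fixation position.
# Rows: locations i; columns: candidates.  `cand_xy` defaults to the grid
# itself (candidates are the predefined locations).
dprime2_matrix <- function(grid, field, T = 0.25, cand_xy = NULL,
                           floor = 1e-4) {
  if (is.null(cand_xy)) cand_xy <- grid$xy
  dx <- outer(grid$xy[, 1], cand_xy[, 1], "-")
  dy <- outer(grid$xy[, 2], cand_xy[, 2], "-")
  r <- sqrt(dx^2 + field$p5 * dy^2)
  a <- field$p1 * exp(-field$p2 * r)
  k <- field$p3 * exp(-field$p4 * r)
  e <- exp(-k * T)
  d <- a * sqrt((1 - e) / (k * (1 + e)))
  pmax(d, floor)^2
}

#' Expected information gain of a candidate fixation
#'
#' The expected reduction in posterior entropy from fixating a candidate
#' location next, in the Gaussian-evidence approximation:
#' \deqn{\tfrac12 \sum_i P_i \, d'^2_{i,cand}}
#' with each location's d-prime evaluated from the candidate at the expected
#' fixation duration.
#'
#' @param P posterior vector over the grid locations.
#' @param candidate length-2 `(x, y)` of the candidate fixation (deg).
#' @param grid a `search_grid`.
#' @param field a [visibility_field()].
#' @param T expected next-fixation duration (s, default 0.25).
#' @return expected gain in nats (non-negative).
#' @export
expected_info_gain <- function(P, candidate, grid, field, T = 0.25) {
  d2 <- dprime_at(grid$xy[, 1] - candidate[1], grid$xy[, 2] - candidate[2],
                  T, field)^2
  0.5 * sum(P * d2)
}

#' Select the next fixation location
#'
#' Evaluates the expected information gain of every predefined location and
#' returns the index of the maximizer.  In `"penalized"` mode the gain is
#' multiplied by the saccadic cost factor
#' \deqn{H(L_f, L_{f+1}) = \exp(-\max[D, 1]/c)}
#' with `D` the distance from the current fixation (the penalty is flat within
#' 1 degree, leaving inhibition of return untouched).  Ties are broken by
#' smaller distance to the current fixation, then by lower index, so replays
#' are deterministic.
#'
#' @param P posterior vector.
#' @param current length-2 `(x, y)` of the current fixation (deg).
#' @param grid a `search_grid`.
#' @param field a [visibility_field()].
#' @param sel a [selection_params()].
#' @param gain_matrix optional precomputed matrix of squared visibilities
#'   (locations x candidates) evaluated at `sel$expected_duration`.
#' @return index of the chosen grid node.
#' @export
select_next_fixation <- function(P, current, grid, field, sel,
                                 gain_matrix = NULL) {
  if (is.null(gain_matrix))
    gain_matrix <- dprime2_matrix(grid, field, T = sel$expected_duration)
  gain <- 0.5 * as.vector(crossprod(gain_matrix, P))
  D <- sqrt((grid$xy[, 1] - current[1])^2 + (grid$xy[, 2] - current[2])^2)
  score <- if (sel$mode == "penalized" && is.finite(sel$c))
    exp(-pmax(D, 1) / sel$c) * gain else gain
  top <- which(score >= max(score) * (1 - 1e-12))
  if (length(top) > 1) top <- top[order(D[top], top)]
  top[1]
}
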