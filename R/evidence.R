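#' Per-fixation evidence draw for the discrete (ELM) searcher
#'
#' One normally distributed evidence sample per location per 250-ms fixation:
#' \eqn{N(+0.5, 1/d'^2)} when the target is present at the location and
#' \eqn{N(-0.5, 1/d'^2)} otherwise, so that the separation between the two
#' distributions in units of their common SD is exactly d-prime.
#'
#' @param target_present logical (vectorized).
#' @param dprime d-prime value(s); floored at `floor`.
#' @param floor minimum d-prime (keeps the variance finite).
#' @return evidence value(s), one per element.
#' @export
sample_elm_response <- function(target_present, dprime, floor = 1e-4) {
  dp <- pmax(dprime, floor)
  n <- max(length(target_present), length(dp))
  mu <- ifelse(rep_len(target_present, n), 0.5, -0.5)
  rnorm(n, mean = mu, sd = 1 / rep_len(dp, n))
}

#' Closed-form moments of the leaky accumulated evidence
#'
#' The leaky drift-diffusion accumulator integrates increments
#' \eqn{N(\pm\Delta t, (8/a^2)\Delta t)} with exponential forgetting at rate
#' `k`.  In the continuous-time limit the accumulated evidence at time `T`
#' is Gaussian with
#' \deqn{\mathrm{mean} = \pm (1 - e^{-kT})/k, \quad
#'       \mathrm{var} = (8/a^2)(1 - e^{-2kT})/(2k).}
#'
#' @param T elapsed time (s, vectorized).
#' @param tv a [temporal_visibility()] (or list with `a`, `k`).
#' @param target_present sign of the drift.
#' @return list with `mean` and `variance`.
#' @export
evidence_moments <- function(T, tv, target_present = TRUE) {
  if (any(T < 0)) stop("T must be non-negative")
  s <- ifelse(target_present, 1, -1)
  m <- s * (1 - exp(-tv$k * T)) / tv$k
  v <- (8 / tv$a^2) * (1 - exp(-2 * tv$k * T)) / (2 * tv$k)
  list(mean = m, variance = v)
}

#' One leaky-integration step of the per-millisecond evidence process
#'
#' Exact discrete recursion used by the continuous-time searchers:
#' \deqn{W \leftarrow \Delta W + W e^{-k \Delta t}, \quad
#'       \Delta W \sim N(\pm\Delta t, (8/a^2)\Delta t).}
#' Vectorized over locations; this is the R reference implementation of the
#' step performed inside the compiled trial loop.
#'
#' @param W current accumulated evidence per location.
#' @param target logical per location (TRUE where the target is).
#' @param a,k temporal-visibility parameters per location.
#' @param dt time step in seconds (default 0.001).
#' @param dW optional increment vector overriding the random draw (for exact
#'   decay checks).
#' @return updated evidence vector.
#' @export
step_accumulate <- function(W, target, a, k, dt = 0.001, dW = NULL) {
  n <- length(W)
  if (is.null(dW)) {
    mu <- ifelse(rep_len(target, n), dt, -dt)
    dW <- rnorm(n, mean = mu, sd = sqrt(8 * dt) / rep_len(a, n))
  }
  dW + W * exp(-rep_len(k, n) * dt)
}

#' Simulate final accumulated evidence for many independent paths
#'
#' Runs the per-millisecond recursion for `n_paths` independent replicates of a
#' single location and returns the evidence at time `T`.  Used to check the
#' stepped process against the closed-form moments.
#'
#' @param n_paths number of independent paths.
#' @param T total time (s).
#' @param tv a [temporal_visibility()].
#' @param target_present drift sign.
#' @param dt step size (s).
#' @return numeric vector of length `n_paths`.
#' @export
simulate_evidence_paths <- function(n_paths, T, tv, target_present = TRUE,
                                    dt = 0.001) {
  n_steps <- round(T / dt)
  decay <- exp(-tv$k * dt)
  mu <- if (target_present) dt else -dt
  sdv <- sqrt(8 * dt) / tv$a
  W <- numeric(n_paths)
  for (i in seq_len(n_steps)) {
    W <- rnorm(n_paths, mu, sdv) + W * decay
  }
  W
}
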