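#' Uniform prior over the predefined locations
#'
#' @param n number of locations.
#' @return probability vector of length `n` summing to 1.
#' @export
uniform_posterior <- function(n) rep(1 / n, n)

# normalize a vector of log-posterior terms with max-subtraction
normalize_log <- function(logp) {
  m <- max(logp)
  p <- exp(logp - m)
  p / sum(p)
}

#' One-fixation Bayesian update of the discrete (ELM) posterior
#'
#' \deqn{P_i \propto P_i^{prev} \exp(d_i'^2 W_i)}
#' computed in the log domain, so the recursion over fixations equals the
#' batch product form exactly up to floating point.
#'
#' @param P_prev posterior vector (normalized) before the fixation.
#' @param W evidence vector for the fixation (one draw per location).
#' @param dprime d-prime vector of each location as seen from the fixation.
#' @return updated, renormalized posterior vector.
#' @export
posterior_elm_update <- function(P_prev, W, dprime) {
  stopifnot(length(P_prev) == length(W), length(W) == length(dprime))
  normalize_log(log(P_prev) + dprime^2 * W)
}

#' Continuous-time posterior from a (possibly memory-limited) fixation buffer
#'
#' For each remembered fixation record the log-likelihood-ratio contribution of
#' location `i` is
#' \deqn{a_i^2 W_i / (2 + 2 e^{-T_f k_i})}
#' and the posterior is the normalized exponential of the summed contributions
#' over the last `min(M, F)` fixations (the current fixation plus up to
#' `M - 1` previous ones), times the uniform prior.
#'
#' @param buffer list of fixation records; each record is a list with numeric
#'   vectors `a`, `k`, `W` (per location) and scalar `T` (elapsed fixation
#'   evidence time, s).  Ordered oldest to newest.
#' @param M memory capacity in fixations including the current one
#'   (default `Inf`).
#' @param prior optional prior vector (default uniform).
#' @return normalized posterior vector.
#' @export
posterior_ct <- function(buffer, M = Inf, prior = NULL) {
  if (length(buffer) == 0) stop("empty fixation buffer")
  n <- length(buffer[[1]]$W)
  first <- if (is.finite(M)) max(1L, length(buffer) - as.integer(M) + 1L) else 1L
  expo <- numeric(n)
  for (f in first:length(buffer)) {
    rec <- buffer[[f]]
    expo <- expo + rec$a^2 * rec$W / (2 + 2 * exp(-rec$T * rec$k))
  }
  lp <- if (is.null(prior)) expo else expo + log(prior)
  normalize_log(lp)
}

#' Shannon entropy of a posterior map
#'
#' \eqn{H = -\sum_i P_i \ln P_i} in nats, with \eqn{0 \ln 0 = 0}.
#'
#' @param P normalized probability vector.
#' @return entropy in nats.
#' @export
entropy <- function(P) {
  nz <- P > 0
  -sum(P[nz] * log(P[nz]))
}

#' Posterior probability at an attention location
#'
#' For searchers restricted to the grid (`node` given) this is the single
#' node's posterior.  For the constrained searcher, whose fixations land
#' anywhere in the field, it is the summed posterior over all predefined
#' locations within `window` degrees of the attended point.
#'
#' @param P posterior vector over `grid$n` locations.
#' @param grid a `search_grid`.
#' @param point length-2 numeric `(x, y)` in degrees (ignored when `node`
#'   is given).
#' @param node optional grid-node index.
#' @param window window radius in degrees (default 0.5, boundary inclusive).
#' @return probability in \[0, 1\].
#' @export
attention_probability <- function(P, grid, point = NULL, node = NULL,
                                  window = 0.5) {
  if (!is.null(node)) return(P[node])
  idx <- window_nodes(grid, point[1], point[2], window)
  if (length(idx) == 0) {
    warning("no predefined locations within the attention window")
    return(0)
  }
  sum(P[idx])
}
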