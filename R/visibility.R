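#' Weibull psychometric curve
#'
#' Two-parameter Weibull psychometric function for a two-interval forced-choice
#' (2IFC) detection task, mapping target RMS contrast to the probability of a
#' correct response:
#' \deqn{f(C) = 0.5 + 0.5 [1 - \exp(-(C/C_T)^s)]}
#' so that performance rises from chance (0.5) to 1.
#'
#' @param threshold threshold RMS contrast \eqn{C_T} (in (0,1)).
#' @param steepness steepness parameter \eqn{s} (> 0).
#' @return an object of class `psychometric_curve`.
#' @export
psychometric_curve <- function(threshold, steepness) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("`threshold` (C_T) must be positive")
  if (!is.numeric(steepness) || steepness <= 0)
    stop("`steepness` (s) must be positive")
  structure(list(threshold = threshold, steepness = steepness),
            class = "psychometric_curve")
}

#' @export
print.psychometric_curve <- function(x, ...) {
  cat(sprintf("Weibull psychometric curve: C_T = %.4g, s = %.4g\n",
              x$threshold, x$steepness))
  invisible(x)
}

#' Detection rate at a given contrast
#'
#' @param C RMS contrast (non-negative, vectorized).
#' @param curve a [psychometric_curve()].
#' @return detection rate(s) in \[0.5, 1\].
#' @examples
#' weibull_rate(0.08, psychometric_curve(0.08, 2.5))  # 0.5 + 0.5*(1 - exp(-1))
#' @export
weibull_rate <- function(C, curve) {
  stopifnot(inherits(curve, "psychometric_curve"))
  if (any(C < 0)) stop("contrast must be non-negative")
  0.5 + 0.5 * (1 - exp(-(C / curve$threshold)^curve$steepness))
}

#' Maximum-likelihood Weibull fit to 2IFC detection trials
#'
#' Fits the Weibull psychometric curve by Bernoulli maximum likelihood to the
#' trial outcomes for one response class.  Hits are trials with the target in
#' the first interval; correct rejections are trials with the target in the
#' second interval (the observer answered "interval 2").
#'
#' @param trials data frame with columns `contrast`, `interval_with_target`
#'   (1 or 2) and either `correct` (0/1) or `response_interval`.
#' @param which `"hit"` or `"correct_rejection"`; `"all"` uses every trial.
#' @return an object of class `weibull_fit` with components `curve`
#'   (a [psychometric_curve()]), `logLik`, `n`, and `which`.
#' @export
fit_weibull <- function(trials, which = c("hit", "correct_rejection", "all")) {
  which <- match.arg(which)
  trials <- as.data.frame(trials)
  if (is.null(trials$correct)) {
    if (is.null(trials$response_interval))
      stop("`trials` needs a `correct` or `response_interval` column")
    trials$correct <- as.integer(trials$response_interval ==
                                   trials$interval_with_target)
  }
  keep <- switch(which,
    hit = trials$interval_with_target == 1,
    correct_rejection = trials$interval_with_target == 2,
    all = rep(TRUE, nrow(trials)))
  tr <- trials[keep, , drop = FALSE]
  if (length(unique(tr$contrast)) < 2)
    stop("non-identifiable: need at least 2 distinct contrast levels")
  if (all(tr$correct == 1))
    stop("non-identifiable: all trials correct (likelihood unbounded)")
  if (all(tr$correct == 0))
    stop("non-identifiable: all trials incorrect")
  y <- tr$correct
  C <- tr$contrast
  nll <- function(par) {
    cv <- psychometric_curve(exp(par[1]), exp(par[2]))
    p <- pmin(pmax(weibull_rate(C, cv), 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  # moment-style start: threshold near the contrast with ~82% correct
  p_emp <- tapply(y, C, mean)
  lev <- as.numeric(names(p_emp))
  c0 <- lev[which.min(abs(p_emp - 0.816))]
  fit <- optim(c(log(c0), log(2)), nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  curve <- psychometric_curve(exp(fit$par[1]), exp(fit$par[2]))
  structure(list(curve = curve, logLik = -fit$value, n = nrow(tr),
                 which = which, convergence = fit$convergence),
            class = "weibull_fit")
}

#' @export
coef.weibull_fit <- function(object, ...) {
  c(threshold = object$curve$threshold, steepness = object$curve$steepness)
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull ML fit (%s trials, n = %d): C_T = %.4g, s = %.4g, logLik = %.2f\n",
              x$which, x$n, x$curve$threshold, x$curve$steepness, x$logLik))
  invisible(x)
}

#' @export
predict.weibull_fit <- function(object, newdata, ...) {
  C <- if (is.data.frame(newdata)) newdata$contrast else newdata
  weibull_rate(C, object$curve)
}

#' Sensitivity (d-prime) from 2IFC hit and correct-rejection rates
#'
#' Signal-detection conversion for the two-interval task:
#' \deqn{d' = [z(f_H) - z(1 - f_{CR})]/\sqrt{2}}
#' with \eqn{z} the inverse standard-normal CDF.  Rates of exactly 0 or 1 are
#' clamped to \eqn{1/(2N)} and \eqn{1 - 1/(2N)} (log-linear rule) with a
#' warning; `n_trials` supplies N (default 100 when unknown).
#'
#' @param hit_rate hit rate in (0, 1).
#' @param cr_rate correct-rejection rate in (0, 1).
#' @param n_trials trial count behind each rate, used only for clamping.
#' @return d-prime (vectorized).
#' @export
dprime_from_rates <- function(hit_rate, cr_rate, n_trials = 100) {
  clamp <- function(r) {
    lo <- 1 / (2 * n_trials)
    bad <- r <= 0 | r >= 1
    if (any(bad)) {
      warning("rate of exactly 0 or 1 clamped to 1/(2N)")
      r <- pmin(pmax(r, lo), 1 - lo)
    }
    r
  }
  h <- clamp(hit_rate)
  cr <- clamp(cr_rate)
  (qnorm(h) - qnorm(1 - cr)) / sqrt(2)
}

#' Temporal visibility parameters at one retinal location
#'
#' Container for the two parameters of the leaky-accumulation visibility time
#' course: `a` scales the asymptote and `k` is the leak rate, giving
#' steady-state \eqn{d' = a/\sqrt{k}}.
#'
#' @param a asymptote-scale parameter (units 1/sqrt(s)), non-negative.
#' @param k leak rate (1/s), positive.
#' @return object of class `temporal_visibility`.
#' @export
temporal_visibility <- function(a, k) {
  if (any(a < 0)) stop("`a` must be non-negative")
  if (any(k <= 0)) stop("`k` must be positive")
  structure(list(a = a, k = k), class = "temporal_visibility")
}

#' Visibility time course within a fixation
#'
#' \deqn{d'(T) = a \sqrt{ (1 - e^{-kT}) / (k (1 + e^{-kT})) }}
#' Rises from 0 at stimulus onset to the steady state \eqn{a/\sqrt{k}}.
#'
#' @param T exposure duration in seconds (non-negative, vectorized).
#' @param tv a [temporal_visibility()] (or a list with `a`, `k`).
#' @return d-prime value(s).
#' @export
dprime_timecourse <- function(T, tv) {
  if (any(T < 0)) stop("exposure must be non-negative")
  e <- exp(-tv$k * T)
  tv$a * sqrt((1 - e) / (tv$k * (1 + e)))
}

#' Spatial visibility-field parameters
#'
#' The five parameters of the spatiotemporal visibility map.  Both temporal
#' parameters decay exponentially with a vertically weighted eccentricity:
#' \deqn{a(x,y) = p_1 e^{-p_2 \sqrt{x^2 + p_5 y^2}}, \quad
#'       k(x,y) = p_3 e^{-p_4 \sqrt{x^2 + p_5 y^2}}}
#' `p5 > 1` expresses poorer vertical than horizontal visibility.
#'
#' @param p1 foveal `a` value (> 0).
#' @param p2 spatial decay rate of `a` (1/deg, > 0).
#' @param p3 foveal leak rate `k` (1/s, > 0).
#' @param p4 spatial decay rate of `k` (1/deg, > 0).
#' @param p5 vertical-anisotropy weight (> 0).
#' @return object of class `visibility_field`.
#' @export
visibility_field <- function(p1, p2, p3, p4, p5) {
  p <- c(p1 = p1, p2 = p2, p3 = p3, p4 = p4, p5 = p5)
  if (any(!is.finite(p)) || any(p <= 0))
    stop("all five visibility-field parameters must be strictly positive")
  structure(as.list(p), class = "visibility_field")
}

#' @export
print.visibility_field <- function(x, ...) {
  cat(sprintf("visibility field: a(0,0) = %.3g (decay %.3g/deg), k(0,0) = %.3g/s (decay %.3g/deg), p5 = %.3g\n",
              x$p1, x$p2, x$p3, x$p4, x$p5))
  cat(sprintf("  foveal steady-state d' = %.3g\n", x$p1 / sqrt(x$p3)))
  invisible(x)
}

#' Temporal visibility parameters at a retinal location
#'
#' @param x,y location relative to fixation, in degrees (vectorized).
#' @param field a [visibility_field()].
#' @return a [temporal_visibility()] with vector `a`, `k`.
#' @export
visibility_params_at <- function(x, y, field) {
  r <- sqrt(x^2 + field$p5 * y^2)
  temporal_visibility(a = field$p1 * exp(-field$p2 * r),
                      k = field$p3 * exp(-field$p4 * r))
}

#' d-prime at a retinal location and exposure
#'
#' Composition of the spatial field and the temporal course, floored at
#' `floor` so that evidence variances stay finite at extreme eccentricity.
#'
#' @param x,y location relative to fixation (deg).
#' @param T exposure (s).
#' @param field a [visibility_field()].
#' @param floor minimum returned d-prime.
#' @return d-prime values.
#' @export
dprime_at <- function(x, y, T, field, floor = 1e-4) {
  tv <- visibility_params_at(x, y, field)
  pmax(dprime_timecourse(T, tv), floor)
}

#' Fit the spatiotemporal visibility field to measured d-prime samples
#'
#' Minimizes the weighted mean squared error between predicted and measured
#' d-prime over the five field parameters.  The default one-stage fit uses the
#' per-sample weights exactly, with multi-start local optimization
#' (Latin-hypercube starts, L-BFGS-B within a bound box).  The two-stage
#' variant first fits `(a, k)` per measured location, then fits the two spatial
#' exponentials to those values.
#'
#' @param samples data frame with columns `x_deg`, `y_deg`, `exposure_s`,
#'   `dprime` and optionally `weight` (defaults to 1; normalized to mean 1).
#' @param method `"one-stage"` (default) or `"two-stage"`.
#' @param n_starts number of Latin-hypercube starts (default 32).
#' @param lower,upper bound boxes for `(p1, p2, p3, p4, p5)`.
#' @param seed integer seed for the starts.
#' @return object of class `visibility_fit`: `field` (a [visibility_field()]),
#'   `objective` (weighted MSE), `method`, `n`.
#' @export
fit_visibility_field <- function(samples, method = c("one-stage", "two-stage"),
                                 n_starts = 32,
                                 lower = c(0.05, 0.01, 0.05, 0.01, 0.05),
                                 upper = c(20, 5, 50, 5, 20),
                                 seed = 1) {
  method <- match.arg(method)
  samples <- as.data.frame(samples)
  need <- c("x_deg", "y_deg", "exposure_s", "dprime")
  if (!all(need %in% names(samples)))
    stop("`samples` must have columns ", paste(need, collapse = ", "))
  if (length(unique(samples$exposure_s)) < 2)
    stop("non-identifiable: need samples at >= 2 exposures")
  ecc <- round(sqrt(samples$x_deg^2 + samples$y_deg^2), 6)
  if (length(unique(ecc)) < 2)
    stop("non-identifiable: need samples at >= 2 eccentricities")
  w <- samples$weight %||% rep(1, nrow(samples))
  if (any(w <= 0)) stop("weights must be positive")
  w <- w / mean(w)

  obj <- function(logp) {
    p <- exp(logp)
    fld <- structure(list(p1 = p[1], p2 = p[2], p3 = p[3], p4 = p[4], p5 = p[5]),
                     class = "visibility_field")
    pred <- dprime_at(samples$x_deg, samples$y_deg, samples$exposure_s, fld,
                      floor = 0)
    mean(w * (pred - samples$dprime)^2)
  }

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  llo <- log(lower); lup <- log(upper)
  starts <- lhs::randomLHS(n_starts, 5)
  starts <- sweep(sweep(starts, 2, lup - llo, "*"), 2, llo, "+")

  if (method == "two-stage") {
    # stage 1: (a, k) per measured location
    key <- interaction(samples$x_deg, samples$y_deg, drop = TRUE)
    locfit <- lapply(split(samples, key), function(d) {
      f <- function(q) {
        tv <- list(a = exp(q[1]), k = exp(q[2]))
        wt <- (d$weight %||% rep(1, nrow(d)))
        sum(wt * (dprime_timecourse(d$exposure_s, tv) - d$dprime)^2)
      }
      o <- optim(c(log(max(mean(d$dprime), 0.05)), log(5)), f,
                 method = "Nelder-Mead", control = list(maxit = 1000))
      c(x = d$x_deg[1], y = d$y_deg[1], a = exp(o$par[1]), k = exp(o$par[2]),
        w = sum(d$weight %||% rep(1, nrow(d))))
    })
    lf <- do.call(rbind, locfit)
    # stage 2: spatial exponentials on the per-location (a, k)
    obj2 <- function(logp) {
      p <- exp(logp)
      r <- sqrt(lf[, "x"]^2 + p[5] * lf[, "y"]^2)
      pa <- p[1] * exp(-p[2] * r)
      pk <- p[3] * exp(-p[4] * r)
      sum(lf[, "w"] * ((pa - lf[, "a"])^2 + (pk - lf[, "k"])^2))
    }
    best <- NULL
    for (s in seq_len(n_starts)) {
      o <- try(optim(starts[s, ], obj2, method = "L-BFGS-B",
                     lower = llo, upper = lup,
                     control = list(maxit = 500)), silent = TRUE)
      if (!inherits(o, "try-error") && (is.null(best) || o$value < best$value))
        best <- o
    }
    p <- exp(best$par)
    fld <- visibility_field(p[1], p[2], p[3], p[4], p[5])
    val <- obj(log(p))  # report the weighted d' MSE for comparability
  } else {
    best <- NULL
    for (s in seq_len(n_starts)) {
      o <- try(optim(starts[s, ], obj, method = "L-BFGS-B",
                     lower = llo, upper = lup,
                     control = list(maxit = 500, factr = 1e4)), silent = TRUE)
      if (!inherits(o, "try-error") && (is.null(best) || o$value < best$value))
        best <- o
    }
    # polish the winner
    o <- optim(best$par, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
    if (o$value < best$value) best <- o
    p <- exp(best$par)
    fld <- visibility_field(p[1], p[2], p[3], p[4], p[5])
    val <- best$value
  }
  structure(list(field = fld, objective = val, method = method,
                 n = nrow(samples)),
            class = "visibility_fit")
}

#' @export
coef.visibility_fit <- function(object, ...) {
  unlist(object$field[c("p1", "p2", "p3", "p4", "p5")])
}

#' @export
print.visibility_fit <- function(x, ...) {
  cat(sprintf("visibility-field fit (%s, %d samples), weighted MSE = %.4g\n",
              x$method, x$n, x$objective))
  print(x$field)
  invisible(x)
}

#' @export
predict.visibility_fit <- function(object, newdata, ...) {
  dprime_at(newdata$x_deg, newdata$y_deg, newdata$exposure_s, object$field,
            floor = 0)
}
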