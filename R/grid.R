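#' Predefined fixation-location grid
#'
#' Builds the set of `n` quasi-uniform candidate locations inside the circular
#' search field on which the searcher's belief is defined.  The default layout
#' is greedy farthest-point (maximin) sampling from a dense uniform candidate
#' pool: each location is placed at the candidate point farthest from all
#' locations placed so far.  This produces a blue-noise arrangement with
#' near-uniform density and reports its realized minimum spacing.  A
#' deterministic sunflower (Fermat spiral) layout is available as an
#' alternative.
#'
#' @param n number of locations (default 400).
#' @param radius field radius in degrees (default 7.5, a 15-degree field).
#' @param seed integer seed for the candidate pool (farthest-point layout).
#' @param layout `"farthest-point"` (default) or `"sunflower"`.
#' @param n_candidates size of the uniform candidate pool.
#' @return an object of class `search_grid`: a list with `xy` (n x 2 matrix of
#'   coordinates in degrees, origin at the field center), `n`, `radius`,
#'   `layout` and `min_spacing`.
#' @examples
#' g <- generate_grid(100, 7.5, seed = 1)
#' g$min_spacing
#' @export
generate_grid <- function(n = 400, radius = 7.5, seed = 1,
                          layout = c("farthest-point", "sunflower"),
                          n_candidates = 1e5) {
  stopifnot(n >= 1, radius > 0)
  layout <- match.arg(layout)
  if (n == 1) {
    xy <- matrix(0, 1, 2)
  } else if (layout == "sunflower") {
    i <- seq_len(n)
    golden <- pi * (3 - sqrt(5))
    r <- radius * sqrt((i - 0.5) / n)
    th <- i * golden
    xy <- cbind(r * cos(th), r * sin(th))
  } else {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    r <- radius * sqrt(runif(n_candidates))
    th <- runif(n_candidates, 0, 2 * pi)
    cx <- r * cos(th)
    cy <- r * sin(th)
    sel <- integer(n)
    sel[1] <- 1L
    d2 <- (cx - cx[1])^2 + (cy - cy[1])^2
    for (i in 2:n) {
      j <- which.max(d2)
      sel[i] <- j
      d2 <- pmin(d2, (cx - cx[j])^2 + (cy - cy[j])^2)
    }
    xy <- cbind(cx[sel], cy[sel])
  }
  colnames(xy) <- c("x", "y")
  ms <- if (n > 1) sqrt(min_spacing_sq(xy)) else NA_real_
  structure(list(xy = xy, n = n, radius = radius, layout = layout,
                 min_spacing = ms),
            class = "search_grid")
}

min_spacing_sq <- function(xy) {
  n <- nrow(xy)
  best <- Inf
  # chunked to keep memory bounded for large n
  for (i in split(seq_len(n), ceiling(seq_len(n) / 500))) {
    d2 <- outer(xy[i, 1], xy[, 1], "-")^2 + outer(xy[i, 2], xy[, 2], "-")^2
    d2[cbind(seq_along(i), i)] <- Inf
    best <- min(best, min(d2))
  }
  best
}

#' @export
print.search_grid <- function(x, ...) {
  cat(sprintf("search grid: %d locations in a %.1f-deg-radius field (%s layout)\n",
              x$n, x$radius, x$layout))
  cat(sprintf("  minimum pairwise spacing: %.3f deg\n", x$min_spacing))
  invisible(x)
}

#' Rotate a grid about the field center
#'
#' Per-trial random rotation of the predefined locations smooths the simulated
#' fixation-location distribution.
#'
#' @param grid a `search_grid`.
#' @param angle rotation angle in radians.
#' @return a `search_grid` with rotated coordinates.
#' @export
rotate_grid <- function(grid, angle) {
  ca <- cos(angle); sa <- sin(angle)
  xy <- cbind(grid$xy[, 1] * ca - grid$xy[, 2] * sa,
              grid$xy[, 1] * sa + grid$xy[, 2] * ca)
  colnames(xy) <- c("x", "y")
  grid$xy <- xy
  grid
}

# indices of grid nodes within `window` degrees of a point
window_nodes <- function(grid, x, y, window = 0.5) {
  which((grid$xy[, 1] - x)^2 + (grid$xy[, 2] - y)^2 <= window^2)
}

#' Attention-window coverage fractions
#'
#' Monte-Carlo estimate of how many predefined locations fall inside the
#' 0.5-degree attention window around a uniformly random point of the search
#' field.  The probability the searcher assigns to "target at the attended
#' point" is the summed posterior over these covered nodes, so the coverage
#' count distribution characterizes the grid geometry.
#'
#' @param grid a `search_grid`.
#' @param n_points Monte-Carlo sample size.
#' @param seed integer seed.
#' @param window window radius in degrees (default 0.5).
#' @return named numeric vector: percentage of points covering exactly
#'   0,1,2,3,4+ nodes.
#' @export
attention_window_fractions <- function(grid, n_points = 1e5, seed = 1,
                                       window = 0.5) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  r <- grid$radius * sqrt(runif(n_points))
  th <- runif(n_points, 0, 2 * pi)
  px <- r * cos(th); py <- r * sin(th)
  cnt <- integer(n_points)
  w2 <- window^2
  for (ch in split(seq_len(n_points), ceiling(seq_len(n_points) / 10000))) {
    d2 <- outer(px[ch], grid$xy[, 1], "-")^2 + outer(py[ch], grid$xy[, 2], "-")^2
    cnt[ch] <- rowSums(d2 <= w2)
  }
  tab <- tabulate(cnt + 1L, nbins = max(cnt) + 1L)
  out <- c(tab[1:4], sum(tab[-(1:4)])) * 100 / n_points
  names(out) <- c("0", "1", "2", "3", "4+")
  out
}
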