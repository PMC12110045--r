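#' Peak-finder configuration
#'
#' Hyperparameters of the momentum-based noisy peak finder and the
#' significance filter applied to the z-score-normalised divergence rate.
#' `eta` is expressed in units of the x-range rescaled to 1.
#'
#' @param eta positive step size of the momentum ascent.
#' @param mu momentum coefficient in `[0, 1)`.
#' @param eps convergence threshold on the ascent position.
#' @param alpha significance threshold: peaks with normalised height
#'   `<= alpha` are discarded.
#' @param max_iter ascent iteration cap (guarantees termination).
#' @return A list of class `peak_config`.
#' @export
peak_config <- function(eta = 0.05, mu = 0.9, eps = 1e-6, alpha = 1.0,
                        max_iter = 10000L) {
  stopifnot(eta > 0, mu >= 0, mu < 1, eps > 0, max_iter >= 1)
  structure(list(eta = eta, mu = mu, eps = eps, alpha = alpha,
                 max_iter = as.integer(max_iter)),
            class = "peak_config")
}

as_points <- function(points) {
  points <- as.data.frame(points)
  stopifnot(all(c("x", "y") %in% names(points)))
  stopifnot(all(is.finite(points$x)), all(is.finite(points$y)))
  if (is.unsorted(points$x, strictly = TRUE))
    stop("points must be sorted by strictly increasing x")
  points
}

# index of the point nearest to x (ties resolved to the lower index)
nearest_index <- function(xs, x) {
  i <- findInterval(x, xs, all.inside = TRUE)
  if (x - xs[i] > xs[i + 1] - x) i + 1L else i
}

#' All strict interior local maxima of a sampled signal
#'
#' Returns the points `i` with `y[i-1] < y[i] > y[i+1]` (strict
#' comparisons, so plateaus yield nothing); endpoints are never returned.
#'
#' @param points data frame with numeric columns `x` (strictly
#'   increasing) and `y`, at least 3 rows.
#' @return A data frame of the local-maximum points (possibly 0 rows).
#' @export
find_all_local_maxima <- function(points) {
  points <- as_points(points)
  n <- nrow(points)
  if (n < 3) stop("need at least 3 points")
  y <- points$y
  i <- 2:(n - 1)
  points[i[y[i - 1] < y[i] & y[i] > y[i + 1]], , drop = FALSE]
}

#' Piecewise-linear gradient of a sampled signal
#'
#' Finds the sample nearest to `x` and returns the slope of its forward
#' segment; at the last sample the preceding segment's slope is used.
#'
#' @param points data frame with columns `x` (sorted increasing) and `y`,
#'   at least 2 rows.
#' @param x query location.
#' @return The local slope (scalar).
#' @export
piecewise_gradient <- function(points, x) {
  points <- as_points(points)
  n <- nrow(points)
  if (n < 2) stop("need at least 2 points")
  o <- nearest_index(points$x, x)
  if (o == n) o <- n - 1L
  (points$y[o + 1] - points$y[o]) / (points$x[o + 1] - points$x[o])
}

#' Momentum ascent to the next local maximum
#'
#' Runs a discrete momentum ascent on the piecewise-linear signal
#' starting from `theta0`, in the explicit-velocity form: the gradient
#' is evaluated at the current position, the velocity update is
#' `v <- mu * v + eta * sign(grad)`, and the position update
#' `theta <- theta + v`.  Iteration stops when the position moves less
#' than `eps` (also detecting the period-2 oscillation that momentum
#' produces around an apex) or at the iteration cap.
#'
#' The gradient enters through its sign only, and the velocity is
#' clipped to the largest grid spacing: on a z-score-normalised
#' divergence series the piecewise slopes span many orders of magnitude
#' (saturated transition spikes against near-flat converged stretches),
#' so magnitude-weighted steps either stall below any convergence
#' threshold or catapult the iterate across the domain.  Sign-based
#' capped steps give a scale-free hill climb, which is also what makes
#' the finder insensitive to the step-size setting.  The position is
#' clamped to the sampled x-range; the returned value is the x of the
#' candidate maximum nearest the converged position (a period-2
#' oscillation ends between two samples, so candidates within half a
#' grid spacing of the nearest are treated as ties, resolved forward —
#' the direction the enclosing sweep proceeds in).
#'
#' @param points data frame with columns `x`, `y` (sorted increasing).
#' @param maxima candidate maxima, e.g. from [find_all_local_maxima()];
#'   must be non-empty.
#' @param theta0 starting x.
#' @param config a [peak_config()].
#' @return The x-coordinate of the reached candidate maximum.
#' @export
find_next_local_maximum <- function(points, maxima, theta0,
                                    config = peak_config()) {
  points <- as_points(points)
  if (nrow(maxima) < 1) stop("`maxima` must be non-empty")
  xs <- points$x
  ys <- points$y
  n <- length(xs)
  lo <- xs[1]; hi <- xs[n]
  step_cap <- max(diff(xs))
  grad_at <- function(x) {
    o <- nearest_index(xs, x)
    if (o == n) o <- n - 1L
    (ys[o + 1] - ys[o]) / (xs[o + 1] - xs[o])
  }
  theta <- theta0
  v <- 0
  theta_prev <- Inf
  theta_prev2 <- Inf
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    theta_prev2 <- theta_prev
    theta_prev <- theta
    v <- config$mu * v + config$eta * sign(grad_at(theta))
    v <- max(min(v, step_cap), -step_cap)
    theta <- max(min(theta + v, hi), lo)
    if (abs(theta - theta_prev) < config$eps ||
        abs(theta - theta_prev2) < config$eps) break
  }
  d <- abs(maxima$x - theta)
  cand <- which(d <= min(d) + step_cap / 2)
  max(maxima$x[cand])
}

#' Significant peaks of a divergence-rate series
#'
#' The full noisy peak finder: candidate maxima and minima are enumerated
#' on the (midpoint, normalised-rate) samples; the momentum ascent
#' ([find_next_local_maximum()]) is launched from each minimum in turn,
#' records the maximum it reaches, and the sweep then jumps to the next
#' minimum beyond that maximum, until the minima are exhausted.
#'
#' Ascent seeds are the *weak* local minima (plateau points included)
#' plus the left boundary of the series.  Strictly interpreted minima
#' would leave two kinds of peaks unreachable: a first peak that the
#' signal rises into monotonically, and any peak separated from the
#' previous one by an exactly flat stretch — both common in divergence
#' series of numerically converged codebook families, where the signal
#' is constant between transitions.  Candidate maxima remain strict.
#' Recorded maxima with normalised height `<= alpha` are then discarded.
#'
#' @param series a [divergence_series()], or any data frame with columns
#'   `x` and `y` (the y-values are then taken as already normalised).
#' @param config a [peak_config()].
#' @return An object of class `peak_set`: a data frame with columns `x`
#'   (critical parameter values, strictly increasing) and `height`
#'   (normalised heights, all `> alpha`).
#' @export
find_significant_peaks <- function(series, config = peak_config()) {
  points <- if (inherits(series, "divergence_series"))
    data.frame(x = series$t_mid, y = series$M_norm)
  else as_points(series)
  if (nrow(points) < 3) stop("need a series of at least 3 samples")
  # rescale x to [0, 1] so eta is in x-range units
  x0 <- points$x[1]
  xr <- diff(range(points$x))
  scaled <- data.frame(x = (points$x - x0) / xr, y = points$y)
  maxima <- find_all_local_maxima(scaled)
  minima <- find_all_local_maxima(transform(scaled, y = -y))
  recorded <- numeric(0)
  if (nrow(maxima) == 0) {
    # nothing to record
  } else if (nrow(minima) == 0) {
    warning("no interior minima: falling back to plain local-maxima filter")
    recorded <- maxima$x
  } else {
    y <- scaled$y
    nn <- length(y)
    weak <- 1L + which(y[2:(nn - 1)] <= y[1:(nn - 2)] &
                       y[2:(nn - 1)] <= y[3:nn])
    seeds <- scaled$x[weak]
    if (!length(seeds) || seeds[1] > scaled$x[1])
      seeds <- c(scaled$x[1], seeds)
    i <- 1L
    theta <- seeds[i]
    repeat {
      m <- find_next_local_maximum(scaled, maxima, theta, config)
      recorded <- c(recorded, m)
      nxt <- which(seeds > m & seq_along(seeds) > i)
      if (length(nxt) == 0) break
      i <- nxt[1]
      theta <- seeds[i]
    }
    recorded <- sort(unique(recorded))
  }
  idx <- match(recorded, scaled$x)
  heights <- scaled$y[idx]
  keep <- heights > config$alpha
  structure(data.frame(x = points$x[idx[keep]],
                       height = heights[keep]),
            class = c("peak_set", "data.frame"))
}

#' @export
print.peak_set <- function(x, ...) {
  cat("Significant peaks:", nrow(x), "\n")
  if (nrow(x) > 0)
    print.data.frame(data.frame(x = x$x, height = x$height), digits = 6)
  invisible(x)
}
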