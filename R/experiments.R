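#' Peak counts on random problems versus the n - 1 line
#'
#' For each state count `n`, draws `trials` random rate-distortion
#' problems ([random_rd_problem()]), counts the significant
#' divergence-rate peaks of each ([count_critical_points()]), and compares
#' the per-`n` mean counts with the fixed line `n - 1` via the coefficient
#' of determination `R^2 = 1 - SS_res / SS_tot` (predictions `n - 1`, not
#' a fitted line).
#'
#' Per-problem seeds are derived from the global `seed` by fixed offsets
#' (`seed + 1000 n + trial`) so each draw is independently reproducible.
#'
#' @param n_values integer vector of state counts (default `2:10`).
#' @param trials number of random problems per `n`.
#' @param seed global integer seed.
#' @param d_low,d_high off-diagonal distortion range of the random draws.
#' @param ... passed to [count_critical_points()] (grid and configs).
#' @return A list of class `critical_count_result` with `n_values`,
#'   `mean_counts`, `sd_counts`, `counts` (trials x n matrix) and
#'   `r_squared`.
#' @export
conjecture1_experiment <- function(n_values = 2:10, trials = 10,
                                   seed = 1, d_low = 0, d_high = 4, ...) {
  stopifnot(trials >= 1)
  counts <- matrix(NA_integer_, trials, length(n_values),
                   dimnames = list(NULL, paste0("n", n_values)))
  for (a in seq_along(n_values)) {
    for (tr in seq_len(trials)) {
      pr <- random_rd_problem(n_values[a],
                              seed = seed + 1000L * n_values[a] + tr,
                              d_low = d_low, d_high = d_high)
      counts[tr, a] <- count_critical_points(pr, ...)
    }
  }
  mean_counts <- colMeans(counts)
  line <- n_values - 1
  ss_res <- sum((mean_counts - line)^2)
  ss_tot <- sum((mean_counts - mean(mean_counts))^2)
  structure(list(n_values = n_values, mean_counts = unname(mean_counts),
                 sd_counts = unname(apply(counts, 2, stats::sd)),
                 counts = counts,
                 r_squared = 1 - ss_res / ss_tot),
            class = "critical_count_result")
}

#' @export
print.critical_count_result <- function(x, ...) {
  cat("Significant-peak counts on random RD problems\n")
  print(data.frame(n = x$n_values, mean = x$mean_counts, sd = x$sd_counts,
                   line = x$n_values - 1), digits = 3, row.names = FALSE)
  cat(sprintf("R^2 against the line n - 1: %.4f\n", x$r_squared))
  invisible(x)
}

#' Weak-universality comparison of two random distortion matrices
#'
#' Builds two problems on `n` states with uniform source and independent
#' distortion matrices (zero diagonal, off-diagonal uniform on `[0, 1]`),
#' traces both rate-distortion curves, measures the sup vertical gap
#' between them on the common distortion range (linear interpolation of
#' `R(D)`), and extracts each curve's significant peak set.  As `n` grows
#' the curves approach each other while the critical points need not.
#'
#' @param n number of states.
#' @param seed1,seed2 seeds of the two distortion draws.
#' @param beta_min,beta_max,n_grid trade-off grid.
#' @param ... further arguments to [critical_peaks()].
#' @return A list with both `curves`, both `peaks`, and `gap` (sup
#'   vertical distance between the two `R(D)` interpolants).
#' @export
weak_universality_experiment <- function(n = 50, seed1 = 1, seed2 = 2,
                                         beta_min = 0.05, beta_max = 10,
                                         n_grid = 400, ...) {
  make <- function(seed) {
    set.seed(seed)
    d <- matrix(stats::runif(n * n), n, n)
    diag(d) <- 0
    rd_problem(rep(1 / n, n), d)
  }
  p1 <- make(seed1); p2 <- make(seed2)
  s1 <- critical_peaks(p1, beta_min = beta_min, beta_max = beta_max,
                       n_grid = n_grid, ...)
  s2 <- critical_peaks(p2, beta_min = beta_min, beta_max = beta_max,
                       n_grid = n_grid, ...)
  c1 <- curve_points(s1$curve); c2 <- curve_points(s2$curve)
  d_lo <- max(min(c1$D), min(c2$D)); d_hi <- min(max(c1$D), max(c2$D))
  gap <- if (d_hi > d_lo) {
    dd <- seq(d_lo, d_hi, length.out = 200)
    r1 <- stats::approx(c1$D, c1$R, xout = dd, ties = mean)$y
    r2 <- stats::approx(c2$D, c2$R, xout = dd, ties = mean)$y
    max(abs(r1 - r2))
  } else NA_real_
  list(curves = list(c1, c2), peaks = list(s1$peaks, s2$peaks), gap = gap)
}

#' Criticality heatmap of the Berger three-state family
#'
#' For each middle-state mass `u` computes the normalised divergence-rate
#' series of [berger_problem()] over the `beta` grid; rows of the returned
#' matrix are `u` values, columns the series midpoints.  The theoretical
#' critical curve `beta = -log(berger_critical_w(u))` (defined for
#' `u <= 3 - 2*sqrt(2)`) is returned as an overlay.
#'
#' @param u_grid vector of `u` values in (0, 1).
#' @param beta_grid strictly increasing `beta` grid.
#' @param ba a [ba_config()].
#' @param kl a [kl_config()].
#' @return A list of class `criticality_heatmap` with `u_grid`,
#'   `beta_mid`, `M_norm` (matrix, rows = `u`), and `overlay` (data frame
#'   `u`, `beta_star`, `NA` outside the closed-form domain).
#' @export
criticality_heatmap <- function(u_grid, beta_grid,
                                ba = ba_config(), kl = kl_config()) {
  M <- matrix(NA_real_, length(u_grid), length(beta_grid) - 1)
  for (k in seq_along(u_grid)) {
    curve <- rd_curve(berger_problem(u_grid[k]), beta_grid, config = ba)
    M[k, ] <- curve_divergence(curve, config = kl)$M_norm
  }
  beta_star <- vapply(u_grid, function(u) {
    ws <- berger_critical_w(u)
    if (is.null(ws)) NA_real_ else -log(ws)
  }, numeric(1))
  structure(list(u_grid = u_grid,
                 beta_mid = (beta_grid[-1] + beta_grid[-length(beta_grid)]) / 2,
                 M_norm = M,
                 overlay = data.frame(u = u_grid, beta_star = beta_star)),
            class = "criticality_heatmap")
}

#' @export
print.criticality_heatmap <- function(x, ...) {
  cat(sprintf("Criticality heatmap: %d u-values x %d beta midpoints\n",
              length(x$u_grid), length(x$beta_mid)))
  cat(sprintf("  closed-form overlay defined for %d of %d u-values\n",
              sum(!is.na(x$overlay$beta_star)), length(x$u_grid)))
  invisible(x)
}
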