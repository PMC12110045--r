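#' End-to-end critical-point detection on a rate-distortion problem
#'
#' Traces the rate-distortion curve over a trade-off grid, computes the
#' z-score-normalised divergence-rate series of the resulting codebooks,
#' and extracts the significant peaks: the estimated critical parameter
#' values.
#'
#' The grid is specified either in `beta` (log-spaced by default, since
#' critical points of generic problems spread multiplicatively) or in
#' `w = exp(-beta)` (linear), mirroring plots against `w`.  The default
#' abscissa `"neglogbeta"` traverses the curve from low to high
#' distortion with uniform sample spacing across decades of `beta` — the
#' configuration used for counting critical points; `"w"` on a linear
#' `w` grid is the natural choice when peak *locations* in `w` are
#' compared against closed-form critical values.
#'
#' @param problem an [rd_problem()].
#' @param beta_min,beta_max,n_grid trade-off grid (used unless
#'   `abscissa = "w"`).
#' @param w_min,w_max linear `w`-grid endpoints (used when
#'   `abscissa = "w"`).
#' @param abscissa `"neglogbeta"`, `"w"` or `"beta"`: the control
#'   parameter on which the divergence series and peaks are expressed
#'   (see [curve_divergence()]).
#' @param log_spacing logical; log-spaced `beta` grid (ignored for `w`).
#' @param ba a [ba_config()].
#' @param kl a [kl_config()].
#' @param peaks a [peak_config()].
#' @return A list of class `critical_scan` with the `curve`
#'   ([rd_curve()]), `series` ([divergence_series()]), `peaks` (a
#'   [find_significant_peaks()] result, augmented with `beta` and `w`
#'   columns) and `grid_step` (the largest spacing of the abscissa grid).
#' @export
critical_peaks <- function(problem,
                           beta_min = 0.05, beta_max = 500, n_grid = 400,
                           w_min = 0.01, w_max = 0.99,
                           abscissa = c("neglogbeta", "w", "beta"),
                           log_spacing = TRUE,
                           ba = ba_config(), kl = kl_config(),
                           peaks = peak_config()) {
  abscissa <- match.arg(abscissa)
  if (abscissa == "w") {
    w_grid <- seq(w_min, w_max, length.out = n_grid)
    beta_grid <- sort(-log(w_grid))
  } else {
    beta_grid <- if (log_spacing)
      exp(seq(log(beta_min), log(beta_max), length.out = n_grid))
    else seq(beta_min, beta_max, length.out = n_grid)
  }
  curve <- rd_curve(problem, beta_grid, config = ba)
  series <- curve_divergence(curve, abscissa = abscissa, config = kl)
  ps <- find_significant_peaks(series, config = peaks)
  ps$beta <- switch(abscissa, beta = ps$x, w = -log(ps$x),
                    neglogbeta = exp(-ps$x))
  ps$w <- exp(-ps$beta)
  structure(list(curve = curve, series = series, peaks = ps,
                 abscissa = abscissa,
                 grid_step = max(diff(sort(series$t_mid)))),
            class = "critical_scan")
}

#' @export
print.critical_scan <- function(x, ...) {
  cat(sprintf("Critical scan over %s in [%.4g, %.4g] (%d points)\n",
              x$abscissa, min(x$series$t_mid), max(x$series$t_mid),
              length(x$series$t_mid) + 1))
  print(x$peaks)
  invisible(x)
}

#' Number of significant critical points of a problem
#'
#' Runs [critical_peaks()] and returns the peak count — the estimated
#' number of critical trade-off parameters.
#'
#' @inheritParams critical_peaks
#' @param ... passed on to [critical_peaks()].
#' @return Integer peak count.
#' @export
count_critical_points <- function(problem, ...) {
  if (problem$n < 2) return(0L)
  nrow(critical_peaks(problem, ...)$peaks)
}
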