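#' Blahut-Arimoto solver configuration
#'
#' @param tol fixed-point convergence tolerance on the max-abs change of the
#'   output distribution between iterations.
#' @param max_iter iteration cap per solve.
#' @param support_eps threshold below which an output-marginal entry counts
#'   as zero when reporting the support.
#' @return A list of class `ba_config`.
#' @export
ba_config <- function(tol = 1e-10, max_iter = 10000L, support_eps = 1e-8) {
  stopifnot(tol > 0, max_iter >= 1, support_eps > 0)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 support_eps = support_eps),
            class = "ba_config")
}

#' Boltzmann weight matrix W
#'
#' Computes `W[i, j] = exp(-beta * d[i, j]) = w^d[i,j]` with `w = exp(-beta)`.
#' Entries equal 1 exactly where `d[i, j] = 0`.
#'
#' @param problem an [rd_problem()].
#' @param beta finite trade-off parameter.
#' @return A list of class `w_matrix` with fields `beta`, `w`, `W`.
#' @export
make_w_matrix <- function(problem, beta) {
  stopifnot(inherits(problem, "rd_problem"), is.finite(beta))
  structure(list(beta = beta, w = exp(-beta),
                 W = exp(-beta * problem$d)),
            class = "w_matrix")
}

#' One Blahut-Arimoto fixed-point update of the output distribution
#'
#' Applies the compact self-consistency map
#' `p <- p * ( W %*% (q / (t(W) %*% p)) )`, whose fixed points are the
#' optimal output marginals.  The map preserves the probability simplex.
#'
#' @param p_out current output distribution, strictly positive.
#' @param problem an [rd_problem()].
#' @param Wm a [make_w_matrix()] result for the same problem.
#' @return Updated output distribution (sums to 1).
#' @export
ba_update <- function(p_out, problem, Wm) {
  W <- Wm$W
  Zt <- as.vector(crossprod(W, p_out))       # Z_j = sum_i p_i W[i,j]
  if (any(Zt == 0))
    stop("degenerate input: t(W) %*% p underflowed to zero")
  as.vector(p_out * (W %*% (problem$q / Zt)))
}

#' Solve one rate-distortion point by Blahut-Arimoto iteration
#'
#' Iterates [ba_update()] from the uniform distribution (or `p_init`)
#' until the max-abs change drops below `config$tol` or `config$max_iter`
#' is reached.  The converged marginal defines the codebook
#' `p(i|j) = p_i W[i,j] / Z_j`, the average distortion
#' `D = sum_ij q_j p(i|j) d[i,j]` and the rate
#' `R = sum_ij q_j p(i|j) log2(p(i|j)/p_i)` in bits.
#'
#' @param problem an [rd_problem()].
#' @param beta finite trade-off parameter.
#' @param config a [ba_config()].
#' @param p_init optional warm-start output distribution.
#' @return An object of class `rd_solution` with fields `beta`, `w`,
#'   `p_out`, `codebook` (rows = outputs, cols = inputs), `D`, `R`,
#'   `support`, `converged`, `residual`, `iterations`.
#' @export
ba_solve <- function(problem, beta, config = ba_config(), p_init = NULL) {
  stopifnot(inherits(problem, "rd_problem"), is.finite(beta))
  n <- problem$n
  Wm <- make_w_matrix(problem, beta)
  p <- if (is.null(p_init)) rep(1 / n, n) else {
    stopifnot(length(p_init) == n, all(p_init > 0))
    p_init / sum(p_init)
  }
  W <- Wm$W
  q <- problem$q
  residual <- Inf
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    Zt <- as.vector(crossprod(W, p))
    if (any(Zt == 0))
      stop("degenerate input: t(W) %*% p underflowed to zero")
    p_new <- as.vector(p * (W %*% (q / Zt)))
    residual <- max(abs(p_new - p))
    p <- p_new
    if (residual < config$tol) break
  }
  converged <- residual < config$tol
  if (!converged)
    warning(sprintf(
      "Blahut-Arimoto did not converge at beta=%g (residual %.3g after %d iterations)",
      beta, residual, iter))
  Z <- as.vector(crossprod(W, p))
  codebook <- sweep(p * W, 2, Z, "/")
  D <- sum((codebook * problem$d) %*% q)
  ratio <- codebook / p                      # p recycles down columns
  lg <- ifelse(codebook > 0, log2(ratio), 0)
  R <- max(sum((codebook * lg) %*% q), 0)
  structure(list(beta = beta, w = Wm$w, p_out = p, codebook = codebook,
                 D = D, R = R, support = which(p > config$support_eps),
                 converged = converged, residual = residual,
                 iterations = iter),
            class = "rd_solution")
}

#' @export
print.rd_solution <- function(x, ...) {
  cat(sprintf("RD point at beta = %.6g (w = %.6g): D = %.6g, R = %.6g bits, support %d/%d%s\n",
              x$beta, x$w, x$D, x$R, length(x$support), length(x$p_out),
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Trace the rate-distortion curve over a beta grid
#'
#' Solves [ba_solve()] at each grid point in increasing order of `beta`,
#' warm-starting each solve from the previous point's output distribution
#' (continuation).  Because the multiplicative update can never revive an
#' entry that underflowed to exactly zero, the warm start is floored at
#' `reseed_eps / n` so states whose marginal vanished at smaller `beta` can
#' re-emerge where the solution calls for it.
#'
#' @param problem an [rd_problem()].
#' @param beta_grid strictly increasing, non-empty numeric vector.
#' @param config a [ba_config()].
#' @param reseed_eps warm-start floor (total mass scale) for vanished states.
#' @return An object of class `rd_curve`: a list with the `problem`,
#'   `beta` grid and `solutions` (one `rd_solution` per grid point).
#' @export
rd_curve <- function(problem, beta_grid, config = ba_config(),
                     reseed_eps = 1e-6) {
  stopifnot(length(beta_grid) >= 1, !is.unsorted(beta_grid, strictly = TRUE))
  sols <- vector("list", length(beta_grid))
  p_prev <- NULL
  for (k in seq_along(beta_grid)) {
    init <- if (is.null(p_prev)) NULL else {
      p0 <- pmax(p_prev, reseed_eps / problem$n)
      p0 / sum(p0)
    }
    sols[[k]] <- ba_solve(problem, beta_grid[k], config, p_init = init)
    p_prev <- sols[[k]]$p_out
  }
  structure(list(problem = problem, beta = beta_grid, solutions = sols),
            class = "rd_curve")
}

#' @export
print.rd_curve <- function(x, ...) {
  D <- vapply(x$solutions, `[[`, numeric(1), "D")
  R <- vapply(x$solutions, `[[`, numeric(1), "R")
  cat(sprintf("RD curve on %d states, %d beta points in [%.4g, %.4g]\n",
              x$problem$n, length(x$beta), min(x$beta), max(x$beta)))
  cat(sprintf("  D in [%.4g, %.4g], R in [%.4g, %.4g] bits\n",
              min(D), max(D), min(R), max(R)))
  invisible(x)
}

#' Extract the (D, R) points of a curve
#'
#' @param curve an [rd_curve()] result.
#' @return A data frame with columns `beta`, `w`, `D`, `R`, `n_support`.
#' @export
curve_points <- function(curve) {
  stopifnot(inherits(curve, "rd_curve"))
  data.frame(
    beta = curve$beta,
    w = vapply(curve$solutions, `[[`, numeric(1), "w"),
    D = vapply(curve$solutions, `[[`, numeric(1), "D"),
    R = vapply(curve$solutions, `[[`, numeric(1), "R"),
    n_support = vapply(curve$solutions,
                       function(s) length(s$support), integer(1)))
}
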