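#' Closed-form high-beta output distribution
#'
#' In the low-distortion regime (large `beta`, all marginals positive) the
#' fixed point of the Blahut-Arimoto map has the explicit matrix form
#' `p = solve(t(W), q / solve(W, 1))`.  Past the first critical point some
#' entries of this algebraic continuation go negative; the caller
#' interprets signs (that is exactly how critical points are located).
#'
#' @param problem an [rd_problem()].
#' @param beta trade-off parameter; `W` must be invertible here (guaranteed
#'   for large `beta`).
#' @return Numeric vector of length `n` (not necessarily a distribution
#'   below the first critical point).
#' @export
high_beta_output <- function(problem, beta) {
  stopifnot(inherits(problem, "rd_problem"), is.finite(beta))
  W <- exp(-beta * problem$d)
  ones <- rep(1, problem$n)
  a <- tryCatch(solve(W, ones),
                error = function(e) stop("W is singular at beta = ", beta,
                                         ": ", conditionMessage(e)))
  as.vector(solve(t(W), problem$q / a))
}

#' First critical trade-off parameter
#'
#' Going from large to small `beta`, the first critical `beta*` is the
#' largest `beta` at which some entry of the closed-form output
#' ([high_beta_output()]) reaches zero.  The search brackets the first sign
#' change of the minimum entry by a downward scan that is geometric in
#' `w = exp(-beta)`, then refines by bisection.
#'
#' @param problem an [rd_problem()].
#' @param beta_hi upper end of the search range; all entries must be
#'   positive here.
#' @param beta_lo lower end of the search range.
#' @param tol bisection tolerance on `beta`.
#' @param n_scan number of scan points bracketing the sign change.
#' @return A list of class `critical_point` with `beta_star`, `w_star` and
#'   `vanishing_index` (the output whose probability reaches zero), or an
#'   error of class `no_critical_point` if the minimum entry stays positive
#'   on the range.
#' @export
first_critical_beta <- function(problem, beta_hi = 30, beta_lo = 1e-3,
                                tol = 1e-10, n_scan = 400L) {
  stopifnot(beta_hi > beta_lo, beta_lo > 0, tol > 0)
  min_entry <- function(beta) min(high_beta_output(problem, beta))
  if (min_entry(beta_hi) <= 0)
    stop("precondition violated: high_beta_output must be positive at beta_hi")
  # geometric scan in w from w_hi = exp(-beta_hi) up to w_lo = exp(-beta_lo)
  w_grid <- exp(seq(-beta_hi, -beta_lo, length.out = n_scan))
  betas <- -log(w_grid)                      # decreasing
  lo <- NA_real_; hi <- NA_real_
  prev_beta <- beta_hi
  for (b in betas[-1]) {
    m <- tryCatch(min_entry(b), error = function(e) NA_real_)
    if (!is.na(m) && m <= 0) { lo <- b; hi <- prev_beta; break }
    if (!is.na(m)) prev_beta <- b
  }
  if (is.na(lo))
    stop(structure(class = c("no_critical_point", "error", "condition"),
                   list(message = sprintf(
                          "no critical point in range [%g, %g]",
                          beta_lo, beta_hi),
                        call = sys.call(-1))))
  while (hi - lo > tol) {
    mid <- (hi + lo) / 2
    if (min_entry(mid) <= 0) lo <- mid else hi <- mid
  }
  beta_star <- (hi + lo) / 2
  structure(list(beta_star = beta_star, w_star = exp(-beta_star),
                 vanishing_index = which.min(high_beta_output(problem, lo))),
            class = "critical_point")
}

#' @export
print.critical_point <- function(x, ...) {
  cat(sprintf("Critical point: beta* = %.8g (w* = %.8g), vanishing output state %d\n",
              x$beta_star, x$w_star, x$vanishing_index))
  invisible(x)
}

#' Explicit two-state output distributions
#'
#' For the two-state family of [two_state_problem()] the output marginals
#' before the first critical point are, with `w = exp(-beta)`:
#' `p1 = (1 - 2 w^a + w^(a+1)) / (2 (1-w)(1-w^a))` and
#' `p2 = (1 - 2 w   + w^(a+1)) / (2 (1-w)(1-w^a))`.
#' The removable singularity at `w = 1` (or `w^a = 1`) is refused rather
#' than limit-evaluated; it lies outside the operating range `beta > 0`.
#'
#' @param a positive asymmetry parameter, `a != 0`.
#' @param beta trade-off parameter with `exp(-beta)` away from 1.
#' @return Numeric vector `c(p1, p2)`.
#' @export
two_state_outputs <- function(a, beta) {
  stopifnot(a != 0)
  w <- exp(-beta)
  if (abs(1 - w) < 1e-12 || abs(1 - w^a) < 1e-12)
    stop("removable singularity: w = 1 or w^a = 1 (beta must be > 0)")
  den <- 2 * (1 - w) * (1 - w^a)
  c((1 - 2 * w^a + w^(a + 1)) / den,
    (1 - 2 * w + w^(a + 1)) / den)
}

#' Closed-form critical point of the Berger three-state family
#'
#' For [berger_problem()] with middle-state mass `u`, the middle output
#' vanishes at `w* = (1 - u - sqrt(1 - 6 u + u^2)) / 2`, which is real
#' exactly when `u <= 3 - 2*sqrt(2)`.
#'
#' @param u middle-state probability, in (0, 1).
#' @return `w*` as a single number, or `NULL` when `u > 3 - 2*sqrt(2)` (no
#'   real critical point in this family branch).
#' @export
berger_critical_w <- function(u) {
  stopifnot(is.numeric(u), length(u) == 1L, u > 0, u < 1)
  u_max <- 3 - 2 * sqrt(2)
  if (u > u_max + 1e-15) return(NULL)
  disc <- max(1 - 6 * u + u^2, 0)
  (1 - u - sqrt(disc)) / 2
}

#' Descartes' rule-of-signs bound on positive roots
#'
#' Counts strict sign alternations among the nonzero coefficients
#' (ascending powers).  The number of positive real roots equals the count
#' minus an even non-negative integer.
#'
#' @param coefficients numeric vector of polynomial coefficients in
#'   ascending powers; at least one must be nonzero.
#' @return A list of class `polynomial_sign_profile` with `coefficients`
#'   and `sign_changes`.
#' @export
descartes_positive_root_bound <- function(coefficients) {
  stopifnot(is.numeric(coefficients), any(coefficients != 0))
  nz <- sign(coefficients[coefficients != 0])
  structure(list(coefficients = coefficients,
                 sign_changes = sum(diff(nz) != 0)),
            class = "polynomial_sign_profile")
}

#' @export
print.polynomial_sign_profile <- function(x, ...) {
  cat("Polynomial with", x$sign_changes,
      "coefficient sign changes (positive roots = this minus an even k)\n")
  invisible(x)
}
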