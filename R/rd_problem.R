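#' Discrete rate-distortion problem
#'
#' Bundles a source distribution `q` over `n` states with an `n x n`
#' distortion matrix `d`.  The index convention throughout the package is
#' rows = outputs `i`, columns = inputs `j`, so `d[i, j]` is the cost of
#' coding input `j` as output `i`.
#'
#' `q` must be strictly positive and sum to 1 (within `1e-6`; it is
#' renormalised exactly on construction so downstream invariants hold to
#' machine precision).  All entries of `d` must be non-negative.
#'
#' @param q numeric vector of source probabilities, all `> 0`.
#' @param d numeric matrix of non-negative distortions, `length(q)` square.
#' @return An object of class `rd_problem` with fields `n`, `q`, `d`.
#' @examples
#' p <- rd_problem(c(0.5, 0.5), matrix(c(0, 2, 1, 0), 2, 2))
#' p$n
#' @export
rd_problem <- function(q, d) {
  if (!is.numeric(q) || length(q) < 1L)
    stop("`q` must be a non-empty numeric vector")
  if (anyNA(q) || any(q <= 0))
    stop("`q` must have strictly positive entries")
  if (abs(sum(q) - 1) > 1e-6)
    stop("`q` must sum to 1 (off by ", format(sum(q) - 1), ")")
  d <- as.matrix(d)
  n <- length(q)
  if (!is.numeric(d) || nrow(d) != n || ncol(d) != n)
    stop("`d` must be a ", n, "x", n, " numeric matrix to match `q`")
  if (anyNA(d) || any(d < 0))
    stop("`d` must have non-negative entries")
  structure(list(n = n, q = as.numeric(q) / sum(q), d = unname(d)),
            class = "rd_problem")
}

#' @export
print.rd_problem <- function(x, ...) {
  cat("Rate-distortion problem on", x$n, "states\n")
  cat("  q:", format(x$q, digits = 4), "\n")
  cat("  d: ", nrow(x$d), "x", ncol(x$d),
      " distortion matrix (rows = outputs, cols = inputs), max ",
      format(max(x$d), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Two-state rate-distortion family
#'
#' The worked two-state example: `q = (1/2, 1/2)` and distortion
#' `d = [[0, 1], [a, 0]]` for a shape parameter `a`.  For `a > 1` the
#' second output state vanishes at the first critical point; the critical
#' `w* = exp(-beta*)` is the positive root (other than 1) of
#' `1 - 2 w + w^(a+1)`.
#'
#' @param a positive distortion asymmetry parameter (`a != 0`).
#' @return An `rd_problem` on 2 states.
#' @export
two_state_problem <- function(a = 2) {
  stopifnot(is.numeric(a), length(a) == 1L, a > 0)
  rd_problem(c(0.5, 0.5), matrix(c(0, a, 1, 0), 2, 2))
}

#' Berger's three-state rate-distortion family
#'
#' Source `q = ((1-u)/2, u, (1-u)/2)` for `u` in (0,1) with the fixed
#' distortion matrix `[[0,1,2],[1,0,1],[2,1,0]]`.  For `u <= 3 - 2*sqrt(2)`
#' the middle state has a closed-form critical point, see
#' [berger_critical_w()].
#'
#' @param u middle-state probability, in (0, 1).
#' @return An `rd_problem` on 3 states.
#' @export
berger_problem <- function(u) {
  stopifnot(is.numeric(u), length(u) == 1L, u > 0, u < 1)
  d <- matrix(c(0, 1, 2,
                1, 0, 1,
                2, 1, 0), 3, 3, byrow = TRUE)
  rd_problem(c((1 - u) / 2, u, (1 - u) / 2), d)
}

#' Random rate-distortion problem
#'
#' Draws `q` as normalised uniform(0, 1) variates and a distortion matrix
#' with zero diagonal and off-diagonal entries uniform on
#' `[d_low, d_high]` (default `[0, 4]`).  Fully reproducible from `seed`.
#'
#' @param n number of states, `>= 2`.
#' @param seed integer seed; if `NULL` the current RNG state is used.
#' @param d_low,d_high off-diagonal distortion range, `d_high > d_low >= 0`.
#' @return An `rd_problem`.
#' @export
random_rd_problem <- function(n, seed = NULL, d_low = 0, d_high = 4) {
  stopifnot(n >= 2, d_low >= 0, d_high > d_low)
  if (!is.null(seed)) set.seed(seed)
  q <- stats::runif(n)
  q <- q / sum(q)
  d <- matrix(stats::runif(n * n, d_low, d_high), n, n)
  diag(d) <- 0
  rd_problem(q, d)
}

#' Block-structured clustering problem
#'
#' Uniform source over `n_clusters * per_cluster` states whose distortion
#' matrix has low intra-block and high inter-block cost (plus a small
#' uniform jitter to break ties), emulating well-separated clusters.  At
#' intermediate trade-off parameters the optimal codebook supports one
#' output per cluster.
#'
#' @param n_clusters,per_cluster block structure (defaults 3 x 6 = 18 states).
#' @param d_intra,d_inter within/between-block distortion, `d_intra < d_inter`.
#' @param jitter upper bound of the uniform jitter added off-diagonal.
#' @param seed integer seed for the jitter.
#' @return An `rd_problem`.
#' @export
cluster_problem <- function(n_clusters = 3, per_cluster = 6,
                            d_intra = 0.5, d_inter = 4.0,
                            jitter = 0.05, seed = NULL) {
  stopifnot(d_intra < d_inter, jitter >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- n_clusters * per_cluster
  block <- rep(seq_len(n_clusters), each = per_cluster)
  d <- ifelse(outer(block, block, "=="), d_intra, d_inter)
  if (jitter > 0)
    d <- d + matrix(stats::runif(n * n, 0, jitter), n, n)
  diag(d) <- 0
  rd_problem(rep(1 / n, n), d)
}
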