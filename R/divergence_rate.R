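#' Kullback-Leibler configuration
#'
#' The divergence rate is genuinely infinite when an output state's
#' probability drops to zero between consecutive samples.  `floor` clamps
#' the denominator distribution so a single KL term stays finite; `cap`
#' is the finite stand-in for an infinite divergence: every support-loss
#' step is assigned `cap` (per lost state), so all such transitions
#' saturate at a common magnitude and the downstream z-score treats them
#' on an equal footing regardless of how much probability mass moved.
#' `support_eps` is the output-marginal threshold below which a state
#' counts as absent; it sits well above the numerical decay floor of a
#' vanished state and well below any dynamically relevant mass.
#'
#' @param floor probability clamp applied to the second argument of the KL
#'   divergence.
#' @param cap finite stand-in for an infinite divergence.
#' @param support_eps marginal threshold defining support membership.
#' @return A list of class `kl_config`.
#' @export
kl_config <- function(floor = 1e-12, cap = 1e6, support_eps = 1e-4) {
  stopifnot(floor > 0, floor < 1, cap > 0, support_eps > 0, support_eps < 1)
  structure(list(floor = floor, cap = cap, support_eps = support_eps),
            class = "kl_config")
}

# core KL without simplex validation (codebook columns may be
# sub-normalised in the deterministic-map convention)
kl_core <- function(u, v, config) {
  pos <- u > 0
  val <- sum(u[pos] * log(u[pos] / pmax(v[pos], config$floor)))
  min(max(val, 0), config$cap)
}

#' Kullback-Leibler divergence with floor and cap
#'
#' `KL(u || v) = sum_y u_y log(u_y / max(v_y, floor))` in nats, with the
#' convention `0 log(0/.) = 0`, clamped to `[0, cap]`.
#'
#' @param u,v probability vectors of equal length, each summing to 1
#'   within `1e-6`.
#' @param config a [kl_config()].
#' @return A non-negative scalar (nats).
#' @export
kl_divergence <- function(u, v, config = kl_config()) {
  if (length(u) != length(v))
    stop("`u` and `v` must have the same length")
  if (abs(sum(u) - 1) > 1e-6 || abs(sum(v) - 1) > 1e-6)
    stop("`u` and `v` must each sum to 1 within 1e-6")
  kl_core(u, v, config)
}

#' Divergence rate between consecutive codebooks
#'
#' The change measure at the heart of the package:
#' `M = (1/dt) * sum_x q_x KL(p_t(.|x) || p_(t+dt)(.|x))`,
#' the input-averaged KL divergence between the conditionals of two
#' codebooks, per unit of the control parameter.
#'
#' @param cb_t,cb_next codebook matrices (rows = outputs, cols = inputs)
#'   of identical shape, columns conformable with `q`.
#' @param q input distribution used for averaging.
#' @param dt positive control-parameter increment.
#' @param config a [kl_config()].
#' @return A non-negative scalar.
#' @export
divergence_rate <- function(cb_t, cb_next, q, dt, config = kl_config()) {
  if (dt <= 0) stop("`dt` must be positive")
  if (!all(dim(cb_t) == dim(cb_next)) || ncol(cb_t) != length(q))
    stop("codebooks must share a shape conformable with `q`")
  acc <- 0
  for (j in seq_along(q))
    acc <- acc + q[j] * kl_core(cb_t[, j], cb_next[, j], config)
  min(acc / dt, config$cap)
}

#' Divergence-rate series over a codebook family
#'
#' Computes the raw divergence rate between each consecutive pair of
#' codebooks along the control parameter `t`, then z-score-normalises the
#' whole series (mean 0, sd 1).  Each rate is assigned the interval
#' midpoint `(t_k + t_(k+1)) / 2` as its abscissa, avoiding a systematic
#' half-step bias in peak locations.
#'
#' Support losses are detected on the output marginals
#' (`codebook %*% q`): every state above `config$support_eps` at step `k`
#' and below it at `k + 1` adds `config$cap` to `M_raw[k]`, the finite
#' sentinel for the genuinely infinite divergence at a support
#' transition.  All support-loss spikes therefore saturate at a common
#' magnitude and survive the z-score normalisation together, however
#' little probability mass the vanishing state carried.
#'
#' @param codebooks list of codebook matrices (rows = outputs,
#'   cols = inputs), length `>= 3`.
#' @param t strictly increasing control-parameter samples, same length.
#' @param q input distribution used for averaging.
#' @param config a [kl_config()].
#' @return An object of class `divergence_series` with fields `t_mid`,
#'   `M_raw`, `M_norm`, `q` and `constant` (`TRUE`, with `M_norm` all
#'   zeros, when the raw series has zero spread).
#' @export
divergence_series <- function(codebooks, t, q, config = kl_config()) {
  m <- length(codebooks)
  stopifnot(m >= 3, length(t) == m, !is.unsorted(t, strictly = TRUE))
  alive <- lapply(codebooks, function(cb) as.vector(cb %*% q) > config$support_eps)
  M_raw <- vapply(seq_len(m - 1), function(k) {
    n_lost <- sum(alive[[k]] & !alive[[k + 1]])
    divergence_rate(codebooks[[k]], codebooks[[k + 1]], q,
                    t[k + 1] - t[k], config) + config$cap * n_lost
  }, numeric(1))
  s <- stats::sd(M_raw)
  constant <- !is.finite(s) || s == 0
  if (constant) {
    M_norm <- rep(0, m - 1)
    warning("constant divergence series: sd = 0, M_norm set to zeros")
  } else {
    M_norm <- (M_raw - mean(M_raw)) / s
  }
  structure(list(t_mid = (t[-m] + t[-1]) / 2, M_raw = M_raw,
                 M_norm = M_norm, q = q, constant = constant),
            class = "divergence_series")
}

#' @export
print.divergence_series <- function(x, ...) {
  cat(sprintf("Divergence-rate series: %d steps over t in [%.4g, %.4g]\n",
              length(x$M_raw), min(x$t_mid), max(x$t_mid)))
  cat(sprintf("  max M_raw = %.4g at t = %.6g; normalized peak z = %.3g\n",
              max(x$M_raw), x$t_mid[which.max(x$M_raw)], max(x$M_norm)))
  invisible(x)
}

#' Divergence series of a rate-distortion curve
#'
#' Convenience wrapper: extracts the codebooks of an [rd_curve()] and
#' computes their [divergence_series()] along the chosen abscissa.
#'
#' `"beta"` keeps the solve order (increasing trade-off).  `"w"` and
#' `"neglogbeta"` reverse it, traversing the curve from low to high
#' distortion — the direction in which output states disappear, which is
#' what the (asymmetric) divergence rate detects most sharply:
#' `"w"` uses `t = exp(-beta)` (mirrors plots against `w`), while
#' `"neglogbeta"` uses `t = -log(beta)`, which is uniformly spaced on a
#' log-spaced `beta` grid and therefore resolves transitions evenly
#' across decades of `beta`.
#'
#' @param curve an [rd_curve()].
#' @param abscissa `"beta"`, `"w"` or `"neglogbeta"`.
#' @param config a [kl_config()].
#' @return A [divergence_series()].
#' @export
curve_divergence <- function(curve, abscissa = c("beta", "w", "neglogbeta"),
                             config = kl_config()) {
  stopifnot(inherits(curve, "rd_curve"))
  abscissa <- match.arg(abscissa)
  cbs <- lapply(curve$solutions, `[[`, "codebook")
  t <- switch(abscissa,
              beta = curve$beta,
              w = rev(exp(-curve$beta)),
              neglogbeta = rev(-log(curve$beta)))
  if (abscissa != "beta") cbs <- rev(cbs)
  divergence_series(cbs, t, curve$problem$q, config)
}

#' Codebook of a deterministic input-to-output map
#'
#' Builds the conditional matrix of a deterministic map.  In `"one_hot"`
#' mode column `x` carries probability 1 at `mapping[x]`.  The
#' `"subnorm"` mode instead places `1/(n_out + 1)` there (a convention in
#' which one extra implicit output state absorbs the remaining mass),
#' leaving columns deliberately sub-normalised; downstream KL computations
#' handle either via the floor clamp.
#'
#' @param mapping integer vector of length `n_in` with values in
#'   `1..n_out`, or a function applied to `1..n_in`.
#' @param n_in,n_out input/output alphabet sizes.
#' @param mode `"one_hot"` or `"subnorm"`.
#' @return An `n_out x n_in` codebook matrix.
#' @export
codebook_from_deterministic_map <- function(mapping, n_in, n_out,
                                            mode = c("one_hot", "subnorm")) {
  mode <- match.arg(mode)
  if (is.function(mapping))
    mapping <- vapply(seq_len(n_in), mapping, numeric(1))
  mapping <- as.integer(mapping)
  stopifnot(length(mapping) == n_in)
  if (any(mapping < 1L | mapping > n_out))
    stop("mapping out of range: values must lie in 1..n_out")
  val <- if (mode == "one_hot") 1 else 1 / (n_out + 1)
  cb <- matrix(0, n_out, n_in)
  cb[cbind(mapping, seq_len(n_in))] <- val
  cb
}
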