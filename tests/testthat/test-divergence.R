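test_that("KL divergence matches closed forms and is non-negative on random pairs", {
  expect_equal(kl_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.9, 0.1)),
               0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1),
               tolerance = 1e-12)
  expect_error(kl_divergence(c(1, 0), c(0.2, 0.3, 0.5)), "length")
  set.seed(21)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    u <- stats::runif(n); u <- u / sum(u)
    v <- stats::runif(n); v <- v / sum(v)
    expect_gte(kl_divergence(u, v), 0)
  }
  # identity case up to floor effects
  u <- c(0.999999, 0.000001)
  expect_lt(kl_divergence(u, u), 1e-12)
})

test_that("the divergence rate is an input-weighted KL per parameter unit", {
  q <- c(0.25, 0.75)
  cb1 <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2)
  cb2 <- matrix(c(0.6, 0.4, 0.5, 0.5), 2, 2)
  manual <- (0.25 * (0.8 * log(0.8 / 0.6) + 0.2 * log(0.2 / 0.4)) +
             0.75 * (0.3 * log(0.3 / 0.5) + 0.7 * log(0.7 / 0.5))) / 0.1
  expect_equal(divergence_rate(cb1, cb2, q, 0.1), manual, tolerance = 1e-12)
  expect_equal(divergence_rate(cb1, cb1, q, 0.1), 0)
  # single-input system reduces to a plain KL over dt
  u <- matrix(c(0.8, 0.2), 2, 1); v <- matrix(c(0.6, 0.4), 2, 1)
  expect_equal(divergence_rate(u, v, 1, 0.5),
               kl_divergence(c(0.8, 0.2), c(0.6, 0.4)) / 0.5)
  expect_error(divergence_rate(cb1, cb2, q, 0), "positive")
  # asymmetry: only non-negativity is guaranteed
  expect_gte(divergence_rate(cb2, cb1, q, 0.1), 0)
})

test_that("series are z-scored with midpoint abscissae and flag constant input", {
  q <- c(0.5, 0.5)
  cbs <- lapply(c(0.2, 0.5, 0.6, 0.9), function(a)
    matrix(c(a, 1 - a, 1 - a, a), 2, 2))
  s <- divergence_series(cbs, c(1, 2, 4, 8), q)
  expect_equal(s$t_mid, c(1.5, 3, 6))
  expect_equal(mean(s$M_norm), 0, tolerance = 1e-9)
  expect_equal(stats::sd(s$M_norm), 1, tolerance = 1e-9)
  expect_true(all(s$M_raw >= 0))
  # constant family: raw zeros, flagged, normalised zeros
  const <- lapply(1:3, function(i) matrix(c(0.7, 0.3, 0.2, 0.8), 2, 2))
  expect_warning(sc <- divergence_series(const, 1:3, q), "constant")
  expect_true(sc$constant)
  expect_equal(sc$M_raw, c(0, 0))
  expect_equal(sc$M_norm, c(0, 0))
})

test_that("the divergence rate of a smooth family vanishes linearly with grid spacing", {
  family <- function(m) {
    t <- seq(-1, 1, length.out = m)
    cbs <- lapply(t, function(ti) {
      p <- exp(ti) / (1 + exp(ti))
      matrix(c(p, 1 - p), 2, 1)
    })
    max(divergence_series(cbs, t, 1)$M_raw)
  }
  m1 <- family(21); m2 <- family(41); m3 <- family(81)
  expect_gt(m1 / m2, 1.5)
  expect_lt(m1 / m2, 3)
  expect_gt(m2 / m3, 1.5)
  expect_lt(m2 / m3, 3)
})

test_that("losing an output state saturates the series at the cap sentinel", {
  q <- c(0.5, 0.5)
  full <- matrix(c(0.6, 0.4, 0.4, 0.6), 2, 2)
  lost <- matrix(c(1, 0, 1, 0), 2, 2)   # second output extinct
  s <- suppressWarnings(
    divergence_series(list(full, full, lost), c(1, 2, 3), q))
  expect_gte(s$M_raw[2], kl_config()$cap / 2)
  expect_lt(s$M_raw[1], 1)
})

test_that("deterministic maps produce the documented codebooks", {
  expect_equal(codebook_from_deterministic_map(1:3, 3, 3), diag(3))
  all_to_one <- codebook_from_deterministic_map(rep(2, 4), 4, 3)
  expect_equal(all_to_one[2, ], rep(1, 4))
  expect_equal(rowSums(all_to_one)[c(1, 3)], c(0, 0), ignore_attr = TRUE)
  sub <- codebook_from_deterministic_map(c(2, 3, 1), 3, 3, mode = "subnorm")
  expect_equal(sub[cbind(c(2, 3, 1), 1:3)], rep(1 / 4, 3))
  expect_equal(sum(sub), 3 / 4)
  expect_equal(codebook_from_deterministic_map(function(x) x, 2, 2), diag(2))
  expect_error(codebook_from_deterministic_map(c(1, 4), 2, 3), "out of range")
})
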