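test_that("the weight matrix is the elementwise exponential of -beta * d", {
  pr <- rd_problem(c(0.5, 0.5), matrix(c(0, 2, 1, 0), 2, 2))
  expect_equal(make_w_matrix(pr, 0)$W, matrix(1, 2, 2))
  Wm <- make_w_matrix(pr, log(2))
  expect_equal(Wm$W, matrix(c(1, 0.25, 0.5, 1), 2, 2))
  expect_equal(Wm$w, 0.5)
  pr3 <- random_rd_problem(4, seed = 5)
  expect_equal(diag(make_w_matrix(pr3, 2.7)$W), rep(1, 4))
})

test_that("the fixed-point update has the closed-form limits and matches hand evaluation", {
  pr <- rd_problem(c(0.3, 0.7), matrix(c(0, 5, 5, 0), 2, 2))
  # identity W (large beta, zero diagonal): any positive p maps to q
  Wm_id <- list(W = diag(2))
  expect_equal(ba_update(c(0.9, 0.1), pr, Wm_id), pr$q)
  # all-ones W (beta = 0): every simplex point is fixed
  Wm_one <- list(W = matrix(1, 2, 2))
  expect_equal(ba_update(c(0.4, 0.6), pr, Wm_one), c(0.4, 0.6))
  # one step at beta = 1, evaluated element by element
  pr2 <- rd_problem(c(0.5, 0.5), matrix(c(0, 2, 1, 0), 2, 2))
  W <- matrix(c(1, exp(-2), exp(-1), 1), 2, 2)
  p <- c(0.5, 0.5)
  Z <- c(W[1, 1] * p[1] + W[2, 1] * p[2], W[1, 2] * p[1] + W[2, 2] * p[2])
  manual <- c(p[1] * (W[1, 1] * 0.5 / Z[1] + W[1, 2] * 0.5 / Z[2]),
              p[2] * (W[2, 1] * 0.5 / Z[1] + W[2, 2] * 0.5 / Z[2]))
  expect_equal(ba_update(p, pr2, make_w_matrix(pr2, 1)), manual,
               tolerance = 1e-14)
})

test_that("every update conserves the simplex", {
  set.seed(11)
  for (pr in random_problem_set()) {
    for (beta in c(0.1, 1, 5)) {
      Wm <- make_w_matrix(pr, beta)
      p <- stats::runif(pr$n) + 0.01
      p <- p / sum(p)
      p_new <- ba_update(p, pr, Wm)
      expect_equal(sum(p_new), 1, tolerance = 1e-12)
      expect_true(all(p_new >= 0))
    }
  }
})

test_that("converged solutions match the distortion-free and zero-rate limits", {
  pr <- two_state_problem(2)
  hi <- ba_solve(pr, 20)
  expect_lt(hi$D, 1e-6)
  expect_equal(hi$R, 1, tolerance = 1e-6)   # H(1/2, 1/2) = 1 bit
  expect_equal(hi$codebook, diag(2), tolerance = 1e-5)
  # zero-rate limit: single active output achieving min_i sum_j q_j d[i, j]
  lo <- suppressWarnings(ba_solve(pr, 1e-9))
  expect_lt(lo$R, 1e-6)
  lo2 <- ba_solve(pr, 0.01, ba_config(max_iter = 100000L))
  expect_equal(lo2$D, min(pr$d %*% pr$q), tolerance = 1e-2)
})

test_that("solutions agree with the high-beta closed form and are self-consistent", {
  for (pr in list(two_state_problem(2), berger_problem(1 / 13),
                  random_rd_problem(4, seed = 31))) {
    for (beta in c(3, 8)) {
      s <- ba_solve(pr, beta)
      # the closed form describes the solution only above the problem's
      # first critical point (all entries positive)
      if (min(high_beta_output(pr, beta)) > 1e-3)
        expect_equal(s$p_out, high_beta_output(pr, beta), tolerance = 1e-8)
      # output-marginal consistency
      expect_equal(s$p_out, as.vector(s$codebook %*% pr$q), tolerance = 1e-9)
      # codebook columns normalised
      expect_equal(colSums(s$codebook), rep(1, pr$n), tolerance = 1e-9)
      # rate and distortion bounds
      expect_true(s$R >= 0 && s$R <= -sum(pr$q * log2(pr$q)) + 1e-9)
      expect_true(s$D >= 0 && s$D <= max(pr$d))
    }
  }
})

test_that("the curve is monotone in beta and warm starts match single solves", {
  pr <- two_state_problem(2)
  curve <- suppressWarnings(
    rd_curve(pr, seq(0.05, 5, length.out = 200)))
  cp <- curve_points(curve)
  expect_true(all(diff(cp$D) <= 1e-6))
  expect_true(all(diff(cp$R) >= -1e-6))
  # single-element grid equals ba_solve
  one <- rd_curve(pr, 2.5)
  expect_equal(one$solutions[[1]]$p_out, ba_solve(pr, 2.5)$p_out)
  # one-state problem is degenerate everywhere
  p1 <- rd_problem(1, matrix(0, 1, 1))
  c1 <- rd_curve(p1, c(0.5, 1, 2))
  expect_true(all(vapply(c1$solutions, `[[`, numeric(1), "D") == 0))
  expect_true(all(vapply(c1$solutions, `[[`, numeric(1), "R") == 0))
})

test_that("non-convergence is reported with the residual and still returns a solution", {
  pr <- two_state_problem(2)
  expect_warning(s <- ba_solve(pr, 0.4832, ba_config(max_iter = 20L)),
                 "did not converge")
  expect_false(s$converged)
  expect_true(is.finite(s$residual) && s$residual > 0)
})
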