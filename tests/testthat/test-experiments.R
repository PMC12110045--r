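test_that("the worked families yield their known critical-point counts and locations", {
  scan <- two_state_w_scan()
  expect_equal(nrow(scan$peaks), 1)
  expect_lt(abs(scan$peaks$x - w_star_two_state), scan$grid_step)
  b <- berger_w_scan()
  expect_equal(nrow(b$peaks), 2)
  # the two peaks bracket the zero interval of the middle state's marginal
  expect_lt(abs(min(b$peaks$x) - w_star_berger), b$grid_step)
  expect_gt(max(b$peaks$x), 0.8)
  # counting wrapper agrees
  expect_equal(suppressWarnings(count_critical_points(two_state_problem(2))), 1L)
  expect_equal(suppressWarnings(count_critical_points(berger_problem(1 / 13))), 2L)
  expect_equal(count_critical_points(rd_problem(1, matrix(0, 1, 1))), 0L)
})

test_that("divergence-rate peaks sit at zero crossings of the closed-form outputs", {
  # two-state family across asymmetries
  for (a in c(1.5, 2, 3)) {
    ws <- stats::uniroot(function(w) 1 - 2 * w + w^(a + 1),
                         c(0.4, 0.95), tol = 1e-12)$root
    scan <- suppressWarnings(
      critical_peaks(two_state_problem(a), abscissa = "w", n_grid = 400))
    expect_equal(nrow(scan$peaks), 1)
    expect_lt(abs(scan$peaks$x - ws), scan$grid_step)
  }
  # Berger family: low peak at the closed-form w*
  for (u in c(1 / 13, 0.05)) {
    scan <- suppressWarnings(
      critical_peaks(berger_problem(u), abscissa = "w",
                     w_min = 0.018, w_max = 0.951, n_grid = 400))
    expect_lt(abs(min(scan$peaks$x) - berger_critical_w(u)),
              2 * scan$grid_step)
  }
})

test_that("mean peak counts of random problems regress onto the line n - 1", {
  res <- suppressWarnings(
    conjecture1_experiment(n_values = c(2, 4, 6), trials = 3, seed = 1))
  expect_equal(length(res$mean_counts), 3)
  expect_true(all(diff(res$mean_counts) > 0))
  expect_equal(res$mean_counts[1], 1, tolerance = 0.5)
  # deterministic given (seed, config)
  res2 <- suppressWarnings(
    conjecture1_experiment(n_values = c(2, 4, 6), trials = 3, seed = 1))
  expect_identical(res$counts, res2$counts)
})

test_that("weak universality: curves converge with n while critical points differ", {
  same <- suppressWarnings(
    weak_universality_experiment(5, seed1 = 3, seed2 = 3, n_grid = 120))
  expect_equal(same$gap, 0, tolerance = 1e-9)
  expect_equal(same$peaks[[1]]$x, same$peaks[[2]]$x)
  gaps5 <- gaps50 <- numeric(3)
  for (k in 1:3) {
    g5 <- suppressWarnings(
      weak_universality_experiment(5, seed1 = 2 * k, seed2 = 2 * k + 1,
                                   n_grid = 120))
    g50 <- suppressWarnings(
      weak_universality_experiment(50, seed1 = 2 * k, seed2 = 2 * k + 1,
                                   n_grid = 120))
    gaps5[k] <- g5$gap; gaps50[k] <- g50$gap
    # peak locations differ between the two draws at n = 50
    if (nrow(g50$peaks[[1]]) > 0 && nrow(g50$peaks[[2]]) > 0)
      expect_false(isTRUE(all.equal(g50$peaks[[1]]$x, g50$peaks[[2]]$x)))
  }
  expect_lt(mean(gaps50), mean(gaps5))
})

test_that("the criticality heatmap ridge follows the closed-form critical curve", {
  grid <- exp(seq(log(0.5), log(8), length.out = 150))
  hm <- suppressWarnings(
    criticality_heatmap(c(1 / 13, 0.05, 0.2), grid))
  expect_equal(dim(hm$M_norm), c(3, 149))
  # overlay only inside the closed-form domain
  expect_false(anyNA(hm$overlay$beta_star[1:2]))
  expect_true(is.na(hm$overlay$beta_star[3]))
  # ridge within one grid step of -log(w*) for u = 1/13 and u = 0.05
  for (k in 1:2) {
    ridge <- hm$beta_mid[which.max(hm$M_norm[k, ])]
    theory <- hm$overlay$beta_star[k]
    step <- theory * (log(8 / 0.5) / 149)
    expect_lt(abs(ridge - theory), 2 * step)
  }
})

test_that("the cluster problem passes through a one-output-per-block codebook", {
  pr <- cluster_problem(seed = 7)
  cur <- suppressWarnings(
    rd_curve(pr, exp(seq(log(0.05), log(30), length.out = 200))))
  marg <- t(sapply(cur$solutions, `[[`, "p_out"))
  sup <- rowSums(marg > 1e-4)
  runs <- rle(sup == 3)
  expect_gte(max(runs$lengths[runs$values]), 10)  # contiguous 3-state plateau
  k <- which(sup == 3)[5]
  alive <- which(marg[k, ] > 1e-4)
  expect_equal(sort(unique((alive - 1) %/% 6)), 0:2)  # one per block
})
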