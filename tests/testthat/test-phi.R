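test_that("phi_m matches the Lyapunov population value and vanishes for noise", {
  # white noise: Sigma(U) = Sigma(E)
  m0 <- var_model(matrix(0, 2, 2), diag(2))
  ts0 <- simulate_timeseries(m0, 50000, seed = 51)
  expect_lt(abs(phi_m(ts0)), 0.01)

  A <- rbind(c(0.5, 0.2), c(0, 0.4))
  ts <- simulate_timeseries(var_model(A, diag(2)), 50000, seed = 52)
  SU <- lyapunov_cov(A, diag(2))
  pop <- 0.5 * log(det(SU) / det(diag(2)))
  expect_lt(abs(phi_m(ts) - pop) / pop, 0.02)

  # simultaneous permutation of regions leaves the value unchanged
  tsp <- parcellated_ts(ts$values[, 2:1], ts$sampling_interval,
                        ts$region_labels[2:1], ts$session_id)
  expect_equal(phi_m(tsp), phi_m(ts), tolerance = 1e-10)
})

test_that("phi_g agrees with the grid-search KL oracle", {
  A <- rbind(c(0.5, 0.2), c(0, 0.4))
  ts <- simulate_timeseries(var_model(A, diag(2)), 50000, seed = 53)
  refine <- as.numeric(phi_g(ts, method = "refine"))
  expect_lt(abs(refine - grid_phi_g(ts)), 1e-3)
  # refinement never worse than the per-node estimate
  pernode <- as.numeric(phi_g(ts, method = "pernode"))
  expect_lte(refine, pernode + 1e-8)

  # disconnected truth: diagonal A, diagonal noise
  md <- var_model(diag(c(0.5, 0.3)), diag(2))
  tsd <- simulate_timeseries(md, 50000, seed = 54)
  expect_lt(as.numeric(phi_g(tsd)), 0.01)
})

test_that("phi_m >= phi_g >= 0 on fitted models", {
  for (r in 1:5) {
    A <- withr::with_seed(60 + r, {
      A <- matrix(runif(9, -0.25, 0.25), 3, 3)
      diag(A) <- runif(3, 0.2, 0.5)
      A
    })
    A <- A * 0.9 / max(Mod(eigen(A, only.values = TRUE)$values))
    ts <- simulate_timeseries(var_model(A, diag(3)), 2000, seed = 70 + r)
    g <- as.numeric(phi_g(ts))
    m <- phi_m(ts)
    expect_gte(g, 0)
    expect_gte(m, g - 1e-6)
  }
})

test_that("estimated phi_g increases with the generating coupling", {
  vals <- vapply(c(0.1, 0.2, 0.3), function(a) {
    A <- rbind(c(0.4, a), c(a, 0.4))
    ts <- simulate_timeseries(var_model(A, diag(2)), 20000, seed = 55)
    as.numeric(phi_g(ts))
  }, 0)
  expect_true(all(diff(vals) > 0))
})

test_that("subsystem maximization finds the planted coupled pair", {
  # coupled pair plus independent noise nodes. In population every
  # subsystem containing the pair ties with the pair itself (independent
  # nodes contribute zero), and finite-sample overfit breaks ties toward
  # larger sets, so the contract is: the maximizer contains the pair, its
  # value matches the pair's own phi_g closely, and the pair dominates
  # every same-size alternative.
  A <- matrix(0, 5, 5)
  A[1, 2] <- A[2, 1] <- 0.35
  diag(A) <- c(0.4, 0.4, 0.3, 0.3, 0.3)
  ts <- simulate_timeseries(var_model(A, diag(5)), 20000, seed = 56)
  res <- max_phi_subsystem(ts, "phi_g", strategy = "exhaustive")
  expect_true(all(1:2 %in% res$subsystem))
  pair_phi <- as.numeric(phi_g(restrict_ts(ts, 1:2)))
  expect_lt(abs(res$value - pair_phi) / pair_phi, 0.05)
  expect_gte(res$value, res$full_value)
  pairs <- utils::combn(5, 2, simplify = FALSE)
  pair_vals <- vapply(pairs, function(s) {
    as.numeric(phi_g(restrict_ts(ts, s)))
  }, 0)
  expect_identical(pairs[[which.max(pair_vals)]], 1:2)
})

test_that("hierarchical subsystem search tracks the exhaustive maximum", {
  for (r in 1:8) {
    A <- withr::with_seed(80 + r, {
      A <- matrix(runif(36, 0, 0.2), 6, 6)
      diag(A) <- 0.35
      A
    })
    A <- A * 0.9 / max(Mod(eigen(A, only.values = TRUE)$values))
    ts <- simulate_timeseries(var_model(A, diag(6)), 3000, seed = 90 + r)
    ex <- max_phi_subsystem(ts, "phi_g", strategy = "exhaustive")
    hi <- max_phi_subsystem(ts, "phi_g", strategy = "hierarchical")
    expect_gte(hi$value, 0.95 * ex$value)
    expect_lte(hi$value, ex$value + 1e-10)
  }
})
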