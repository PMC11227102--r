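test_that("participation rates count region membership", {
  sets <- list(c(1, 2), c(1, 3), c(1, 2, 4))
  pm <- participation_rates(sets, 5)
  expect_equal(pm$rates, c(1, 2 / 3, 1 / 3, 1 / 3, 0))
  expect_identical(pm$n_units, 3L)
  expect_error(participation_rates(list(), 5), "at least one")
  expect_error(participation_rates(list(c(1, 6)), 5), "out of range")
})

test_that("surrogates degenerate to permutations when smoothing is off", {
  withr::with_seed(1, {
    map <- runif(15)
  })
  D <- matrix(1, 15, 15) - diag(15)
  surr <- variogram_surrogates(map, D, 20, seed = 2, smooth = FALSE)
  for (i in 1:20) expect_equal(sort(surr[i, ]), sort(map))
  # determinism
  surr2 <- variogram_surrogates(map, D, 20, seed = 2, smooth = FALSE)
  expect_identical(surr, surr2)
  # constant maps yield constant surrogates
  cs <- variogram_surrogates(rep(0.4, 15), D, 5, seed = 3)
  expect_true(all(cs == 0.4))
  expect_error(variogram_surrogates(runif(5), matrix(0, 5, 5), 3, 1),
               "at least 10")
})

test_that("surrogates preserve the variogram of a smooth map", {
  co <- generate_coordinates(100, seed = 3)
  mp <- smooth_map(co, lengthscale = 0.6, seed = 53)
  surr <- variogram_surrogates(mp, co$distances, 100, seed = 103,
                               resample_values = FALSE, n_bins = 12)
  vo <- empirical_variogram(mp, co$distances, n_bins = 12)
  gs <- rowMeans(vapply(1:100, function(i) {
    empirical_variogram(surr[i, ], co$distances, n_bins = 12)$gamma
  }, numeric(nrow(vo))))
  half <- 1:floor(nrow(vo) / 2)
  expect_lt(max(abs(gs[half] - vo$gamma[half]) / vo$gamma[half]), 0.2)
})

test_that("rate permutation test has the exact combinatorial spike p-value", {
  n <- 20
  spike <- c(1, rep(0, n - 1))
  rep1 <- permutation_test_rates(spike, distances = NULL, n_perm = 1000,
                                 seed = 4)
  # surrogate equals 1 at the spike with probability 1/n per permutation
  expected <- (1 + 1000 / n) / 1001
  expect_lt(abs(rep1$p_values[1] - expected), 0.025)
  expect_gte(min(rep1$p_values), 1 / 1001)

  # constant map: nothing can be significant
  repc <- permutation_test_rates(rep(0.5, 20), distances = NULL,
                                 n_perm = 200, seed = 5)
  expect_false(any(repc$significant))
  expect_equal(repc$p_values, rep(1, 20))
})

test_that("the plain-permutation null is calibrated at the nominal level", {
  # region count chosen away from the alpha * n discreteness boundary:
  # the attainable p-values are about rank/n, so at n = 50 the true level
  # of the procedure is ~0.04
  n <- 50
  n_perm <- 999
  hits <- withr::with_seed(6, {
    vapply(1:200, function(r) {
      map <- runif(n)
      rep_r <- permutation_test_rates(map, distances = NULL,
                                      n_perm = n_perm, seed = 6000 + r)
      c(mean(rep_r$p_values <= 0.05), any(rep_r$significant))
    }, numeric(2))
  })
  expect_gte(mean(hits[1, ]), 0.03)
  expect_lte(mean(hits[1, ]), 0.07)
  # FDR: fully-null maps rarely yield any rejection
  expect_lte(mean(hits[2, ]), 0.05 + 0.03)
})

test_that("BH step-up follows the hand-evaluated rule", {
  expect_true(all(bh_fdr(rep(0.001, 10))))
  expect_false(any(bh_fdr(rep(0.9, 10))))
  mask <- bh_fdr(c(0.001, 0.01, 0.02, 0.03, 0.5), q = 0.05)
  expect_identical(mask, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_error(bh_fdr(c(0.5, 1.2)))
})

test_that("ICC forms recover known consistency structure", {
  withr::with_seed(7, {
    rows <- rnorm(50, sd = 2)
    m_same <- matrix(rows, 50, 4)
  })
  r1 <- icc(m_same, form = "oneway")
  expect_equal(r1$icc, 1)

  withr::with_seed(8, {
    m_null <- matrix(rnorm(800), 100, 8)
  })
  expect_lt(abs(icc(m_null, "oneway")$icc), 0.1)

  # one-way random effects: sigma_b^2 = 3, sigma_e^2 = 1 -> ICC = 0.75
  withr::with_seed(9, {
    b <- rnorm(200, sd = sqrt(3))
    m_sim <- matrix(b, 200, 8) + matrix(rnorm(1600), 200, 8)
  })
  r_sim <- icc(m_sim, "oneway")
  expect_lt(abs(r_sim$icc - 0.75), 0.05)
  expect_true(r_sim$lower < r_sim$icc, r_sim$icc < r_sim$upper)
  expect_lt(r_sim$p_value, 1e-6)

  for (f in c("c1", "a1", "ck", "ak")) {
    r <- icc(m_sim, f)
    expect_true(r$icc > 0.5 && r$icc <= 1)
    expect_true(r$lower <= r$icc && r$icc <= r$upper)
  }
  expect_error(icc(matrix(1, 5, 3)), "degenerate")
})

test_that("map correlation test behaves at the identity and under the null", {
  withr::with_seed(10, {
    map <- runif(20)
  })
  res <- map_correlation_test(map, map, n_perm = 99, seed = 11)
  expect_equal(res$r, 1)
  expect_equal(res$p_value, 1 / 100)

  # independent rough maps: mostly non-significant
  pvals <- withr::with_seed(12, {
    vapply(1:100, function(r) {
      a <- runif(30)
      b <- runif(30)
      map_correlation_test(a, b, n_perm = 99, seed = 7000 + r)$p_value
    }, 0)
  })
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("the spatial null is wider than the naive null for smooth maps", {
  co <- clustered_coords(60, seed = 13)
  diffs <- vapply(1:30, function(r) {
    shared <- smooth_map(co, 0.6, seed = 8000 + r)
    a <- shared + 0.6 * smooth_map(co, 0.4, seed = 8100 + r)
    b <- shared + 0.6 * smooth_map(co, 0.4, seed = 8200 + r)
    sa <- map_correlation_test(a, b, co$distances, n_perm = 99,
                               seed = 8300 + r,
                               resample_values = FALSE)$p_value
    naive <- map_correlation_test(a, b, NULL, n_perm = 99,
                                  seed = 8300 + r)$p_value
    sa - naive
  }, 0)
  expect_gte(mean(diffs), 0)
})

test_that("Williams t for dependent correlations is calibrated", {
  expect_equal(compare_dependent_correlations(0.4, 0.4, 0.3, 50)$t, 0)
  up <- compare_dependent_correlations(0.5, 0.3, 0.2, 50)
  dn <- compare_dependent_correlations(0.3, 0.5, 0.2, 50)
  expect_equal(up$t, -dn$t)
  expect_error(compare_dependent_correlations(1.2, 0.3, 0.2, 50))
  expect_error(compare_dependent_correlations(0.2, 0.3, 0.2, 3))

  # type-I calibration under an exact null (rho_ab = rho_ac)
  S <- matrix(0.4, 3, 3)
  diag(S) <- 1
  L <- chol(S)
  rate <- withr::with_seed(14, {
    mean(vapply(1:1000, function(r) {
      X <- matrix(rnorm(300), 100, 3) %*% L
      rs <- cor(X)
      compare_dependent_correlations(rs[1, 2], rs[1, 3], rs[2, 3],
                                     100)$p_value < 0.05
    }, TRUE))
  })
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})
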