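test_that("generated VAR networks honor the planted structure", {
  sp0 <- cohort_spec(n_subjects = 2, n_regions = 4, core_regions = 1:2,
                     core_weight = 0, background_weight = 0,
                     self_weight = 0.5, n_samples = 100, seed = 1)
  m0 <- generate_var_network(sp0)
  expect_equal(m0$coefficients[1, , ], diag(4) * 0.5)

  sp <- cohort_spec(n_subjects = 2, n_regions = 10, core_regions = 1:5,
                    core_weight = 0.15, n_samples = 200, seed = 3)
  m <- generate_var_network(sp)
  A <- m$coefficients[1, , ]
  expect_lt(max(Mod(eigen(A, only.values = TRUE)$values)), 1)
  # off-diagonal core block uniform (possibly uniformly rescaled)
  core_block <- A[1:5, 1:5]
  off <- core_block[row(core_block) != col(core_block)]
  expect_equal(length(unique(round(off, 12))), 1)
  expect_true(is_spd(m$noise_cov))

  m2 <- generate_var_network(sp)
  expect_identical(m$coefficients, m2$coefficients)

  expect_error(cohort_spec(n_subjects = 2, n_regions = 4, core_regions = 1,
                           n_samples = 100, seed = 1),
               "at least 2")
})

test_that("simulated series match the Lyapunov stationary covariance", {
  # white-noise limit: A = 0
  m0 <- var_model(matrix(0, 3, 3), diag(3))
  ts0 <- simulate_timeseries(m0, 50000, seed = 11)
  expect_lt(max(abs(cov(ts0$values) - diag(3))), 0.05)

  # coupled 2-node model vs discrete Lyapunov solve
  A <- rbind(c(0.5, 0.2), c(0, 0.4))
  m <- var_model(A, diag(2))
  ts <- simulate_timeseries(m, 50000, seed = 12)
  SU <- lyapunov_cov(A, diag(2))
  expect_lt(norm(cov(ts$values) - SU, "F") / norm(SU, "F"), 0.05)

  # seed determinism
  ts_b <- simulate_timeseries(m, 500, seed = 13)
  ts_c <- simulate_timeseries(m, 500, seed = 13)
  expect_identical(ts_b$values, ts_c$values)

  bad <- var_model(diag(2) * 1.05, diag(2))
  expect_error(simulate_timeseries(bad, 500, seed = 1), "stationary")
  expect_error(simulate_timeseries(m, 5, seed = 1), "n_samples")
})

test_that("cohorts are reproducible with independent subjects", {
  sp <- cohort_spec(n_subjects = 5, n_regions = 6, core_regions = 1:3,
                    n_samples = 200, seed = 21)
  coh <- generate_cohort(sp)
  expect_length(coh$series, 5)
  labs <- lapply(coh$series, `[[`, "region_labels")
  expect_true(all(vapply(labs, identical, TRUE, labs[[1]])))
  expect_false(identical(coh$series[[1]]$values, coh$series[[2]]$values))
  expect_identical(coh$core, 1:3)
  coh2 <- generate_cohort(sp)
  expect_identical(coh$series[[3]]$values, coh2$series[[3]]$values)
})

test_that("hypnogram generator respects profiles and absorbing chains", {
  h <- generate_hypnogram("n1", seed = 5)
  expect_length(h$stages, 30)
  expect_true(all(h$stages %in% 0:3))

  # absorbing wake chain: identity transition from state 0
  P <- diag(4)
  h0 <- generate_hypnogram("custom", seed = 6, transition = P, init = 0L)
  expect_identical(h0$stages, rep(0L, 30))

  # profiles span distinct depths
  means <- vapply(c("wake", "n1", "n2"), function(p) {
    mean(vapply(1:50, function(s) {
      mean(generate_hypnogram(p, seed = s)$stages)
    }, 0))
  }, 0)
  expect_true(means[["wake"]] < means[["n1"]],
              means[["n1"]] < means[["n2"]])
  expect_error(generate_hypnogram("rem", seed = 1))
})

test_that("coordinates and smooth maps have the stated spatial structure", {
  co <- generate_coordinates(60, seed = 31)
  D <- co$distances
  expect_true(isSymmetric(D))
  expect_equal(diag(D), rep(0, 60))
  expect_true(all(rowSums(co$positions^2) <= 1 + 1e-12))

  # lengthscale 0: nearest-neighbor values uncorrelated
  rough <- smooth_map(co, lengthscale = 0, seed = 32)
  nb <- apply(D + diag(99, 60), 1, which.min)
  expect_lt(abs(cor(rough, rough[nb])), 0.15)

  # large lengthscale: variogram increases over the first half of bins
  smooth <- smooth_map(co, lengthscale = 0.8, seed = 32)
  vg <- empirical_variogram(smooth, D, n_bins = 10)
  half <- vg$gamma[1:5]
  expect_true(all(diff(half) > 0))
  expect_identical(smooth_map(co, 0.8, seed = 32), smooth)
})

test_that("text round trips preserve series, hypnograms and coordinates", {
  dir <- withr::local_tempdir()
  ts <- parcellated_ts(matrix(rnorm(40), 20, 2), 0.72,
                       c("LH_Vis", "RH_Default"), "subj01")
  p <- file.path(dir, "ts.tsv")
  write_parcellated_ts(ts, p)
  back <- read_parcellated_ts(p)
  expect_equal(back$values, ts$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(back$region_labels, ts$region_labels)
  expect_equal(back$sampling_interval, 0.72)
  expect_identical(back$session_id, "subj01")

  h <- hypnogram(rep(c(0L, 1L, 2L), 10), "sess1")
  hp <- file.path(dir, "sess1.txt")
  write_hypnogram(h, hp)
  expect_identical(read_hypnogram(hp)$stages, h$stages)

  co <- generate_coordinates(5, seed = 2)
  cp <- file.path(dir, "coords.tsv")
  write_coordinates(co, cp)
  expect_equal(read_coordinates(cp)$distances, co$distances,
               tolerance = 1e-6)

  g <- causal_graph(matrix(c(0, 2, 1, 0), 2, 2), c("A", "B"))
  gp <- file.path(dir, "graph.tsv")
  write_causal_graph(g, gp)
  expect_equal(read_causal_graph(gp)$weights, g$weights)
})
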