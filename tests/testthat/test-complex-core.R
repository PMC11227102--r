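test_that("bipartition strength is the smaller directed cut sum", {
  g <- causal_graph(rbind(c(0, 3), c(1, 0)))   # w(1->2) = 1?? see below
  # weights[i, j] = flow j -> i: here 2->1 carries 3, 1->2 carries 1
  expect_equal(bipartition_strength(g, 1), 1)
  g_uni <- causal_graph(rbind(c(0, 5), c(0, 0)))
  expect_equal(bipartition_strength(g_uni, 1), 0)
  # random 6-node graphs vs double-loop summation oracle
  for (r in 1:100) {
    W <- random_graph(6, 500 + r)
    gr <- causal_graph(W)
    sub <- withr::with_seed(600 + r, sort(sample(1:6, sample(1:5, 1))))
    ref <- {
      rest <- setdiff(1:6, sub)
      fwd <- 0; bwd <- 0
      for (i in sub) for (j in rest) {
        fwd <- fwd + W[j, i]; bwd <- bwd + W[i, j]
      }
      min(fwd, bwd)
    }
    expect_equal(bipartition_strength(gr, sub), ref)
  }
  expect_error(bipartition_strength(g, 1:2), "proper subset")
})

test_that("minimum cuts match analytic fixtures and the max-flow reduction", {
  # two disjoint bidirectional pairs: cutting between them costs nothing
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 5
  W[3, 4] <- W[4, 3] <- 2
  g <- causal_graph(W)
  expect_equal(min_cut(g)$strength, 0)

  # complete uniform bidirectional graph: singleton split, (n-1) w
  for (n in c(4, 6)) {
    w <- 0.7
    Wu <- matrix(w, n, n); diag(Wu) <- 0
    mc <- min_cut(causal_graph(Wu), method = "exhaustive")
    expect_equal(mc$strength, (n - 1) * w)
    expect_true(length(mc$subset) %in% c(1, n - 1))
  }

  # max-flow solver agrees with exhaustive enumeration on random graphs
  for (r in 1:100) {
    g <- causal_graph(random_graph(8, 700 + r))
    e <- min_cut(g, method = "exhaustive")
    f <- min_cut(g, method = "maxflow")
    expect_equal(f$strength, e$strength, tolerance = 1e-10)
  }
  expect_error(min_cut(causal_graph(matrix(0, 2, 2)), within = 1),
               "at least 2")
})

test_that("hierarchical complex extraction matches analytic fixtures", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 5
  W[3, 4] <- W[4, 3] <- 2
  h <- extract_complexes(causal_graph(W))
  expect_identical(h$main_complex, 1:2)
  expect_equal(h$main_weight, 5)
  # both pairs qualify as complexes; the whole (weight 0) does too
  entry_sets <- lapply(h$entries, `[[`, "subset")
  expect_true(any(vapply(entry_sets, identical, TRUE, 3:4)))

  n <- 5; w <- 1.2
  Wu <- matrix(w, n, n); diag(Wu) <- 0
  h2 <- extract_complexes(causal_graph(Wu))
  expect_identical(h2$main_complex, 1:5)
  expect_equal(h2$main_weight, (n - 1) * w)
})

test_that("hierarchical extraction equals the all-subsets oracle", {
  for (r in 1:20) {
    W <- random_graph(8, 900 + r)
    h <- extract_complexes(causal_graph(W))
    ref <- brute_main_complex(W)
    expect_identical(h$main_complex, ref$subset)
    expect_equal(h$main_weight, ref$weight, tolerance = 1e-10)
    # the whole system is itself a candidate subsystem
    whole <- Filter(function(e) length(e$subset) == 8, h$hierarchy)
    expect_gte(h$main_weight, whole[[1]]$weight)
  }
})

test_that("the main complex has >= 2 nodes and is permutation equivariant", {
  W <- random_graph(7, 77)
  mc <- main_complex(causal_graph(W))
  expect_gte(length(mc$subset), 2)
  perm <- c(4, 1, 7, 3, 2, 6, 5)
  Wp <- W[perm, perm]
  mcp <- main_complex(causal_graph(Wp))
  expect_setequal(perm[mcp$subset], mc$subset)
  expect_equal(mcp$weight, mc$weight)

  # locality: edges incident only to nodes outside a separable main
  # complex do not affect it
  W2 <- matrix(0, 5, 5)
  W2[1, 2] <- W2[2, 1] <- 4
  W2[4, 5] <- W2[5, 4] <- 1
  base <- main_complex(causal_graph(W2))
  W2b <- W2
  W2b[4, 5] <- W2b[5, 4] <- 0
  expect_identical(main_complex(causal_graph(W2b))$subset, base$subset)
})

test_that("the planted core is recovered across a simulated cohort", {
  sp <- cohort_spec(n_subjects = 10, n_regions = 10, core_regions = 1:5,
                    core_weight = 0.15, n_samples = 4000, seed = 11)
  coh <- generate_cohort(sp)
  hits <- vapply(coh$series, function(ts) {
    setequal(main_complex(gc_matrix(ts))$subset, coh$core)
  }, TRUE)
  expect_gte(sum(hits), 9)
  # participation rates separate core from background at this SNR
  sets <- lapply(coh$series, function(ts) main_complex(gc_matrix(ts))$subset)
  pm <- participation_rates(sets, 10)
  expect_gte(mean(pm$rates[1:5]), 0.9)
  expect_lte(mean(pm$rates[6:10]), 0.2)
})

test_that("graphs with substantially negative weights are refused", {
  W <- matrix(0.5, 3, 3)
  W[1, 2] <- -0.2
  expect_error(causal_graph(W), "negative")
})
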