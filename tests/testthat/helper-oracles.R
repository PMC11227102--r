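# Independent oracles used across the suite. All are deliberately naive
# (enumeration, closed forms, direct moment algebra) and never call the
# package code paths they check.

# stationary covariance of U_{t+1} = A U_t + E: solve S = A S A' + Sigma_E
# via the Kronecker-vectorized linear system
lyapunov_cov <- function(A, Sigma) {
  n <- nrow(A)
  matrix(solve(diag(n * n) - kronecker(A, A), as.vector(Sigma)), n, n)
}

# population conditional Granger causality source -> target for a VAR(1)
# with known A, Sigma (unit-lag linear prediction): full residual variance
# is Sigma[target, target]; the reduced model predicts U_target(t+1) from
# all lagged regions except the source.
population_gc <- function(A, Sigma, source, target) {
  SU <- lyapunov_cov(A, Sigma)
  cross <- SU %*% t(A)                      # Cov(U_t, U_{t+1})
  keep <- setdiff(seq_len(nrow(A)), source)
  Sxx <- SU[keep, keep, drop = FALSE]
  sxy <- cross[keep, target]
  var_y <- (A %*% SU %*% t(A))[target, target] + Sigma[target, target]
  s_red <- var_y - drop(t(sxy) %*% solve(Sxx, sxy))
  log(s_red / Sigma[target, target])
}

# brute-force minimum bidirectional cut weight of `within`, enumerating
# every bipartition and summing crossing edges directly
brute_wmc <- function(W, within) {
  m <- length(within)
  best <- Inf
  bits <- bitwShiftL(1L, 0:(m - 2))
  for (mask in 0:(bitwShiftL(1L, m - 1L) - 2L)) {
    side <- within[c(1L, 1L + which(bitwAnd(mask, bits) != 0))]
    rest <- setdiff(within, side)
    v <- min(sum(W[rest, side]), sum(W[side, rest]))
    best <- min(best, v)
  }
  best
}

# brute-force main complex: evaluate w_mc on every subset of size >= 2 and
# apply the definition (w_mc strictly above every strict superset's w_mc);
# tie-break by weight, then size, then label order
brute_main_complex <- function(W) {
  n <- nrow(W)
  subs <- unlist(lapply(2:n, function(m) utils::combn(n, m, simplify = FALSE)),
                 recursive = FALSE)
  wmc <- vapply(subs, function(s) brute_wmc(W, s), 0)
  is_complex <- vapply(seq_along(subs), function(i) {
    sup <- which(vapply(subs, function(t) {
      length(t) > length(subs[[i]]) && all(subs[[i]] %in% t)
    }, TRUE))
    all(wmc[i] > wmc[sup])
  }, TRUE)
  idx <- which(is_complex)
  keys <- vapply(subs[idx], function(s) paste(s, collapse = " "), "")
  best <- idx[order(-wmc[idx], -vapply(subs[idx], length, 0L), keys)][1]
  list(subset = subs[[best]], weight = wmc[best])
}

random_graph <- function(n, seed) {
  withr::with_seed(seed, {
    W <- matrix(runif(n * n), n, n)
    diag(W) <- 0
    W
  })
}

# dense 2-parameter grid search for the diagonally-constrained Gaussian KL
# objective of a 2-region VAR(1) fit (coarse pass then local refinement)
grid_phi_g <- function(ts) {
  X <- ts$values[-nrow(ts$values), ]
  Y <- ts$values[-1, ]
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  d <- nrow(Yc) - 3
  Bh <- solve(crossprod(Xc), crossprod(Xc, Yc))
  ld_full <- log(det(crossprod(Yc - Xc %*% Bh) / d))
  obj <- function(a) {
    0.5 * (log(det(crossprod(Yc - Xc %*% diag(a)) / d)) - ld_full)
  }
  gr <- seq(-0.9, 0.9, length.out = 121)
  vals <- outer(gr, gr, Vectorize(function(a, b) obj(c(a, b))))
  ij <- which(vals == min(vals), arr.ind = TRUE)[1, ]
  g2a <- seq(gr[max(ij[1] - 2, 1)], gr[min(ij[1] + 2, 121)],
             length.out = 101)
  g2b <- seq(gr[max(ij[2] - 2, 1)], gr[min(ij[2] + 2, 121)],
             length.out = 101)
  min(outer(g2a, g2b, Vectorize(function(a, b) obj(c(a, b)))))
}

# adjusted Rand index between two labelings (contingency-table closed form)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  s_ij <- sum_comb(tab)
  s_a <- sum_comb(rowSums(tab))
  s_b <- sum_comb(colSums(tab))
  expected <- s_a * s_b / choose(n, 2)
  (s_ij - expected) / ((s_a + s_b) / 2 - expected)
}

# region coordinates reordered so regions 1..n are sorted by distance from
# region 1: makes a planted core in regions 1..k spatially contiguous
clustered_coords <- function(n, seed) {
  co <- generate_coordinates(n, seed)
  region_coordinates(co$positions[order(co$distances[1, ]), ])
}

restrict_ts <- function(ts, idx) {
  parcellated_ts(ts$values[, idx, drop = FALSE], ts$sampling_interval,
                 ts$region_labels[idx], ts$session_id)
}
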