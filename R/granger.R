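#' Directed causal graph
#'
#' Weight matrix of conditional Granger causality values; entry `(i, j)`
#' holds `F_{j -> i | Z}`, the causality from region `j` to region `i`
#' conditioned on all remaining regions. The diagonal is defined as 0 and
#' small negative finite-sample estimates are clipped to 0.
#'
#' @param weights n x n numeric matrix (targets in rows, sources in
#'   columns).
#' @param region_labels unique labels, one per region.
#' @param order VAR lag order the weights were computed at.
#' @return An object of class `causal_graph`.
#' @export
causal_graph <- function(weights, region_labels = NULL, order = 1L) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  stopifnot(ncol(weights) == n, all(is.finite(weights)))
  region_labels <- region_labels %||% rownames(weights) %||%
    paste0("R", seq_len(n))
  if (any(weights < -1e-6)) {
    stop("causal graph has substantially negative weights")
  }
  weights <- pmax(weights, 0)
  diag(weights) <- 0
  dimnames(weights) <- list(region_labels, region_labels)
  structure(list(weights = weights, region_labels = region_labels,
                 order = as.integer(order)),
            class = "causal_graph")
}

#' @export
print.causal_graph <- function(x, ...) {
  cat(sprintf("causal_graph: %d regions, VAR order %d, total weight %.4f\n",
              nrow(x$weights), x$order, sum(x$weights)))
  invisible(x)
}

# centered lagged design for a VAR(p) fit: response rows t = p+1..T,
# regressors are lags 1..p of every region (n*p columns)
lagged_design <- function(values, order) {
  T <- nrow(values)
  n <- ncol(values)
  if (T <= order * n + 10) {
    stop("series too short for the requested VAR order (need T > order*n + 10)")
  }
  Y <- values[(order + 1):T, , drop = FALSE]
  X <- do.call(cbind, lapply(seq_len(order), function(l) {
    values[(order + 1 - l):(T - l), , drop = FALSE]
  }))
  list(Y = Y, X = X, n = n, p = order, N = nrow(Y))
}

# OLS solve from centered cross-products; errors on rank deficiency unless
# ridge > 0 adds a diagonal penalty
ols_from_moments <- function(Sxx, Sxy, ridge = 0) {
  if (ridge > 0) Sxx <- Sxx + diag(ridge, nrow(Sxx))
  rc <- rcond(Sxx)
  if (rc < 1e-12) {
    stop(sprintf(paste0("regressor matrix is rank deficient ",
                        "(reciprocal condition number %.3e); ",
                        "consider the ridge fallback"), rc), call. = FALSE)
  }
  solve(Sxx, Sxy)
}

var_moments <- function(design) {
  Xc <- scale(design$X, scale = FALSE)
  Yc <- scale(design$Y, scale = FALSE)
  list(Sxx = crossprod(Xc), Sxy = crossprod(Xc, Yc), Syy = crossprod(Yc),
       N = design$N, k = ncol(design$X) + 1L)  # +1: intercept (mean removal)
}

#' Fit a VAR model by ordinary least squares
#'
#' Estimates the lag coefficients and innovation covariance of a VAR(p) by
#' per-equation OLS with an intercept. The residual covariance uses the
#' degrees-of-freedom denominator `T_eff - (n p + 1)`, which matters for the
#' determinant ratios downstream.
#'
#' @param ts a [parcellated_ts()].
#' @param order lag order (default 1).
#' @param ridge optional nonnegative ridge penalty used as a fallback for
#'   rank-deficient designs (default 0 = plain OLS).
#' @return A [var_model()] with the fitted coefficients and residual
#'   covariance; attribute `"rcond"` records the design's reciprocal
#'   condition number.
#' @examples
#' m <- var_model(matrix(c(0.5, 0, 0.2, 0.4), 2, 2), diag(2))
#' fit <- fit_var(simulate_timeseries(m, 2000, seed = 1))
#' @export
fit_var <- function(ts, order = 1, ridge = 0) {
  stopifnot(inherits(ts, "parcellated_ts"))
  d <- lagged_design(ts$values, order)
  mom <- var_moments(d)
  B <- ols_from_moments(mom$Sxx, mom$Sxy, ridge)  # (n p) x n
  resid_ss <- mom$Syy - crossprod(B, mom$Sxy) -
    crossprod(mom$Sxy, B) + t(B) %*% mom$Sxx %*% B
  Sigma <- (resid_ss + t(resid_ss)) / (2 * (mom$N - mom$k))
  coefs <- array(0, c(order, d$n, d$n))
  for (l in seq_len(order)) {
    coefs[l, , ] <- t(B[((l - 1) * d$n + 1):(l * d$n), , drop = FALSE])
  }
  out <- var_model(coefs, Sigma, ts$region_labels)
  attr(out, "rcond") <- rcond(mom$Sxx)
  attr(out, "n_obs") <- mom$N
  out
}

# scalar residual variance of regressing one target column on a subset of
# lagged regressors, from precomputed moments; denominator N - n_coef - 1
target_resid_var <- function(mom, y_col, x_idx, ridge = 0) {
  Sxx <- mom$Sxx[x_idx, x_idx, drop = FALSE]
  Sxy <- mom$Sxy[x_idx, y_col, drop = FALSE]
  b <- ols_from_moments(Sxx, Sxy, ridge)
  ss <- mom$Syy[y_col, y_col] - drop(crossprod(Sxy, b))
  ss / (mom$N - length(x_idx) - 1L)
}

#' Conditional Granger causality between two regions
#'
#' Computes `F_{source -> target | Z} = log(sigma2_reduced / sigma2_full)`,
#' where the full model regresses the target on the past of every region and
#' the reduced model omits the source's past; the conditioning set `Z` is
#' always all remaining regions. Negative finite-sample values are clipped
#' to 0.
#'
#' @param ts a [parcellated_ts()].
#' @param source,target region indices (1-based) or labels; must differ.
#' @param order VAR lag order (default 1).
#' @param ridge ridge fallback as in [fit_var()].
#' @return Nonnegative scalar causality in nats.
#' @export
conditional_gc <- function(ts, source, target, order = 1, ridge = 0) {
  stopifnot(inherits(ts, "parcellated_ts"))
  source <- resolve_region(ts, source)
  target <- resolve_region(ts, target)
  if (source == target) stop("source and target must differ")
  d <- lagged_design(ts$values, order)
  mom <- var_moments(d)
  gc_from_moments(mom, source, target, d$n, order, ridge)
}

gc_from_moments <- function(mom, source, target, n, order, ridge = 0) {
  full_idx <- seq_len(n * order)
  red_idx <- full_idx[((full_idx - 1) %% n) + 1 != source]
  s_full <- target_resid_var(mom, target, full_idx, ridge)
  s_red <- target_resid_var(mom, target, red_idx, ridge)
  max(log(s_red / s_full), 0)
}

resolve_region <- function(ts, r) {
  if (is.character(r)) {
    i <- match(r, ts$region_labels)
    if (is.na(i)) stop("unknown region label: ", r)
    return(i)
  }
  i <- as.integer(r)
  if (i < 1 || i > n_regions(ts)) stop("region index out of range")
  i
}

#' Conditional Granger causality matrix
#'
#' Applies [conditional_gc()] to every ordered pair of regions, sharing the
#' lagged cross-moment matrices across pairs, and returns the directed
#' weight matrix as a [causal_graph()].
#'
#' @inheritParams conditional_gc
#' @return A `causal_graph` with `weights[i, j] = F_{j -> i | Z}`.
#' @export
gc_matrix <- function(ts, order = 1, ridge = 0) {
  stopifnot(inherits(ts, "parcellated_ts"))
  d <- lagged_design(ts$values, order)
  mom <- var_moments(d)
  n <- d$n
  W <- matrix(0, n, n)
  for (target in seq_len(n)) {
    for (source in seq_len(n)) {
      if (source != target) {
        W[target, source] <- gc_from_moments(mom, source, target, n, order,
                                             ridge)
      }
    }
  }
  causal_graph(W, ts$region_labels, order = order)
}
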