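# Shared machinery: both Phi measures are minimized Gaussian KL divergences
# between the fitted full VAR transition model and a constrained
# ("disconnected") model U_{t+1} = A' U_t + E'. With the residual covariance
# of the constrained model profiled out in closed form, the objective
# reduces to 1/2 * [logdet M(A') - logdet Sigma(E)], where
# M(A') = cov of (Y - A'X) on the aligned sample. At A' = Ahat (OLS) this is
# 0; at A' = 0 it is the mutual information Phi_M; minimizing over diagonal
# A' gives Phi_G. All moments share the same centering and
# degrees-of-freedom denominator so the nesting Phi_M >= Phi_G >= 0 holds
# exactly on fitted models.

phi_moments <- function(ts, order) {
  d <- lagged_design(ts$values, order)
  mom <- var_moments(d)
  denom <- mom$N - mom$k
  Bhat <- ols_from_moments(mom$Sxx, mom$Sxy)
  rss <- mom$Syy - crossprod(Bhat, mom$Sxy) - crossprod(mom$Sxy, Bhat) +
    t(Bhat) %*% mom$Sxx %*% Bhat
  list(mom = mom, n = d$n, p = order, denom = denom, Bhat = Bhat,
       ld_full = logdet_spd(rss / denom, "full-model residual"))
}

# logdet of the constrained-model residual covariance at coefficient matrix
# B ((n p) x n); quadratic in B via the cross-moment matrices
constrained_logdet <- function(pm, B) {
  mom <- pm$mom
  ss <- mom$Syy - crossprod(B, mom$Sxy) - crossprod(mom$Sxy, B) +
    t(B) %*% mom$Sxx %*% B
  logdet_spd(ss / pm$denom, "constrained-model residual")
}

diag_to_B <- function(a, n, p) {
  B <- matrix(0, n * p, n)
  for (l in seq_len(p)) {
    B[cbind((l - 1) * n + seq_len(n), seq_len(n))] <- a[(l - 1) * n +
                                                          seq_len(n)]
  }
  B
}

#' Mutual information of consecutive system states
#'
#' `Phi_M = 1/2 * log(|Sigma(U)| / |Sigma(E)|)` in nats: the Gaussian mutual
#' information between the system's past and present, i.e. the KL divergence
#' from the fitted full VAR model to the model whose transition matrix is
#' identically zero. `Sigma(U)` is the sample covariance of the response
#' block and `Sigma(E)` the full-model residual covariance, both with the
#' same centering and denominator (see [fit_var()]).
#'
#' @param ts a [parcellated_ts()].
#' @param order VAR lag order (default 1).
#' @return Nonnegative scalar in nats.
#' @examples
#' m <- var_model(matrix(c(0.5, 0, 0.2, 0.4), 2, 2), diag(2))
#' phi_m(simulate_timeseries(m, 2000, seed = 1))
#' @export
phi_m <- function(ts, order = 1) {
  pm <- phi_moments(ts, order)
  val <- 0.5 * (constrained_logdet(pm, matrix(0, pm$n * pm$p, pm$n)) -
                  pm$ld_full)
  max(val, 0)
}

#' Geometric integrated information
#'
#' `Phi_G = min_q D_KL(p || q) = 1/2 * log(|Sigma(E')| / |Sigma(E)|)` in
#' nats, where the disconnected model `q` is constrained to a diagonal
#' transition matrix (self-influence kept, all cross-region influence
#' removed) and its residual covariance is profiled out in closed form.
#'
#' `method = "pernode"` sets each diagonal entry by single-regressor least
#' squares of a region on its own past and evaluates the objective there;
#' `method = "refine"` (default) numerically minimizes the objective over
#' the diagonal entries (BFGS, objective tolerance 1e-10), initialized at
#' the per-node solution, and is never worse.
#'
#' @inheritParams phi_m
#' @param method `"refine"` or `"pernode"`.
#' @return Nonnegative scalar in nats; attributes `"diag_coef"` (the
#'   optimized diagonal) and, for `"refine"`, `"converged"`.
#' @export
phi_g <- function(ts, order = 1, method = c("refine", "pernode")) {
  method <- match.arg(method)
  pm <- phi_moments(ts, order)
  n <- pm$n
  p <- pm$p
  mom <- pm$mom
  # per-node init: region i on its own lag(s) only
  a0 <- numeric(n * p)
  for (i in seq_len(n)) {
    idx <- (seq_len(p) - 1) * n + i
    b <- solve(mom$Sxx[idx, idx, drop = FALSE],
               mom$Sxy[idx, i, drop = FALSE])
    a0[idx] <- b
  }
  objective <- function(a) {
    constrained_logdet(pm, diag_to_B(a, n, p))
  }
  if (method == "pernode") {
    val <- 0.5 * (objective(a0) - pm$ld_full)
    a_best <- a0
    converged <- NA
  } else {
    opt <- optim(a0, objective, method = "BFGS",
                 control = list(reltol = 1e-12, maxit = 500))
    # keep whichever of init/optimum is lower (optim can stall)
    if (opt$value <= objective(a0)) {
      a_best <- opt$par
      best <- opt$value
    } else {
      a_best <- a0
      best <- objective(a0)
    }
    val <- 0.5 * (best - pm$ld_full)
    converged <- opt$convergence == 0
  }
  out <- max(val, 0)
  attr(out, "diag_coef") <- a_best
  attr(out, "converged") <- converged
  out
}

subsets_of_size <- function(n, sizes) {
  out <- list()
  for (m in sizes) {
    cm <- utils::combn(n, m)
    out <- c(out, lapply(seq_len(ncol(cm)), function(j) cm[, j]))
  }
  out
}

#' Maximizing subsystem of a Phi measure
#'
#' Evaluates `Phi_G` or `Phi_M` on candidate subsystems — refitting the VAR
#' on the subsystem's own columns — and returns the maximizer; the maximum
#' over subsystems is reported as the Phi of the system.
#' `strategy = "exhaustive"` enumerates every subset of at least `min_size`
#' regions (capped at 15 regions); `strategy = "hierarchical"` restricts
#' candidates to the nested subsystems of the complex hierarchy of the
#' system's causal graph, plus the full set.
#'
#' @inheritParams phi_m
#' @param measure `"phi_g"` or `"phi_m"`.
#' @param min_size smallest subsystem size considered (default 2).
#' @param strategy `"exhaustive"` or `"hierarchical"`.
#' @param phi_method method passed to [phi_g()].
#' @return An object of class `phi_result`: list with `value`, `measure`,
#'   `subsystem` (indices), `labels`, `n_candidates`, `full_value`.
#' @export
max_phi_subsystem <- function(ts, measure = c("phi_g", "phi_m"),
                              order = 1, min_size = 2,
                              strategy = c("exhaustive", "hierarchical"),
                              phi_method = "refine") {
  measure <- match.arg(measure)
  strategy <- match.arg(strategy)
  n <- n_regions(ts)
  if (min_size < 2) stop("min_size must be at least 2")
  if (strategy == "exhaustive") {
    if (n > 15) stop("exhaustive subsystem search capped at 15 regions")
    candidates <- subsets_of_size(n, min_size:n)
  } else {
    h <- extract_complexes(gc_matrix(ts, order = order))
    candidates <- lapply(h$hierarchy, `[[`, "subset")
    candidates <- candidates[vapply(candidates, length, 0L) >= min_size]
    candidates <- unique(c(list(seq_len(n)), candidates))
  }
  evaluate <- function(idx) {
    sub <- parcellated_ts(ts$values[, idx, drop = FALSE],
                          ts$sampling_interval,
                          ts$region_labels[idx], ts$session_id)
    if (measure == "phi_g") as.numeric(phi_g(sub, order, phi_method))
    else phi_m(sub, order)
  }
  vals <- vapply(candidates, evaluate, 0)
  best <- which.max(vals)
  structure(
    list(value = vals[best], measure = measure,
         subsystem = candidates[[best]],
         labels = ts$region_labels[candidates[[best]]],
         n_candidates = length(candidates),
         full_value = vals[[which(vapply(candidates, length, 0L) == n)[1]]]),
    class = "phi_result")
}

#' @export
print.phi_result <- function(x, ...) {
  cat(sprintf("%s = %.4f nats over subsystem {%s} (%d candidates)\n",
              x$measure, x$value, paste(x$labels, collapse = ", "),
              x$n_candidates))
  invisible(x)
}
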