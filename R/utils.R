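#' @importFrom stats coef cor lm optim p.adjust pf qf pt qnorm rnorm runif
#'   sd var kmeans quantile
#' @importFrom utils head read.table write.table
NULL

# log(det(S)) for a symmetric positive-definite matrix via Cholesky;
# errors with the reciprocal condition number when S is (numerically) singular
logdet_spd <- function(S, label = "covariance") {
  S <- (S + t(S)) / 2
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    stop(sprintf("%s matrix is not positive definite (rcond = %.3e)",
                 label, rcond(S)), call. = FALSE)
  }
  2 * sum(log(diag(ch)))
}

rcond <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

is_spd <- function(S, tol = 1e-10) {
  if (!isSymmetric(unname(S), tol = 1e-8)) return(FALSE)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol * max(abs(ev), 1))
}

is_psd <- function(S, tol = 1e-8) {
  if (!isSymmetric(unname(S), tol = 1e-8)) return(FALSE)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  all(ev > -tol * max(abs(ev), 1))
}

spectral_radius <- function(A) max(Mod(eigen(A, only.values = TRUE)$values))

# companion matrix of lag coefficient array (p x n x n)
companion_matrix <- function(coefficients) {
  p <- dim(coefficients)[1]
  n <- dim(coefficients)[2]
  C <- matrix(0, n * p, n * p)
  for (l in seq_len(p)) {
    C[1:n, ((l - 1) * n + 1):(l * n)] <- coefficients[l, , ]
  }
  if (p > 1) {
    C[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  }
  C
}

# deterministic child seeds, kept within 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
}
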