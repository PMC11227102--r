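#' Vector autoregressive model
#'
#' Container for a VAR(p) process `U_{t+1} = A1 U_t + ... + Ap U_{t-p+1} + E`
#' with Gaussian innovations `E ~ N(0, noise_cov)`. Used both for synthetic
#' ground-truth models and for models estimated from data by [fit_var()].
#'
#' @param coefficients numeric array of dimension `order x n x n`
#'   (`coefficients[l, i, j]` is the effect of region `j` at lag `l` on
#'   region `i`), or an `n x n` matrix for a VAR(1).
#' @param noise_cov `n x n` symmetric positive-definite innovation covariance.
#' @param region_labels character vector of length `n`; defaults to
#'   `R1..Rn`.
#' @param intercept optional length-`n` intercept vector (defaults to zero).
#'
#' @return An object of class `var_model` with elements `order`,
#'   `coefficients`, `noise_cov`, `region_labels`, `intercept`.
#' @examples
#' m <- var_model(diag(2) * 0.5, diag(2))
#' is_stationary(m)
#' @export
var_model <- function(coefficients, noise_cov, region_labels = NULL,
                      intercept = NULL) {
  if (is.matrix(coefficients)) {
    coefficients <- array(coefficients, c(1, dim(coefficients)))
  }
  stopifnot(length(dim(coefficients)) == 3)
  n <- dim(coefficients)[2]
  if (dim(coefficients)[3] != n) stop("coefficient blocks must be square")
  if (!all(dim(noise_cov) == c(n, n))) stop("noise_cov dimension mismatch")
  # estimated residual covariances are Gram matrices: positive SEMIdefinite
  # is the guarantee (simulation additionally requires strict definiteness)
  if (!is_psd(noise_cov)) {
    stop("noise_cov must be symmetric positive semidefinite")
  }
  region_labels <- region_labels %||% paste0("R", seq_len(n))
  if (length(region_labels) != n || anyDuplicated(region_labels)) {
    stop("region_labels must be unique and match the number of regions")
  }
  intercept <- intercept %||% rep(0, n)
  structure(
    list(order = dim(coefficients)[1], coefficients = coefficients,
         noise_cov = noise_cov, region_labels = region_labels,
         intercept = intercept),
    class = "var_model")
}

#' @rdname var_model
#' @param model a `var_model`.
#' @return `is_stationary()`: `TRUE` when the companion-matrix spectral
#'   radius is below 1.
#' @export
is_stationary <- function(model) {
  spectral_radius(companion_matrix(model$coefficients)) < 1
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("VAR(%d) model: %d regions, spectral radius %.3f\n",
              x$order, length(x$region_labels),
              spectral_radius(companion_matrix(x$coefficients))))
  invisible(x)
}

#' Parcellated time series
#'
#' A regions-by-time multivariate series stored time-in-rows, as produced by
#' averaging a volumetric recording within atlas regions, plus its sampling
#' interval and session id.
#'
#' @param values numeric matrix, time in rows, one column per region.
#' @param sampling_interval seconds per sample (> 0).
#' @param region_labels unique character labels, one per column.
#' @param session_id string identifying the session.
#' @return An object of class `parcellated_ts`.
#' @examples
#' ts <- parcellated_ts(matrix(rnorm(40), 20, 2), 0.72)
#' n_samples(ts)
#' @export
parcellated_ts <- function(values, sampling_interval,
                           region_labels = NULL, session_id = "session") {
  values <- as.matrix(values)
  if (anyNA(values)) stop("time series must not contain missing values")
  if (!is.numeric(sampling_interval) || sampling_interval <= 0) {
    stop("sampling_interval must be > 0")
  }
  region_labels <- region_labels %||% colnames(values) %||%
    paste0("R", seq_len(ncol(values)))
  if (length(region_labels) != ncol(values) || anyDuplicated(region_labels)) {
    stop("region_labels must be unique, one per column")
  }
  colnames(values) <- region_labels
  structure(
    list(values = values, sampling_interval = sampling_interval,
         region_labels = region_labels, session_id = session_id),
    class = "parcellated_ts")
}

#' @rdname parcellated_ts
#' @param ts a `parcellated_ts`.
#' @export
n_samples <- function(ts) nrow(ts$values)

#' @rdname parcellated_ts
#' @export
n_regions <- function(ts) ncol(ts$values)

#' @export
print.parcellated_ts <- function(x, ...) {
  cat(sprintf("parcellated_ts '%s': %d samples x %d regions @ %.3g s\n",
              x$session_id, nrow(x$values), ncol(x$values),
              x$sampling_interval))
  invisible(x)
}

#' Hypnogram of a 15-minute session
#'
#' Sleep stages scored in 30-second epochs, coded Wake = 0, N1 = 1, N2 = 2,
#' N3 = 3. A standard session has exactly 30 epochs.
#'
#' @param stages integer vector with values in `0:3`.
#' @param session_id string.
#' @param n_epochs expected length (default 30); pass `NA` to accept any.
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(stages, session_id = "session", n_epochs = 30) {
  stages <- as.integer(stages)
  if (!all(stages %in% 0:3)) stop("stages must take values in 0..3")
  if (!is.na(n_epochs) && length(stages) != n_epochs) {
    stop(sprintf("hypnogram must have %d epochs, got %d",
                 n_epochs, length(stages)))
  }
  structure(list(stages = stages, session_id = session_id),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("hypnogram '%s': %s\n", x$session_id,
              paste(x$stages, collapse = "")))
  invisible(x)
}
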