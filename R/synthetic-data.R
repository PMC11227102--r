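#' Specification of a synthetic cohort with a planted bidirectional core
#'
#' Describes a set of subjects whose region time series follow a common
#' stationary VAR(1) whose off-diagonal coupling is `core_weight` inside a
#' designated core subset (in both directions) and `background_weight`
#' elsewhere, with `self_weight` on the diagonal. The planted core is the
#' ground truth against which downstream complex recovery is scored.
#'
#' @param n_subjects,n_regions positive integers.
#' @param core_regions integer indices (1-based) of the planted core;
#'   at least 2 regions.
#' @param core_weight nonnegative bidirectional coupling within the core.
#' @param background_weight nonnegative magnitude of couplings outside the
#'   core (sign-randomized when `randomize_background_sign`).
#' @param self_weight diagonal (self) coefficient, in (-1, 1).
#' @param n_samples samples to simulate per subject.
#' @param seed integer master seed; per-subject seeds are derived from it.
#' @param randomize_background_sign logical; default `TRUE`.
#' @return A `cohort_spec` list.
#' @examples
#' sp <- cohort_spec(n_subjects = 3, n_regions = 6, core_regions = 1:3,
#'                   core_weight = 0.15, n_samples = 500, seed = 1)
#' @export
cohort_spec <- function(n_subjects, n_regions, core_regions,
                        core_weight = 0.15, background_weight = 0.02,
                        self_weight = 0.5, n_samples = 4000, seed = 1,
                        randomize_background_sign = TRUE) {
  stopifnot_scalar_count(n_subjects, "n_subjects")
  stopifnot_scalar_count(n_regions, "n_regions", min = 2)
  core_regions <- sort(unique(as.integer(core_regions)))
  if (length(core_regions) < 2) {
    stop("core_regions must contain at least 2 regions")
  }
  if (any(core_regions < 1 | core_regions > n_regions)) {
    stop("core_regions out of range")
  }
  if (core_weight < 0 || background_weight < 0) {
    stop("coupling weights must be nonnegative")
  }
  if (abs(self_weight) >= 1) stop("self_weight must lie in (-1, 1)")
  stopifnot_scalar_count(n_samples, "n_samples")
  structure(
    list(n_subjects = n_subjects, n_regions = n_regions,
         core_regions = core_regions, core_weight = core_weight,
         background_weight = background_weight, self_weight = self_weight,
         n_samples = n_samples, seed = as.integer(seed),
         randomize_background_sign = randomize_background_sign),
    class = "cohort_spec")
}

#' Generate the VAR(1) network of a cohort specification
#'
#' Builds the coefficient matrix with `core_weight` on both directions of
#' every within-core pair, `background_weight` (optionally sign-randomized)
#' on all other off-diagonal entries and `self_weight` on the diagonal; if
#' the spectral radius reaches 1 the whole matrix is rescaled uniformly to
#' spectral radius 0.95, preserving relative weights. Innovations are unit
#' white noise.
#'
#' @param spec a [cohort_spec()].
#' @param target_radius spectral radius after rescaling (default 0.95).
#' @return A [var_model()].
#' @export
generate_var_network <- function(spec, target_radius = 0.95) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_regions
  A <- withr::with_seed(derive_seed(spec$seed, 1L), {
    A <- matrix(spec$background_weight, n, n)
    if (spec$randomize_background_sign && spec$background_weight > 0) {
      A <- A * matrix(sample(c(-1, 1), n * n, replace = TRUE), n, n)
    }
    A[spec$core_regions, spec$core_regions] <- spec$core_weight
    diag(A) <- spec$self_weight
    A
  })
  r <- spectral_radius(A)
  if (r >= 1) {
    A <- A * (target_radius / r)
    if (spectral_radius(A) >= 1) {
      stop("model cannot be rescaled to stationarity")
    }
  }
  var_model(A, diag(n))
}

#' Simulate a stationary VAR process
#'
#' Forward-simulates `U_{t+1} = A U_t + E` with Gaussian innovations of the
#' model's covariance, discarding an initial burn-in.
#'
#' @param model a stationary [var_model()].
#' @param n_samples number of retained samples; at least `10 * n_regions`.
#' @param seed integer seed (full reproducibility).
#' @param burn_in discarded initial samples (default 200).
#' @param sampling_interval recorded sampling interval in seconds.
#' @param session_id id stored on the result.
#' @return A [parcellated_ts()].
#' @examples
#' m <- var_model(matrix(c(0.5, 0, 0.2, 0.4), 2, 2), diag(2))
#' ts <- simulate_timeseries(m, 500, seed = 1)
#' @export
simulate_timeseries <- function(model, n_samples, seed, burn_in = 200,
                                sampling_interval = 2.1,
                                session_id = "sim") {
  stopifnot(inherits(model, "var_model"))
  if (!is_stationary(model)) stop("model is not stationary; refusing to simulate")
  n <- length(model$region_labels)
  if (n_samples < 10 * n) stop("n_samples must be at least 10 * n_regions")
  p <- model$order
  if (!is_spd(model$noise_cov)) {
    stop("simulation requires a strictly positive-definite noise covariance")
  }
  L <- chol(model$noise_cov)
  total <- n_samples + burn_in + p
  U <- withr::with_seed(as.integer(seed), {
    E <- matrix(rnorm(total * n), total, n) %*% L
    U <- matrix(0, total, n)
    U[seq_len(p), ] <- E[seq_len(p), ]
    for (t in seq(p, total - 1)) {
      u <- model$intercept
      for (l in seq_len(p)) {
        u <- u + model$coefficients[l, , ] %*% U[t - l + 1, ]
      }
      U[t + 1, ] <- u + E[t + 1, ]
    }
    U
  })
  parcellated_ts(U[(burn_in + p + 1):total, , drop = FALSE],
                 sampling_interval, model$region_labels, session_id)
}

#' Generate a synthetic cohort
#'
#' One independent simulation per subject from the cohort's planted-core
#' VAR(1); per-subject seeds are derived deterministically from the master
#' seed, so cohorts are reproducible while subjects stay independent.
#'
#' @param spec a [cohort_spec()].
#' @param burn_in passed to [simulate_timeseries()].
#' @return A list with `series` (list of `parcellated_ts`), `core`
#'   (ground-truth core indices), `core_labels`, and `model`.
#' @export
generate_cohort <- function(spec, burn_in = 200) {
  model <- generate_var_network(spec)
  series <- lapply(seq_len(spec$n_subjects), function(s) {
    simulate_timeseries(model, spec$n_samples,
                        seed = derive_seed(spec$seed, 100L + s),
                        burn_in = burn_in,
                        session_id = sprintf("subj%03d", s))
  })
  list(series = series, core = spec$core_regions,
       core_labels = model$region_labels[spec$core_regions], model = model)
}

stage_profiles <- function() {
  # rows = from-stage 0..3, columns = to-stage; monotone-tending chains
  list(
    wake = list(init = 0L, P = rbind(c(0.96, 0.04, 0.00, 0),
                                     c(0.50, 0.50, 0.00, 0),
                                     c(0.00, 0.50, 0.50, 0),
                                     c(0.00, 0.00, 0.50, 0.5))),
    n1 = list(init = 0L, P = rbind(c(0.35, 0.65, 0.00, 0),
                                   c(0.12, 0.80, 0.08, 0),
                                   c(0.00, 0.45, 0.55, 0),
                                   c(0.00, 0.00, 0.50, 0.5))),
    n2 = list(init = 1L, P = rbind(c(0.10, 0.90, 0.00, 0.00),
                                   c(0.02, 0.38, 0.60, 0.00),
                                   c(0.00, 0.06, 0.88, 0.06),
                                   c(0.00, 0.00, 0.40, 0.60)))
  )
}

#' Generate a session hypnogram
#'
#' Samples 30 epochs from a stage-profile Markov chain. The `wake` profile
#' stays almost entirely in stage 0, `n1` mixes wake and N1, `n2` descends
#' into N2 with some N1; a custom 4x4 transition matrix may be supplied.
#'
#' @param profile `"wake"`, `"n1"`, `"n2"`, or `"custom"`.
#' @param seed integer seed.
#' @param n_epochs number of epochs (default 30).
#' @param transition 4x4 row-stochastic matrix (required for `"custom"`).
#' @param init initial stage in 0..3 (custom profile only; default 0).
#' @param session_id id stored on the result.
#' @return A [hypnogram()].
#' @export
generate_hypnogram <- function(profile = c("wake", "n1", "n2", "custom"),
                               seed, n_epochs = 30, transition = NULL,
                               init = 0L, session_id = NULL) {
  profile <- match.arg(profile)
  if (profile == "custom") {
    if (is.null(transition) || !all(dim(transition) == c(4, 4))) {
      stop("custom profile requires a 4x4 transition matrix")
    }
    P <- transition / rowSums(transition)
  } else {
    prof <- stage_profiles()[[profile]]
    P <- prof$P
    init <- prof$init
  }
  stages <- withr::with_seed(as.integer(seed), {
    s <- integer(n_epochs)
    s[1] <- init
    for (t in seq_len(n_epochs - 1)) {
      s[t + 1] <- sample(0:3, 1, prob = P[s[t] + 1, ])
    }
    s
  })
  hypnogram(stages,
            session_id = session_id %||% sprintf("%s_%d", profile, seed),
            n_epochs = n_epochs)
}

#' Region coordinates
#'
#' Positions of region centroids in arbitrary 3D units, with the derived
#' pairwise Euclidean distance matrix used by the spatial-autocorrelation
#' surrogate machinery.
#'
#' @param positions n x 3 numeric matrix.
#' @return An object of class `region_coordinates` with `positions` and
#'   `distances`.
#' @export
region_coordinates <- function(positions) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be n x 3")
  D <- as.matrix(stats::dist(positions))
  dimnames(D) <- NULL
  structure(list(positions = unname(positions), distances = D),
            class = "region_coordinates")
}

#' Generate random region coordinates
#'
#' Samples region centroids uniformly inside the unit sphere.
#'
#' @param n_regions number of regions (at least 3).
#' @param seed integer seed.
#' @return A [region_coordinates()] object.
#' @export
generate_coordinates <- function(n_regions, seed) {
  stopifnot_scalar_count(n_regions, "n_regions", min = 3)
  pos <- withr::with_seed(as.integer(seed), {
    out <- matrix(NA_real_, n_regions, 3)
    k <- 0
    while (k < n_regions) {
      cand <- matrix(runif(3 * n_regions * 2, -1, 1), ncol = 3)
      keep <- cand[rowSums(cand^2) <= 1, , drop = FALSE]
      take <- min(nrow(keep), n_regions - k)
      if (take > 0) out[(k + 1):(k + take), ] <- keep[seq_len(take), ]
      k <- k + take
    }
    out
  })
  region_coordinates(pos)
}

#' Generate a spatially smooth region map
#'
#' Mixes white noise through a Gaussian distance kernel
#' `K_ij = exp(-d_ij^2 / (2 lengthscale^2))` (rows normalized), giving a
#' Gaussian-process-like map whose autocorrelation length is set by
#' `lengthscale`; `lengthscale = 0` returns plain white noise.
#'
#' @param coords a [region_coordinates()] object.
#' @param lengthscale kernel lengthscale in coordinate units (>= 0).
#' @param seed integer seed.
#' @return Numeric vector of per-region map values (standardized).
#' @export
smooth_map <- function(coords, lengthscale, seed) {
  stopifnot(inherits(coords, "region_coordinates"), lengthscale >= 0)
  n <- nrow(coords$positions)
  z <- withr::with_seed(as.integer(seed), rnorm(n))
  if (lengthscale == 0) return(as.numeric(scale(z)))
  K <- exp(-coords$distances^2 / (2 * lengthscale^2))
  K <- K / rowSums(K)
  as.numeric(scale(K %*% z))
}

#' Empirical variogram of a region map
#'
#' Half the mean squared difference of map values between region pairs,
#' binned by inter-region distance. Bins are equal-count (distance
#' quantiles) rather than equal-width, so the short-range estimate is not
#' dominated by a handful of close pairs.
#'
#' @param map numeric vector of per-region values.
#' @param distances n x n distance matrix.
#' @param n_bins number of equal-count distance bins (default 25).
#' @return A data frame with `distance` (mean pair distance per bin),
#'   `gamma` (semivariance) and `n_pairs`.
#' @export
empirical_variogram <- function(map, distances, n_bins = 25) {
  n <- length(map)
  stopifnot(all(dim(distances) == c(n, n)))
  iu <- which(upper.tri(distances), arr.ind = TRUE)
  d <- distances[iu]
  g <- 0.5 * (map[iu[, 1]] - map[iu[, 2]])^2
  breaks <- unique(quantile(d, seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(d, breaks, include.lowest = TRUE)
  data.frame(distance = as.numeric(tapply(d, bin, mean)),
             gamma = as.numeric(tapply(g, bin, mean)),
             n_pairs = as.integer(table(bin)))
}
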