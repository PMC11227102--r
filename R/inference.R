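#' Participation rates of regions in individual complexes
#'
#' For each region, the fraction of subjects (or sessions) whose main
#' complex contains that region.
#'
#' @param complexes list of node index sets (one per subject/session).
#' @param n_regions total number of regions.
#' @param condition label stored on the result.
#' @param region_labels optional labels.
#' @return An object of class `participation_map`: list with `rates`
#'   (length `n_regions`, in `[0, 1]`), `condition`, `n_units`,
#'   `region_labels`.
#' @export
participation_rates <- function(complexes, n_regions, condition = "condition",
                                region_labels = NULL) {
  if (length(complexes) == 0) stop("need at least one complex")
  counts <- numeric(n_regions)
  for (s in complexes) {
    s <- as.integer(s)
    if (any(s < 1 | s > n_regions)) stop("node index out of range")
    counts[s] <- counts[s] + 1
  }
  structure(
    list(rates = counts / length(complexes), condition = condition,
         n_units = length(complexes),
         region_labels = region_labels %||% paste0("R", seq_len(n_regions))),
    class = "participation_map")
}

#' @export
print.participation_map <- function(x, ...) {
  cat(sprintf("participation_map '%s': %d regions, %d units, mean %.3f\n",
              x$condition, length(x$rates), x$n_units, mean(x$rates)))
  invisible(x)
}

#' Variogram-matched spatial-autocorrelation surrogates
#'
#' Generates randomized copies of a region map that preserve its spatial
#' autocorrelation structure, for use as a permutation null on spatially
#' smooth maps. Each surrogate permutes the map, smooths it with a Gaussian
#' distance kernel (bandwidth chosen per surrogate among `bandwidths` by
#' least-squares fit of the binned empirical variogram to the original's),
#' rescales it as `sqrt(alpha) * smoothed + sqrt(beta) * noise` with
#' `(alpha, beta)` from the variogram regression, and (by default) maps the
#' result back onto the original value multiset by rank. With
#' `smooth = FALSE` surrogates are plain permutations of the map.
#'
#' @param map numeric per-region values (at least 10 regions).
#' @param distances n x n inter-region distance matrix.
#' @param n_surrogates number of surrogates.
#' @param seed integer seed (full determinism).
#' @param resample_values rank-map surrogate values onto the original
#'   multiset? Default `TRUE`.
#' @param smooth apply the variogram-matching machinery? Default `TRUE`.
#' @param n_bins equal-count distance bins for the variogram fit
#'   (default 25).
#' @param bandwidths candidate kernel bandwidths as fractions of the
#'   maximum distance.
#' @return A `n_surrogates x n` matrix, one surrogate map per row.
#' @export
variogram_surrogates <- function(map, distances, n_surrogates, seed,
                                 resample_values = TRUE, smooth = TRUE,
                                 n_bins = 25,
                                 bandwidths = c(0.03, 0.05, 0.08, 0.12,
                                                0.16, 0.22, 0.3, 0.4, 0.5)) {
  n <- length(map)
  if (n < 10) stop("surrogate generation requires at least 10 regions")
  stopifnot(all(is.finite(map)), all(dim(distances) == c(n, n)))
  if (sd(map) == 0) {           # constant map: every rearrangement is itself
    return(matrix(map, n_surrogates, n, byrow = TRUE))
  }
  sorted_vals <- sort(map)
  if (!smooth) {
    return(withr::with_seed(as.integer(seed), {
      t(replicate(n_surrogates, map[sample.int(n)]))
    }))
  }
  withr::with_seed(as.integer(seed), {
    vg_obs <- empirical_variogram(map, distances, n_bins)
    hs <- bandwidths * max(distances)
    kernels <- lapply(hs, function(h) {
      K <- exp(-distances^2 / (2 * h^2))
      K / rowSums(K)
    })
    # relative least squares: short-range bins (small gamma) carry the
    # spatial-autocorrelation signature and must not be swamped by the sill
    w <- vg_obs$n_pairs / pmax(vg_obs$gamma, 1e-8)^2
    out <- matrix(NA_real_, n_surrogates, n)
    for (s in seq_len(n_surrogates)) {
      xp <- map[sample.int(n)]
      noise <- rnorm(n)
      best <- NULL
      best_sse <- Inf
      for (K in kernels) {
        y <- as.numeric(K %*% xp)
        vg_y <- empirical_variogram(y, distances, n_bins)
        # regress observed variogram on the smoothed surrogate's variogram
        fit <- lm(vg_obs$gamma ~ vg_y$gamma, weights = w)
        alpha <- max(coef(fit)[2], 0)
        beta <- max(coef(fit)[1], 0)
        cand <- sqrt(alpha) * y + sqrt(beta) * noise
        sse <- sum(w * (alpha * vg_y$gamma + beta - vg_obs$gamma)^2)
        if (sse < best_sse) {
          best_sse <- sse
          best <- cand
        }
      }
      if (resample_values) {
        best <- sorted_vals[rank(best, ties.method = "first")]
      }
      out[s, ] <- best
    }
    out
  })
}

#' Permutation test of participation rates with a spatial null
#'
#' Tests, region by region, whether the observed participation rate exceeds
#' what spatial-autocorrelation-preserving randomizations of the map
#' produce. The one-sided p-value uses the add-one convention
#' `p_r = (1 + #{surrogate_r >= observed_r}) / (n_perm + 1)`; the
#' Benjamini-Hochberg step-up procedure is then applied across regions.
#' With `reference = "global_mean"` the surrogate values are compared to the
#' map's mean instead of the region's own rate.
#'
#' @param map a [participation_rates()] map (or numeric vector).
#' @param distances n x n distance matrix (`NULL` disables smoothing and
#'   yields a plain label-permutation test).
#' @param n_perm number of surrogates (default 1000).
#' @param seed integer seed.
#' @param fdr_q FDR level (default 0.05).
#' @param reference `"per_region"` (default) or `"global_mean"`.
#' @param ... further arguments for [variogram_surrogates()].
#' @return An object of class `permutation_report`: list with `p_values`,
#'   `significant` (post-FDR logical mask), `observed`, `n_perm`, `seed`,
#'   `fdr_q`, `region_labels`.
#' @export
permutation_test_rates <- function(map, distances = NULL, n_perm = 1000,
                                   seed = 1, fdr_q = 0.05,
                                   reference = c("per_region", "global_mean"),
                                   ...) {
  reference <- match.arg(reference)
  if (inherits(map, "participation_map")) {
    obs <- map$rates
    labels <- map$region_labels
  } else {
    obs <- as.numeric(map)
    labels <- names(map) %||% paste0("R", seq_along(obs))
  }
  n <- length(obs)
  smooth <- !is.null(distances)
  if (!smooth) distances <- matrix(1, n, n) - diag(n)
  surr <- variogram_surrogates(obs, distances, n_perm, seed,
                               smooth = smooth, ...)
  ref <- if (reference == "per_region") obs else rep(mean(obs), n)
  exceed <- colSums(surr >= matrix(ref, n_perm, n, byrow = TRUE))
  p <- (1 + exceed) / (n_perm + 1)
  structure(
    list(p_values = p, significant = bh_fdr(p, fdr_q), observed = obs,
         n_perm = n_perm, seed = seed, fdr_q = fdr_q,
         region_labels = labels),
    class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf("permutation_report: %d regions, %d perms, %d significant at q = %g\n",
              length(x$p_values), x$n_perm, sum(x$significant), x$fdr_q))
  invisible(x)
}

#' Benjamini-Hochberg step-up rejection mask
#'
#' Rejects all hypotheses with p-value at most `p_(k)`, where `k` is the
#' largest index with `p_(k) <= k q / m` over the sorted p-values.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Logical rejection mask.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  p.adjust(pvalues, method = "BH") <= q
}

#' Intraclass correlation coefficient
#'
#' Mean-squares ICC of a regions x conditions matrix with F-based 95%
#' confidence interval and p-value against ICC = 0. Forms follow the
#' standard single-score / average-score taxonomy: `"oneway"` = one-way
#' random effects ICC(1); `"c1"`/`"ck"` = two-way consistency, single /
#' average; `"a1"`/`"ak"` = two-way absolute agreement, single / average.
#'
#' @param m numeric matrix, rows = regions (targets), columns = conditions
#'   (raters); at least 3 rows and 2 columns.
#' @param form one of `"oneway"`, `"c1"`, `"a1"`, `"ck"`, `"ak"`.
#' @param conf_level confidence level (default 0.95).
#' @return A list with `icc`, `lower`, `upper`, `p_value`, `form`, `df1`,
#'   `df2`, `F`.
#' @export
icc <- function(m, form = c("oneway", "c1", "a1", "ck", "ak"),
                conf_level = 0.95) {
  form <- match.arg(form)
  m <- as.matrix(m)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3 || k < 2) stop("need at least 3 rows and 2 columns")
  if (all(apply(m, 1, var) == 0) && var(rowMeans(m)) == 0) {
    stop("degenerate matrix: zero variance everywhere")
  }
  alpha <- 1 - conf_level
  grand <- mean(m)
  SSR <- k * sum((rowMeans(m) - grand)^2)        # rows (targets)
  SSC <- n * sum((colMeans(m) - grand)^2)        # columns (raters)
  SST <- sum((m - grand)^2)
  SSE <- SST - SSR - SSC
  SSW <- SST - SSR
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  MSW <- SSW / (n * (k - 1))
  out <- switch(form,
    oneway = {
      Fv <- MSR / MSW
      df1 <- n - 1
      df2 <- n * (k - 1)
      FL <- Fv / qf(1 - alpha / 2, df1, df2)
      FU <- Fv * qf(1 - alpha / 2, df2, df1)
      list(icc = (MSR - MSW) / (MSR + (k - 1) * MSW),
           lower = (FL - 1) / (FL + k - 1), upper = (FU - 1) / (FU + k - 1),
           F = Fv, df1 = df1, df2 = df2)
    },
    c1 = {
      Fv <- MSR / MSE
      df1 <- n - 1
      df2 <- (n - 1) * (k - 1)
      FL <- Fv / qf(1 - alpha / 2, df1, df2)
      FU <- Fv * qf(1 - alpha / 2, df2, df1)
      list(icc = (MSR - MSE) / (MSR + (k - 1) * MSE),
           lower = (FL - 1) / (FL + k - 1), upper = (FU - 1) / (FU + k - 1),
           F = Fv, df1 = df1, df2 = df2)
    },
    ck = {
      Fv <- MSR / MSE
      df1 <- n - 1
      df2 <- (n - 1) * (k - 1)
      FL <- Fv / qf(1 - alpha / 2, df1, df2)
      FU <- Fv * qf(1 - alpha / 2, df2, df1)
      list(icc = (MSR - MSE) / MSR,
           lower = 1 - 1 / FL, upper = 1 - 1 / FU,
           F = Fv, df1 = df1, df2 = df2)
    },
    a1 = {
      r <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
      a <- k * r / (n * (1 - r))
      b <- 1 + k * r * (n - 1) / (n * (1 - r))
      v <- (a * MSC + b * MSE)^2 /
        ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
      FL <- qf(1 - alpha / 2, n - 1, v)
      FU <- qf(1 - alpha / 2, v, n - 1)
      lower <- n * (MSR - FL * MSE) /
        (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
      upper <- n * (FU * MSR - MSE) /
        (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
      list(icc = r, lower = lower, upper = upper,
           F = MSR / MSE, df1 = n - 1, df2 = (n - 1) * (k - 1))
    },
    ak = {
      r1 <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
      a <- k * r1 / (n * (1 - r1))
      b <- 1 + k * r1 * (n - 1) / (n * (1 - r1))
      v <- (a * MSC + b * MSE)^2 /
        ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
      FL <- qf(1 - alpha / 2, n - 1, v)
      FU <- qf(1 - alpha / 2, v, n - 1)
      l1 <- n * (MSR - FL * MSE) /
        (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
      u1 <- n * (FU * MSR - MSE) /
        (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
      r <- (MSR - MSE) / (MSR + (MSC - MSE) / n)
      list(icc = r,
           lower = l1 * k / (1 + (k - 1) * l1),
           upper = u1 * k / (1 + (k - 1) * u1),
           F = MSR / MSE, df1 = n - 1, df2 = (n - 1) * (k - 1))
    })
  out$p_value <- pf(out$F, out$df1, out$df2, lower.tail = FALSE)
  out$form <- form
  out[c("icc", "lower", "upper", "p_value", "form", "df1", "df2", "F")]
}

#' Correlation between two region maps with a spatial null
#'
#' Pearson correlation of two per-region maps, with a one-sided p-value from
#' the null distribution of correlations between variogram-matched
#' surrogates of `map_a` and the observed `map_b` (add-one convention).
#'
#' @param map_a,map_b numeric vectors of equal length (at least 10).
#' @param distances n x n distance matrix (`NULL` for plain permutations).
#' @param n_perm number of surrogates (default 1000).
#' @param seed integer seed.
#' @param ... further arguments for [variogram_surrogates()].
#' @return A list with `r`, `p_value`, `null` (the surrogate correlations),
#'   `n_perm`, `seed`.
#' @export
map_correlation_test <- function(map_a, map_b, distances = NULL,
                                 n_perm = 1000, seed = 1, ...) {
  stopifnot(length(map_a) == length(map_b), length(map_a) >= 10)
  if (sd(map_a) == 0 || sd(map_b) == 0) stop("zero-variance map")
  n <- length(map_a)
  smooth <- !is.null(distances)
  if (!smooth) distances <- matrix(1, n, n) - diag(n)
  surr <- variogram_surrogates(map_a, distances, n_perm, seed,
                               smooth = smooth, ...)
  r_obs <- cor(map_a, map_b)
  null <- apply(surr, 1, function(s) {
    if (sd(s) == 0) 0 else cor(s, map_b)
  })
  p <- (1 + sum(null >= r_obs)) / (n_perm + 1)
  list(r = r_obs, p_value = p, null = null, n_perm = n_perm, seed = seed)
}

#' Williams test for two dependent correlations sharing a variable
#'
#' Tests whether `cor(a, b)` differs from `cor(a, c)` given the three
#' pairwise correlations among maps measured on the same `n` units
#' (Williams/Steiger t with `n - 3` degrees of freedom; two-sided p).
#'
#' @param r_ab,r_ac the two correlations being compared (share variable
#'   `a`).
#' @param r_bc correlation between the two non-shared variables.
#' @param n number of units (> 3).
#' @return A list with `t`, `p_value`, `df`.
#' @export
compare_dependent_correlations <- function(r_ab, r_ac, r_bc, n) {
  rs <- c(r_ab, r_ac, r_bc)
  if (any(!is.finite(rs)) || any(abs(rs) >= 1)) {
    stop("correlations must lie in (-1, 1)")
  }
  if (n <= 3) stop("n must exceed 3")
  detR <- 1 - r_ab^2 - r_ac^2 - r_bc^2 + 2 * r_ab * r_ac * r_bc
  rbar <- (r_ab + r_ac) / 2
  tval <- (r_ab - r_ac) *
    sqrt((n - 1) * (1 + r_bc) /
           (2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r_bc)^3))
  df <- n - 3
  list(t = tval, p_value = 2 * pt(abs(tval), df, lower.tail = FALSE),
       df = df)
}
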