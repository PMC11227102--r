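#' Multi-condition cohort analysis: complexes to common complex
#'
#' The per-subject flow for a multi-condition cohort: for every subject in
#' every condition, estimate the conditional Granger-causality graph and
#' extract its main complex; compute per-condition participation rates;
#' test each region's rate against spatial-autocorrelation surrogates with
#' BH-FDR; intersect the post-FDR significant regions across conditions
#' into the common complex; and measure the cross-condition consistency of
#' the participation-rate profiles by ICC.
#'
#' @param conditions named list; each element is a list of
#'   [parcellated_ts()] (one per subject).
#' @param coords a [region_coordinates()] object (or `NULL` for a plain
#'   permutation null).
#' @param order VAR lag order (default 1).
#' @param n_perm surrogates per permutation test (default 1000).
#' @param fdr_q FDR level (default 0.05).
#' @param seed integer master seed.
#' @param icc_form ICC variant (default `"oneway"`).
#' @param resample_values rank-resample surrogate values? Default `FALSE`
#'   here (unlike [variogram_surrogates()]): the regionwise rate test needs
#'   an amplitude-based null — rank-resampled surrogates redistribute the
#'   observed multiset, so no region can ever beat the Benjamini-Hochberg
#'   threshold.
#' @param ... further arguments for [variogram_surrogates()].
#' @return A list with `participation` (per condition), `reports` (per
#'   condition [permutation_test_rates()] output), `rates_matrix` (regions x
#'   conditions), `common_complex` (indices), `common_labels`, `icc`,
#'   `complexes` (per condition, per subject), and `settings`.
#' @export
run_hcp_like <- function(conditions, coords = NULL, order = 1,
                         n_perm = 1000, fdr_q = 0.05, seed = 1,
                         icc_form = "oneway", resample_values = FALSE, ...) {
  stopifnot(length(conditions) >= 2)
  if (is.null(names(conditions)) || any(names(conditions) == "")) {
    names(conditions) <- paste0("cond", seq_along(conditions))
  }
  first <- conditions[[1]][[1]]
  labels <- first$region_labels
  n <- length(labels)
  distances <- if (!is.null(coords)) coords$distances else NULL
  complexes <- list()
  participation <- list()
  reports <- list()
  rates <- matrix(NA_real_, n, length(conditions),
                  dimnames = list(labels, names(conditions)))
  for (ci in seq_along(conditions)) {
    cname <- names(conditions)[ci]
    subj <- conditions[[ci]]
    if (length(subj) < 2) stop("need at least 2 subjects per condition")
    sets <- lapply(subj, function(ts) {
      main_complex(gc_matrix(ts, order = order))$subset
    })
    complexes[[cname]] <- sets
    pm <- participation_rates(sets, n, condition = cname,
                              region_labels = labels)
    participation[[cname]] <- pm
    reports[[cname]] <- permutation_test_rates(
      pm, distances, n_perm = n_perm, seed = derive_seed(seed, 1000L + ci),
      fdr_q = fdr_q, resample_values = resample_values, ...)
    rates[, ci] <- pm$rates
  }
  sig <- vapply(reports, `[[`, logical(n), "significant")
  common <- which(rowSums(sig) == length(conditions))
  list(participation = participation, reports = reports,
       rates_matrix = rates, common_complex = unname(common),
       common_labels = labels[common],
       icc = icc(rates, form = icc_form),
       complexes = complexes,
       settings = list(order = order, n_perm = n_perm, fdr_q = fdr_q,
                       seed = seed, icc_form = icc_form))
}

# equally-sized set of lowest-rate regions, ties broken by label order
lowest_rate_regions <- function(rates, labels, k) {
  ord <- order(rates, labels)
  sort(ord[seq_len(k)])
}

#' Sleep-session analysis: stage clusters, complexes and Phi
#'
#' The session-level flow for a hypnagogic dataset: cluster sessions by
#' sleep depth from their hypnograms; per cluster, extract each session's
#' main complex and the cluster participation map; correlate each cluster
#' map with a supplied reference map under the spatial-autocorrelation
#' null; and compute session-wise `Phi_G` and `Phi_M` on the regions of a
#' supplied common complex ("inside") and on the equally sized set of
#' lowest-reference-rate regions ("outside"). A stratified permutation
#' contrast of the deepest vs the lightest cluster summarizes the Phi
#' trend.
#'
#' @param sessions list of [parcellated_ts()], one per session.
#' @param hypnograms list of [hypnogram()]s, ids matching `sessions`.
#' @param common_complex indices of the common-complex regions.
#' @param reference_map per-region reference participation rates (length =
#'   regions).
#' @param coords a [region_coordinates()] or `NULL`.
#' @param order VAR lag order.
#' @param k number of stage clusters (default 3).
#' @param n_perm surrogates for the map-correlation tests.
#' @param seed integer master seed.
#' @param subject_ids optional per-session subject ids; when given, the
#'   Phi contrast permutes cluster labels within subject.
#' @param subsystem_search compute Phi as the maximum over the complex
#'   hierarchy's subsystems instead of on the full region set? Default
#'   `FALSE`.
#' @param resample_values rank-resample surrogate values? Default `FALSE`,
#'   as in [run_hcp_like()].
#' @param ... further arguments for [variogram_surrogates()].
#' @return A list with `clusters` ([cluster_sessions()] output),
#'   `participation` (per cluster), `map_tests` (per cluster, vs the
#'   reference map), `phi` (per-session data frame), `phi_summary`
#'   (cluster means), `phi_contrast` (deepest vs lightest cluster, inside
#'   regions), `inside`, `outside`, and `settings`.
#' @export
run_sleep_like <- function(sessions, hypnograms, common_complex,
                           reference_map, coords = NULL, order = 1, k = 3,
                           n_perm = 1000, seed = 1, subject_ids = NULL,
                           subsystem_search = FALSE,
                           resample_values = FALSE, ...) {
  sess_ids <- vapply(sessions, `[[`, "", "session_id")
  hyp_ids <- vapply(hypnograms, `[[`, "", "session_id")
  if (!setequal(sess_ids, hyp_ids) || anyDuplicated(sess_ids)) {
    stop("session ids of time series and hypnograms do not match")
  }
  hypnograms <- hypnograms[match(sess_ids, hyp_ids)]
  labels <- sessions[[1]]$region_labels
  n <- length(labels)
  common_complex <- sort(as.integer(common_complex))
  outside <- lowest_rate_regions(reference_map, labels,
                                 length(common_complex))
  feats <- lapply(hypnograms, multiscale_features)
  if (length(unique(vapply(feats, paste, "", collapse = ","))) < k) {
    warning("fewer distinct stage profiles than clusters; ",
            "returning a single effective cluster")
    k_eff <- 1L
    clusters <- list(labels = factor(rep("Wake", length(sessions))),
                     cluster = rep(1L, length(sessions)),
                     sizes = length(sessions), centroids = NULL,
                     composition = NULL, session_ids = sess_ids)
    class(clusters) <- "cluster_assignment"
  } else {
    k_eff <- k
    clusters <- cluster_sessions(feats, k = k, seed = derive_seed(seed, 7L),
                                 hypnograms = hypnograms,
                                 session_ids = sess_ids)
  }
  distances <- if (!is.null(coords)) coords$distances else NULL
  participation <- list()
  map_tests <- list()
  per_session_sets <- lapply(sessions, function(ts) {
    main_complex(gc_matrix(ts, order = order))$subset
  })
  for (cl in seq_len(k_eff)) {
    cl_name <- as.character(levels(clusters$labels)[cl])
    idx <- which(clusters$cluster == cl)
    pm <- participation_rates(per_session_sets[idx], n,
                              condition = cl_name, region_labels = labels)
    participation[[cl_name]] <- pm
    map_tests[[cl_name]] <- map_correlation_test(
      pm$rates, reference_map, distances, n_perm = n_perm,
      seed = derive_seed(seed, 2000L + cl),
      resample_values = resample_values, ...)
  }
  phi_one <- function(ts, idx) {
    sub <- parcellated_ts(ts$values[, idx, drop = FALSE],
                          ts$sampling_interval, ts$region_labels[idx],
                          ts$session_id)
    if (subsystem_search) {
      g <- max_phi_subsystem(sub, "phi_g", order = order,
                             strategy = "hierarchical")$value
      m <- max_phi_subsystem(sub, "phi_m", order = order,
                             strategy = "hierarchical")$value
    } else {
      g <- as.numeric(phi_g(sub, order))
      m <- phi_m(sub, order)
    }
    c(phi_g = g, phi_m = m)
  }
  phi_df <- do.call(rbind, lapply(seq_along(sessions), function(si) {
    pin <- phi_one(sessions[[si]], common_complex)
    pout <- phi_one(sessions[[si]], outside)
    data.frame(session_id = sess_ids[si],
               cluster = as.character(clusters$labels[si]),
               phi_g_in = pin[["phi_g"]], phi_m_in = pin[["phi_m"]],
               phi_g_out = pout[["phi_g"]], phi_m_out = pout[["phi_m"]],
               stringsAsFactors = FALSE)
  }))
  phi_summary <- do.call(rbind, lapply(split(phi_df, phi_df$cluster),
    function(d) {
      data.frame(cluster = d$cluster[1], n = nrow(d),
                 phi_g_in = mean(d$phi_g_in), phi_m_in = mean(d$phi_m_in),
                 phi_g_out = mean(d$phi_g_out),
                 phi_m_out = mean(d$phi_m_out))
    }))
  phi_contrast <- NULL
  if (k_eff >= 2) {
    lev <- levels(clusters$labels)
    phi_contrast <- phi_cluster_contrast(
      phi_df$phi_g_in, phi_df$cluster, a = lev[1], b = lev[k_eff],
      n_perm = n_perm, seed = derive_seed(seed, 31L), strata = subject_ids)
  }
  list(clusters = clusters, participation = participation,
       map_tests = map_tests, phi = phi_df, phi_summary = phi_summary,
       phi_contrast = phi_contrast,
       inside = common_complex, outside = outside,
       settings = list(order = order, k = k, n_perm = n_perm, seed = seed,
                       subsystem_search = subsystem_search))
}

#' Permutation contrast of a Phi measure between two clusters
#'
#' Difference of cluster means `mean(a) - mean(b)` with a permutation
#' p-value obtained by shuffling cluster labels (within strata such as
#' subjects, when given); two-sided, add-one convention. A descriptive
#' substitute for a mixed-model analysis of cluster effects.
#'
#' @param values numeric vector (e.g. per-session `Phi_G`).
#' @param clusters cluster label per value.
#' @param a,b the two cluster labels to contrast.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @param strata optional stratification factor (labels shuffled within
#'   stratum).
#' @return A list with `contrast`, `p_value`, `n_perm`.
#' @export
phi_cluster_contrast <- function(values, clusters, a, b, n_perm = 1000,
                                 seed = 1, strata = NULL) {
  keep <- clusters %in% c(a, b)
  v <- values[keep]
  cl <- as.character(clusters[keep])
  st <- if (is.null(strata)) rep(1L, sum(keep)) else strata[keep]
  obs <- mean(v[cl == a]) - mean(v[cl == b])
  groups <- split(seq_along(cl), st)
  null <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      clp <- cl
      for (ix in groups) clp[ix] <- cl[ix][sample.int(length(ix))]
      if (!any(clp == a) || !any(clp == b)) return(NA_real_)
      mean(v[clp == a]) - mean(v[clp == b])
    }, 0)
  })
  null <- null[!is.na(null)]
  p <- (1 + sum(abs(null) >= abs(obs))) / (length(null) + 1)
  list(contrast = obs, p_value = p, n_perm = length(null))
}
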