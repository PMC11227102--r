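#' Multiscale stage-average features of a session
#'
#' Maps a 30-epoch hypnogram (stages coded Wake = 0 .. N3 = 3) to the
#' 6-element feature vector of multiscale means: all 30 epochs, first and
#' second halves (epochs 1-15, 16-30), and first, middle and last thirds
#' (1-10, 11-20, 21-30).
#'
#' @param h a [hypnogram()] with exactly 30 epochs, or a length-30 integer
#'   vector.
#' @return Numeric vector of length 6, each element in `[0, 3]`.
#' @examples
#' multiscale_features(hypnogram(c(rep(0, 15), rep(1, 15))))
#' @export
multiscale_features <- function(h) {
  x <- if (inherits(h, "hypnogram")) h$stages else as.integer(h)
  if (length(x) != 30) stop("multiscale features require exactly 30 epochs")
  c(mean(x), mean(x[1:15]), mean(x[16:30]),
    mean(x[1:10]), mean(x[11:20]), mean(x[21:30]))
}

#' Cluster sessions by sleep depth
#'
#' Euclidean k-means (best of `n_restarts` random starts) on the 6-element
#' multiscale feature vectors, with clusters relabelled so that the mean
#' overall stage (feature 1) increases Wake < N1 < N2. When hypnograms are
#' supplied, the per-cluster stage composition is computed over pooled
#' epochs (every session contributes its 30 epochs).
#'
#' @param features list of feature vectors (from [multiscale_features()])
#'   or a sessions x 6 matrix.
#' @param k number of clusters (default 3).
#' @param n_restarts random restarts (default 100).
#' @param seed integer seed.
#' @param hypnograms optional list of [hypnogram()]s matching the sessions.
#' @param session_ids optional ids; defaults to hypnogram ids or `s1..sN`.
#' @return An object of class `cluster_assignment`: list with `labels`
#'   (factor `Wake`/`N1`/`N2`/... per session), `cluster` (integer codes),
#'   `centroids` (k x 6, ordered), `sizes`, `composition` (k x 4 stage
#'   proportions, when hypnograms given), `wcss`, `session_ids`.
#' @export
cluster_sessions <- function(features, k = 3, n_restarts = 100, seed = 1,
                             hypnograms = NULL, session_ids = NULL) {
  X <- if (is.list(features)) do.call(rbind, features) else as.matrix(features)
  ns <- nrow(X)
  if (ns < k) stop("fewer sessions than clusters")
  km <- withr::with_seed(as.integer(seed),
                         kmeans(X, centers = k, nstart = n_restarts,
                                iter.max = 100))
  ord <- order(km$centers[, 1])
  relabel <- match(seq_len(k), ord)   # old cluster id -> depth rank
  cluster <- relabel[km$cluster]
  centroids <- km$centers[ord, , drop = FALSE]
  level_names <- c("Wake", "N1", "N2", paste0("C", seq_len(max(k - 3, 0)) + 3))
  level_names <- level_names[seq_len(k)]
  labels <- factor(level_names[cluster], levels = level_names)
  composition <- NULL
  if (!is.null(hypnograms)) {
    stopifnot(length(hypnograms) == ns)
    composition <- t(vapply(seq_len(k), function(cl) {
      pooled <- unlist(lapply(hypnograms[cluster == cl], `[[`, "stages"))
      if (length(pooled) == 0) return(rep(NA_real_, 4))
      tabulate(pooled + 1, nbins = 4) / length(pooled)
    }, numeric(4)))
    dimnames(composition) <- list(level_names, c("Wake", "N1", "N2", "N3"))
  }
  session_ids <- session_ids %||%
    (if (!is.null(hypnograms)) vapply(hypnograms, `[[`, "", "session_id")
     else paste0("s", seq_len(ns)))
  structure(
    list(labels = labels, cluster = cluster, centroids = centroids,
         sizes = as.integer(table(factor(cluster, levels = seq_len(k)))),
         composition = composition, wcss = km$tot.withinss,
         session_ids = session_ids),
    class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d sessions -> %s\n",
              length(x$cluster),
              paste(sprintf("%s:%d", levels(x$labels), x$sizes),
                    collapse = ", ")))
  invisible(x)
}
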