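#' Bidirectional bipartition strength
#'
#' For a bipartition of `within` into `subset` and its complement, the
#' strength of bidirectional connections is the smaller of the two directed
#' weight sums across the divide: `min(sum of weights subset -> rest,
#' sum of weights rest -> subset)`. Edges incident to nodes outside `within`
#' are ignored.
#'
#' @param graph a [causal_graph()].
#' @param subset node indices (1-based) forming one side; must be a
#'   nonempty proper subset of `within`.
#' @param within node indices of the evaluated (sub)system; defaults to all
#'   nodes.
#' @return Nonnegative scalar strength.
#' @examples
#' g <- causal_graph(matrix(c(0, 3, 1, 0), 2, 2, byrow = TRUE))
#' bipartition_strength(g, 1)  # min(w(1->2), w(2->1))
#' @export
bipartition_strength <- function(graph, subset, within = NULL) {
  stopifnot(inherits(graph, "causal_graph"))
  within <- sort(within %||% seq_len(nrow(graph$weights)))
  subset <- sort(unique(as.integer(subset)))
  if (length(subset) == 0 || !all(subset %in% within) ||
      length(subset) >= length(within)) {
    stop("subset must be a nonempty proper subset of `within`")
  }
  rest <- setdiff(within, subset)
  W <- graph$weights
  # W[i, j] = flow j -> i, so subset -> rest sums W[rest, subset]
  min(sum(W[rest, subset]), sum(W[subset, rest]))
}

min_cut_exhaustive <- function(W, within) {
  m <- length(within)
  best_val <- Inf
  best_side <- NULL
  # enumerate bipartitions: fix node within[1] on one side to halve the count
  bits <- bitwShiftL(1L, 0:(m - 2))
  for (mask in 0:(bitwShiftL(1L, m - 1L) - 2L)) {
    side <- within[c(1L, 1L + which(bitwAnd(mask, bits) != 0))]
    rest <- setdiff(within, side)
    v <- min(sum(W[rest, side]), sum(W[side, rest]))
    if (v < best_val) {
      best_val <- v
      best_side <- side
    }
  }
  list(subset = best_side, strength = best_val)
}

# exact minimum over bipartitions of min(out, in). The minimum of the
# bidirectional strength over all bipartitions equals the global minimum
# directed cut: in(S) is out of the complement, so min over bipartitions of
# min(out, in) = min over S of out(S). Solved with 2(n-1) max-flows.
min_cut_maxflow <- function(W, within) {
  m <- length(within)
  Wl <- W[within, within, drop = FALSE]
  eps <- 1e-12
  edges <- which(Wl > 0, arr.ind = TRUE)  # rows: (target, source)
  g <- igraph::make_empty_graph(n = m, directed = TRUE)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(edges[, 2], edges[, 1]))
    igraph::E(g)$capacity <- Wl[edges]
  }
  best_val <- Inf
  best_side <- NULL
  for (t in seq(2, m)) {
    for (dir in 1:2) {
      s <- if (dir == 1) 1 else t
      tt <- if (dir == 1) t else 1
      mc <- igraph::min_cut(g, source = s, target = tt,
                            capacity = igraph::E(g)$capacity %||% numeric(0),
                            value.only = FALSE)
      if (mc$value < best_val - eps) {
        best_val <- mc$value
        best_side <- within[as.integer(mc$partition1)]
      }
    }
  }
  side <- sort(best_side)
  rest <- setdiff(within, side)
  # recompute the bidirectional strength at the chosen bipartition
  list(subset = side,
       strength = min(sum(W[rest, side]), sum(W[side, rest])))
}

#' Minimum bidirectional cut of a node set
#'
#' Finds the bipartition of `within` minimizing the bidirectional strength
#' of [bipartition_strength()]; the minimum value is the minimum cut weight
#' `w_mc` of the (sub)system. `method = "exhaustive"` enumerates all
#' bipartitions (limited to 20 nodes); `method = "maxflow"` solves the
#' equivalent global minimum directed cut problem exactly with max-flows
#' (the bidirectional strength minimum coincides with the directed-cut
#' minimum because the inward sum of a subset is the outward sum of its
#' complement); `"auto"` picks exhaustive up to 12 nodes and max-flow above.
#'
#' @param graph a [causal_graph()] with nonnegative weights.
#' @param within node indices of the evaluated set (default: all nodes).
#' @param method `"auto"`, `"exhaustive"` or `"maxflow"`.
#' @return A list with `subset` (one side of the minimizing bipartition,
#'   containing the first node of `within`) and `strength` (`w_mc`).
#' @export
min_cut <- function(graph, within = NULL,
                    method = c("auto", "exhaustive", "maxflow")) {
  stopifnot(inherits(graph, "causal_graph"))
  method <- match.arg(method)
  within <- sort(within %||% seq_len(nrow(graph$weights)))
  m <- length(within)
  if (m < 2) stop("`within` must contain at least 2 nodes")
  if (method == "exhaustive" && m > 20) {
    stop("exhaustive enumeration limited to 20 nodes")
  }
  if (method == "auto") method <- if (m <= 12) "exhaustive" else "maxflow"
  W <- graph$weights
  res <- switch(method,
                exhaustive = min_cut_exhaustive(W, within),
                maxflow = min_cut_maxflow(W, within))
  if (!(within[1] %in% res$subset)) {
    res$subset <- setdiff(within, res$subset)
  }
  res$subset <- sort(res$subset)
  res
}

#' Hierarchy of bidirectionally connected complexes
#'
#' Recursively splits the node set at its minimum bidirectional cut,
#' recording the minimum cut weight `w_mc` of every nested subsystem with
#' at least two nodes. Because any subset straddling a minimum cut has
#' `w_mc` no larger than the cut it straddles, every complex (a subsystem
#' whose `w_mc` strictly exceeds that of all strict supersets) appears in
#' this hierarchy, and a hierarchy member is a complex exactly when its
#' `w_mc` strictly exceeds the `w_mc` of all its hierarchy ancestors. The
#' main complex is the complex with maximal `w_mc`; ties prefer the larger
#' subset, then the lexicographically smallest sorted label set.
#'
#' @param graph a [causal_graph()] with nonnegative weights.
#' @param method min-cut method, see [min_cut()].
#' @return An object of class `complex_hierarchy` with `entries` (the
#'   complexes: list of `subset`, `labels`, `weight`), `hierarchy` (all
#'   recorded subsystems), `main_complex` (indices), `main_labels` and
#'   `main_weight`.
#' @export
extract_complexes <- function(graph, method = "auto") {
  stopifnot(inherits(graph, "causal_graph"))
  if (any(graph$weights < 0)) stop("graph weights must be nonnegative")
  n <- nrow(graph$weights)
  if (n < 2) stop("graph must have at least 2 nodes")
  nodes <- list()
  recurse <- function(within, ancestors_max) {
    cut <- min_cut(graph, within, method = method)
    nodes[[length(nodes) + 1]] <<- list(subset = within,
                                        weight = cut$strength,
                                        ancestors_max = ancestors_max)
    amax <- max(ancestors_max, cut$strength)
    left <- cut$subset
    right <- setdiff(within, left)
    if (length(left) >= 2) recurse(left, amax)
    if (length(right) >= 2) recurse(right, amax)
  }
  recurse(seq_len(n), -Inf)
  is_complex <- vapply(nodes, function(nd) nd$weight > nd$ancestors_max,
                       TRUE)
  entries <- lapply(nodes[is_complex], function(nd) {
    list(subset = nd$subset, labels = graph$region_labels[nd$subset],
         weight = nd$weight)
  })
  # order complexes by decreasing weight, then decreasing size, then labels
  keys <- vapply(entries, function(e) {
    paste(collapse = " ", e$labels)
  }, "")
  ord <- order(-vapply(entries, `[[`, 0, "weight"),
               -vapply(entries, function(e) length(e$subset), 0L),
               keys)
  entries <- entries[ord]
  main <- entries[[1]]
  structure(
    list(entries = entries,
         hierarchy = lapply(nodes, function(nd) {
           list(subset = nd$subset, weight = nd$weight)
         }),
         main_complex = main$subset, main_labels = main$labels,
         main_weight = main$weight, region_labels = graph$region_labels),
    class = "complex_hierarchy")
}

#' @export
print.complex_hierarchy <- function(x, ...) {
  cat(sprintf("complex_hierarchy: %d complexes; main = {%s}, w_mc = %.4f\n",
              length(x$entries), paste(x$main_labels, collapse = ", "),
              x$main_weight))
  invisible(x)
}

#' Main complex of a causal graph
#'
#' Convenience projection of [extract_complexes()]: the subsystem with the
#' maximal minimum bidirectional cut weight.
#'
#' @inheritParams extract_complexes
#' @return A list with `subset` (indices), `labels` and `weight`.
#' @export
main_complex <- function(graph, method = "auto") {
  h <- extract_complexes(graph, method = method)
  list(subset = h$main_complex, labels = h$main_labels,
       weight = h$main_weight)
}
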