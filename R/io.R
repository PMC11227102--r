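#' Read and write parcellated time series
#'
#' Series are stored as tab-separated text with a header row of region labels
#' (regions in columns, time in rows) plus a JSON sidecar `<path>.json`
#' holding the sampling interval and session id.
#'
#' @param ts a [parcellated_ts()].
#' @param path file path of the TSV; the sidecar is written to `<path>.json`.
#' @return `write_parcellated_ts()` returns `path` invisibly;
#'   `read_parcellated_ts()` returns a `parcellated_ts`.
#' @export
write_parcellated_ts <- function(ts, path) {
  stopifnot(inherits(ts, "parcellated_ts"))
  write.table(ts$values, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  jsonlite::write_json(
    list(sampling_interval = ts$sampling_interval,
         session_id = ts$session_id),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parcellated_ts
#' @export
read_parcellated_ts <- function(path) {
  values <- as.matrix(read.table(path, sep = "\t", header = TRUE,
                                 check.names = FALSE))
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("missing sidecar metadata: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  parcellated_ts(values, meta$sampling_interval,
                 region_labels = colnames(values),
                 session_id = meta$session_id)
}

#' Read and write hypnograms
#'
#' One integer stage per line, one file per session; the session id defaults
#' to the file name without extension.
#'
#' @param h a [hypnogram()].
#' @param path file path.
#' @param n_epochs expected epoch count on read (default 30, `NA` for any).
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  writeLines(as.character(h$stages), path)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path, n_epochs = 30) {
  stages <- as.integer(readLines(path))
  hypnogram(stages, session_id = sub("\\.[^.]+$", "", basename(path)),
            n_epochs = n_epochs)
}

#' Read and write region coordinates
#'
#' Three columns (x, y, z) of tab-separated text, one row per region.
#'
#' @param coords a `region_coordinates` object (see [generate_coordinates()]).
#' @param path file path.
#' @export
write_coordinates <- function(coords, path) {
  write.table(coords$positions, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = c("x", "y", "z"))
  invisible(path)
}

#' @rdname write_coordinates
#' @export
read_coordinates <- function(path) {
  pos <- as.matrix(read.table(path, sep = "\t", header = TRUE))
  region_coordinates(pos)
}

#' Read and write causal-graph weight matrices
#'
#' The directed Granger-causality weight matrix is stored as a labelled TSV
#' (rows = targets, columns = sources, first column = target label).
#'
#' @param graph a `causal_graph` (see [gc_matrix()]).
#' @param path file path.
#' @export
write_causal_graph <- function(graph, path) {
  m <- graph$weights
  df <- data.frame(region = graph$region_labels, m, check.names = FALSE)
  colnames(df) <- c("region", graph$region_labels)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_causal_graph
#' @param order VAR order to record on the read graph.
#' @export
read_causal_graph <- function(path, order = 1L) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- labels
  causal_graph(m, labels, order = order)
}
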