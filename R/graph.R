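# Per-pathway sample graph: directed kNN construction and shared-nearest-
# neighbour (SNN) weighting.

#' Build a directed k-nearest-neighbour adjacency
#'
#' Connects every sample to its `k` nearest other samples by Euclidean
#' distance. Exact mode ranks all pairwise distances, breaking ties at the
#' k-th neighbour by smallest sample index; approximate mode runs a seeded
#' NN-descent search and is intended for large sample counts where the
#' quadratic scan is wasteful. Mode `"auto"` uses exact search up to
#' `exact_threshold` samples and approximate search above.
#'
#' @param points numeric matrix, samples x features.
#' @param k number of neighbours per sample; must be at least 1 and smaller
#'   than the number of samples.
#' @param mode `"auto"`, `"exact"`, or `"approximate"`.
#' @param seed integer seed for the approximate search (ignored in exact
#'   mode, which is fully deterministic).
#' @param exact_threshold sample count up to which `"auto"` stays exact.
#' @return an integer matrix, samples x `k`: row `i` holds the (1-based)
#'   indices of the `k` nearest neighbours of sample `i`, nearest first.
#'   A sample is never its own neighbour.
#' @examples
#' pts <- matrix(c(0, 1, 10), ncol = 1)
#' build_knn(pts, k = 1)
#' @export
build_knn <- function(points, k, mode = c("auto", "exact", "approximate"),
                      seed = 1L, exact_threshold = 2000L) {
  mode <- match.arg(mode)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (ncol(points) < 1L) stop("points must have at least one feature")
  if (!is_count(k, min = 1L)) stop("k must be a positive integer")
  if (k >= n) stop(sprintf("k (%d) must be smaller than the number of samples (%d)", k, n))
  if (anyNA(points)) stop("points must not contain missing values")
  if (mode == "auto") mode <- if (n <= exact_threshold) "exact" else "approximate"
  idx <- if (mode == "exact") {
    .knn_exact_cpp(points, as.integer(k))
  } else {
    .knn_descent_cpp(points, as.integer(k), as.integer(seed))
  }
  rownames(idx) <- rownames(points)
  idx
}

#' Weight a kNN adjacency by shared-nearest-neighbour similarity
#'
#' For every stored edge (i, j) the SNN similarity is the number of
#' out-neighbours shared by i and j divided by `k`, i.e. the entries of
#' B = A.t(A) restricted to the edges of A and scaled by 1/k. The weighted
#' graph keeps A's topology: weights are attached only to existing edges and
#' zero-overlap edges are retained with weight 0, so every node keeps
#' out-degree exactly `k`.
#'
#' @param adjacency integer matrix of out-neighbour indices as returned by
#'   [build_knn()] (samples x k, 1-based, no self-edges).
#' @param k number of neighbours; defaults to `ncol(adjacency)`.
#' @return an object of class `snn_graph`: a list with `n`, `k`, `idx`
#'   (the adjacency), `weights` (samples x k matrix of similarities in
#'   [0, 1]), and `sample_ids`.
#' @export
snn_weights <- function(adjacency, k = ncol(adjacency)) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "integer"
  n <- nrow(adjacency)
  if (k != ncol(adjacency)) stop("k must equal the number of adjacency columns")
  if (any(adjacency < 1L) || any(adjacency > n)) stop("neighbour index out of range")
  if (any(adjacency == row(adjacency))) stop("self-edges are not allowed")
  if (any(apply(adjacency, 1L, anyDuplicated) > 0L)) {
    stop("duplicate out-neighbours within a row")
  }
  counts <- .snn_counts_cpp(adjacency)
  weights <- counts / k
  structure(
    list(n = n, k = as.integer(k), idx = adjacency, weights = weights,
         sample_ids = rownames(adjacency)),
    class = "snn_graph"
  )
}

#' Build the SNN-weighted kNN graph of a point set
#'
#' Convenience composition of [build_knn()] and [snn_weights()].
#'
#' @inheritParams build_knn
#' @return an `snn_graph` (see [snn_weights()]).
#' @export
build_snn_graph <- function(points, k, mode = c("auto", "exact", "approximate"),
                            seed = 1L, exact_threshold = 2000L) {
  snn_weights(build_knn(points, k, mode, seed, exact_threshold), k)
}

#' @export
print.snn_graph <- function(x, ...) {
  cat(sprintf("snn_graph: %d samples, k = %d, mean SNN weight %.3f\n",
              x$n, x$k, mean(x$weights)))
  invisible(x)
}

#' Edge list of an SNN graph
#'
#' @param graph an `snn_graph`.
#' @return a data.frame with columns `src`, `dst` (1-based sample indices)
#'   and `weight`.
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "snn_graph"))
  data.frame(
    src = rep(seq_len(graph$n), times = graph$k),
    dst = as.vector(graph$idx),
    weight = as.vector(graph$weights)
  )
}

#' Write an SNN graph as an edge-list TSV
#'
#' Debug dump with columns `src`, `dst`, `weight`; sample identifiers are
#' used when present, row indices otherwise.
#'
#' @param graph an `snn_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graph_edges <- function(graph, path) {
  edges <- graph_edges(graph)
  if (!is.null(graph$sample_ids)) {
    edges$src <- graph$sample_ids[edges$src]
    edges$dst <- graph$sample_ids[edges$dst]
  }
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
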