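# Feature graphs over the neurons of a structured layer: construction,
# Laplacian computation, the spectral smoothness penalty, kernel-based graph
# estimation from activations, and connected-component analysis.

#' Build a feature graph from a weighted adjacency matrix
#'
#' Constructs a `feature_graph` from a symmetric, nonnegative weight matrix
#' `W`, computing its combinatorial graph Laplacian `L = D - W`, where `D` is
#' the diagonal degree matrix with `D_ii = sum_j W_ij`. The diagonal of `W` is
#' zeroed first: self-loops contribute equally to `D` and `W` and therefore
#' cancel in `L`.
#'
#' @param weights Square numeric matrix of edge weights; must be symmetric
#'   (within `1e-8`) with nonnegative entries.
#' @param node_labels Optional character vector of node names, one per node.
#' @return An object of class `feature_graph`: a list with elements
#'   `n_nodes`, `weights` (diagonal zeroed), `laplacian`, and `node_labels`.
#'   Every row of `laplacian` sums to zero and the matrix is positive
#'   semi-definite.
#' @examples
#' g <- laplacian_from_weights(matrix(c(0, 1, 1, 0), 2))
#' g$laplacian
#' @export
laplacian_from_weights <- function(weights, node_labels = NULL) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    stop("`weights` must be a numeric matrix")
  }
  if (nrow(weights) != ncol(weights)) {
    stop(sprintf("`weights` must be square; got %d x %d",
                 nrow(weights), ncol(weights)))
  }
  if (any(!is.finite(weights))) {
    stop("`weights` contains non-finite entries")
  }
  asym <- abs(weights - t(weights))
  if (any(asym > 1e-8)) {
    idx <- which(asym > 1e-8, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "`weights` is not symmetric: W[%d,%d] = %g but W[%d,%d] = %g",
      idx[1], idx[2], weights[idx[1], idx[2]],
      idx[2], idx[1], weights[idx[2], idx[1]]))
  }
  if (any(weights < 0)) {
    idx <- which(weights < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative edge weight W[%d,%d] = %g",
                 idx[1], idx[2], weights[idx[1], idx[2]]))
  }
  n <- nrow(weights)
  if (!is.null(node_labels) && length(node_labels) != n) {
    stop("`node_labels` must have one entry per node")
  }
  w <- (weights + t(weights)) / 2  # exact symmetry
  diag(w) <- 0
  lap <- diag(rowSums(w), nrow = n) - w
  dimnames(w) <- dimnames(lap) <- NULL
  structure(
    list(n_nodes = n, weights = w, laplacian = lap,
         node_labels = node_labels),
    class = "feature_graph")
}

#' @export
print.feature_graph <- function(x, ...) {
  n_edges <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("feature_graph: %d nodes, %d edges (nonzero weights)\n",
              x$n_nodes, n_edges))
  invisible(x)
}

is_feature_graph <- function(x) inherits(x, "feature_graph")

#' Graph spectral regularization penalty
#'
#' Evaluates the Laplacian smoothness penalty `G(z, L) = z' L z` of layer
#' activations on a feature graph, averaged over samples. For a single
#' activation vector `z` this equals the ordered-pair sum
#' `1/2 * sum_ij W_ij (z_i - z_j)^2`, so the penalty is zero exactly when the
#' activations are constant across every connected component, and is always
#' nonnegative (the Laplacian is positive semi-definite).
#'
#' @param activations Numeric matrix (samples x neurons) or a single numeric
#'   vector of activations; the number of neurons must equal the number of
#'   graph nodes.
#' @param graph A [feature_graph][laplacian_from_weights].
#' @return A single nonnegative number: the mean of `z' L z` over samples.
#' @examples
#' g <- laplacian_from_weights(matrix(c(0, 1, 1, 0), 2))
#' gsr_penalty(c(1, 0), g)  # 1
#' @export
gsr_penalty <- function(activations, graph) {
  stopifnot(is_feature_graph(graph))
  if (is.vector(activations) && is.numeric(activations)) {
    activations <- matrix(activations, nrow = 1L)
  }
  if (!is.matrix(activations) || !is.numeric(activations)) {
    stop("`activations` must be a numeric matrix or vector")
  }
  if (ncol(activations) != graph$n_nodes) {
    stop(sprintf(
      "activation columns (%d) must match graph nodes (%d)",
      ncol(activations), graph$n_nodes))
  }
  # rowwise quadratic form z' L z, averaged over the batch
  q <- rowSums((activations %*% graph$laplacian) * activations)
  max(mean(q), 0)  # clip the tiny negative float noise of an exact zero
}

#' Rectangular grid graph
#'
#' A 4-neighbour lattice with unit edge weights, used to give a hidden layer a
#' 2-D spatial organization (e.g. an 8 x 8 grid over a 64-unit layer). Nodes
#' are indexed in row-major order: node `r * cols + c + 1` sits at row `r`,
#' column `c` (0-based `r`, `c`).
#'
#' @param rows,cols Positive integers, the lattice dimensions.
#' @return A `feature_graph` with `rows * cols` nodes and
#'   `rows*(cols-1) + cols*(rows-1)` edges.
#' @export
grid_graph <- function(rows, cols) {
  if (length(rows) != 1L || length(cols) != 1L ||
      rows < 1 || cols < 1 || rows != floor(rows) || cols != floor(cols)) {
    stop("`rows` and `cols` must be positive integers")
  }
  n <- rows * cols
  w <- matrix(0, n, n)
  for (r in seq_len(rows) - 1L) {
    for (cc in seq_len(cols) - 1L) {
      i <- r * cols + cc + 1L
      if (cc < cols - 1L) { j <- i + 1L;    w[i, j] <- w[j, i] <- 1 }
      if (r  < rows - 1L) { j <- i + cols;  w[i, j] <- w[j, i] <- 1 }
    }
  }
  laplacian_from_weights(w)
}

#' Disjoint node-pairs graph
#'
#' `n_pairs` disconnected edges: nodes `2i - 1` and `2i` are joined with unit
#' weight. With one pair per expected data cluster, each pair can act as a
#' "super node" whose two neurons split the cluster's substructure.
#'
#' @param n_pairs Positive integer.
#' @return A `feature_graph` with `2 * n_pairs` nodes and `n_pairs` connected
#'   components.
#' @export
disjoint_pairs_graph <- function(n_pairs) {
  if (length(n_pairs) != 1L || n_pairs < 1 || n_pairs != floor(n_pairs)) {
    stop("`n_pairs` must be a positive integer")
  }
  n <- 2L * n_pairs
  w <- matrix(0, n, n)
  for (p in seq_len(n_pairs)) {
    i <- 2L * p - 1L
    w[i, i + 1L] <- w[i + 1L, i] <- 1
  }
  laplacian_from_weights(w)
}

#' Complete graph
#'
#' All `n` nodes pairwise connected with unit weights; the Laplacian is
#' `n * I - J` (with `J` the all-ones matrix). Smoothing on a complete graph
#' pulls every node of the layer toward the layer mean.
#'
#' @param n Positive integer number of nodes.
#' @return A `feature_graph`.
#' @export
complete_graph <- function(n) {
  if (length(n) != 1L || n < 1 || n != floor(n)) {
    stop("`n` must be a positive integer")
  }
  w <- matrix(1, n, n)
  diag(w) <- 0
  laplacian_from_weights(w)
}

#' Kernel parameters for activation-based graph estimation
#'
#' @param k Positive integer: the adaptive bandwidth of each feature is its
#'   Euclidean distance to its `k`-th nearest *other* feature. `k = 1`
#'   (nearest neighbour) is the default.
#' @param bandwidth_floor Small positive lower bound on the bandwidth,
#'   guarding against zero distances between duplicated features.
#' @param standardize If `TRUE`, z-score each feature's activation profile
#'   across samples before computing distances. Off by default: the adaptive
#'   bandwidth already absorbs scale differences between neurons.
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(k = 1L, bandwidth_floor = 1e-8,
                          standardize = FALSE) {
  if (length(k) != 1L || k < 1 || k != floor(k)) {
    stop("`k` must be a positive integer")
  }
  if (length(bandwidth_floor) != 1L || bandwidth_floor <= 0) {
    stop("`bandwidth_floor` must be > 0")
  }
  structure(list(k = as.integer(k), bandwidth_floor = bandwidth_floor,
                 standardize = isTRUE(standardize)),
            class = "kernel_params")
}

#' Adaptive-bandwidth Gaussian kernel graph from feature activations
#'
#' Builds a feature graph from the co-activation pattern of a layer: each
#' feature (neuron) is a point whose coordinates are its activations across
#' all samples, and the affinity between features `i` and `j` is
#' \deqn{W_{ij} = \tfrac12 \exp(-d_{ij}^2 / 2\sigma_i^2) +
#'               \tfrac12 \exp(-d_{ij}^2 / 2\sigma_j^2)}
#' with `d_ij` the Euclidean distance between activation profiles and
#' `sigma_i` the distance from feature `i` to its `k`-th nearest other
#' feature. The per-feature bandwidth makes the affinity insensitive to the
#' absolute activation scale, which varies between layers and architectures.
#' The diagonal is zeroed (self-loops cancel in the Laplacian) and the result
#' is exactly symmetric with entries in `[0, 1]`.
#'
#' @param feature_vectors Numeric matrix, features x samples: one row per
#'   feature/neuron, one column per sample. Note this is the transpose of the
#'   usual samples x neurons activation matrix.
#' @param params A [kernel_params] object.
#' @return A `feature_graph` over the rows of `feature_vectors`.
#' @examples
#' z <- matrix(c(0, 0, 1, 1), nrow = 2, byrow = TRUE)  # two features
#' adaptive_gaussian_kernel(z, kernel_params(k = 1))$weights[1, 2]  # exp(-1/2)
#' @export
adaptive_gaussian_kernel <- function(feature_vectors,
                                     params = kernel_params()) {
  stopifnot(inherits(params, "kernel_params"))
  if (!is.matrix(feature_vectors) || !is.numeric(feature_vectors)) {
    stop("`feature_vectors` must be a numeric matrix (features x samples)")
  }
  n <- nrow(feature_vectors)
  if (n < 2L) stop("need at least 2 features")
  if (n < params$k + 1L) {
    stop(sprintf("need at least k + 1 = %d features for k = %d; got %d",
                 params$k + 1L, params$k, n))
  }
  if (any(!is.finite(feature_vectors))) {
    stop("`feature_vectors` contains non-finite entries")
  }
  x <- feature_vectors
  if (params$standardize) {
    mu <- rowMeans(x)
    sd_ <- apply(x, 1L, stats::sd)
    sd_[sd_ == 0] <- 1
    x <- (x - mu) / sd_
  }
  d <- as.matrix(stats::dist(x))
  # sigma_i: distance to the k-th nearest *other* feature, floored
  sigma <- vapply(seq_len(n), function(i) {
    sort(d[i, -i])[params$k]
  }, numeric(1L))
  floored <- sigma < params$bandwidth_floor
  if (any(floored)) {
    warning(sprintf(
      "%d feature(s) have a k-th neighbour distance below the bandwidth floor (duplicated features); using bandwidth_floor = %g",
      sum(floored), params$bandwidth_floor))
    sigma[floored] <- params$bandwidth_floor
  }
  gi <- exp(-d^2 / (2 * sigma^2))        # rows scaled by sigma_i
  w <- (gi + t(gi)) / 2
  diag(w) <- 0
  w <- pmin(pmax(w, 0), 1)
  laplacian_from_weights(w)
}

#' Connected components of a thresholded feature graph
#'
#' Binarizes the weight matrix at `edge_threshold` (an edge exists where
#' `W_ij > edge_threshold`, strictly) and labels the connected components of
#' the resulting graph. Labels are contiguous integers starting at 0 and are
#' assigned deterministically: the component containing the lowest-indexed
#' node gets label 0, and so on. In a learned co-activation graph each
#' component is read as one feature module.
#'
#' @param graph A `feature_graph`.
#' @param edge_threshold Nonnegative weight cutoff; kernel weights decay
#'   quickly, so values below the default `0.01` are treated as numerically
#'   absent edges.
#' @return An object of class `component_labeling`: list with `labels`
#'   (0-based integer per node), `n_components`, and `edge_threshold`.
#' @export
connected_components <- function(graph, edge_threshold = 0.01) {
  stopifnot(is_feature_graph(graph))
  if (length(edge_threshold) != 1L || edge_threshold < 0) {
    stop("`edge_threshold` must be a single nonnegative number")
  }
  adj <- (graph$weights > edge_threshold) * 1
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(ig)$membership
  # igraph numbers components by first appearance, i.e. lowest node index
  labels <- as.integer(memb) - 1L
  structure(
    list(labels = labels, n_components = max(labels) + 1L,
         edge_threshold = edge_threshold),
    class = "component_labeling")
}

#' @export
print.component_labeling <- function(x, ...) {
  cat(sprintf("component_labeling: %d components over %d nodes (threshold %g)\n",
              x$n_components, length(x$labels), x$edge_threshold))
  invisible(x)
}

# ---- graph I/O --------------------------------------------------------------

#' Write a feature graph as an edge-list TSV
#'
#' One undirected edge per line with columns `node_i`, `node_j`, `weight`;
#' node indices 0-based with `node_i < node_j`. Only nonzero weights are
#' written.
#'
#' @param graph A `feature_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(is_feature_graph(graph))
  w <- graph$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  df <- data.frame(node_i = idx[, 1L] - 1L, node_j = idx[, 2L] - 1L,
                   weight = w[idx])
  df <- df[order(df$node_i, df$node_j), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a feature graph from an edge-list TSV
#'
#' @param path File written by [write_edge_list] (columns `node_i`, `node_j`,
#'   `weight`, 0-based).
#' @param n_nodes Number of nodes; defaults to one more than the largest index
#'   present (isolated trailing nodes need an explicit count).
#' @return A `feature_graph`.
#' @export
read_edge_list <- function(path, n_nodes = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("node_i", "node_j", "weight") %in% names(df))) {
    stop("edge list must have columns node_i, node_j, weight")
  }
  if (is.null(n_nodes)) {
    n_nodes <- if (nrow(df) == 0L) 0L else max(df$node_i, df$node_j) + 1L
  }
  w <- matrix(0, n_nodes, n_nodes)
  for (r in seq_len(nrow(df))) {
    i <- df$node_i[r] + 1L
    j <- df$node_j[r] + 1L
    w[i, j] <- w[j, i] <- df$weight[r]
  }
  laplacian_from_weights(w)
}

#' Write a feature graph as GraphML
#'
#' @param graph A `feature_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  stopifnot(is_feature_graph(graph))
  ig <- igraph::graph_from_adjacency_matrix(graph$weights,
                                            mode = "undirected",
                                            weighted = TRUE)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Export the graph Laplacian as a dense CSV
#'
#' @param graph A `feature_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_laplacian_csv <- function(graph, path) {
  stopifnot(is_feature_graph(graph))
  lab <- graph$node_labels %||% paste0("node", seq_len(graph$n_nodes) - 1L)
  m <- graph$laplacian
  colnames(m) <- lab
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
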