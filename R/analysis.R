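# Interpretation readouts for a structured layer: per-class mean activation
# maps, segmentation of the layer by class, top-activation masks, marker
# correlation grouped by learned components, and cluster assignment through
# graph components ("super nodes").

#' Per-class average activation maps
#'
#' For each class, the column-wise mean of the structured layer's activations
#' over that class's samples. On a grid-structured layer these are the
#' "brain map" images showing where each class lives.
#'
#' @param activations Samples x neurons matrix.
#' @param labels Vector of class labels aligned with rows; must contain no
#'   missing values.
#' @return A named list (one element per class, in label sort order) of
#'   `activation_map` objects: each a list with `values` (mean activation per
#'   neuron) and `class_id`.
#' @export
class_average_maps <- function(activations, labels) {
  if (!is.matrix(activations)) activations <- as.matrix(activations)
  if (length(labels) != nrow(activations)) {
    stop("`labels` must have one entry per activation row")
  }
  if (anyNA(labels)) stop("`labels` contains missing values")
  classes <- sort(unique(labels))
  maps <- lapply(classes, function(cl) {
    structure(
      list(values = colMeans(activations[labels == cl, , drop = FALSE]),
           class_id = cl),
      class = "activation_map")
  })
  names(maps) <- as.character(classes)
  maps
}

#' Segment the structured layer by class
#'
#' Assigns each neuron to the class whose average map activates it most
#' strongly; ties go to the lowest class id. A neuron whose winning margin
#' (top mean activation minus runner-up) falls below `margin_floor` is left
#' unassigned (`NA`), which is how classes with no dedicated territory show
#' up as a null case.
#'
#' @param maps List of `activation_map`s from [class_average_maps]
#'   (at least 2).
#' @param margin_floor Nonnegative margin below which a neuron is unlabeled.
#' @return An object of class `segmentation`: list with `labels` (class id
#'   per neuron, `NA` where undecided) and `margin` (top1 - top2 per neuron).
#' @export
segment_embedding <- function(maps, margin_floor = 0) {
  if (length(maps) < 2L) stop("need at least 2 class maps")
  lens <- vapply(maps, function(m) length(m$values), integer(1L))
  if (length(unique(lens)) != 1L) {
    stop("all maps must cover the same number of neurons")
  }
  m <- do.call(rbind, lapply(maps, function(x) x$values))  # classes x nodes
  class_ids <- vapply(maps, function(x) x$class_id, maps[[1L]]$class_id)
  win <- apply(m, 2L, which.max)   # ties: lowest row = lowest class id
  margin <- apply(m, 2L, function(col) {
    srt <- sort(col, decreasing = TRUE)
    srt[1L] - srt[2L]
  })
  labels <- class_ids[win]
  labels[margin < margin_floor] <- NA
  structure(list(labels = labels, margin = margin), class = "segmentation")
}

#' Mask of the top-activated neurons
#'
#' Marks the `ceiling(fraction * n)` largest entries of a single activation
#' vector; ties at the cutoff are resolved toward the lower index.
#'
#' @param activation Numeric vector (one sample's activations).
#' @param fraction Fraction in `(0, 1]` of neurons to mark (default 0.1,
#'   i.e. the top 10%).
#' @return Logical vector the same length as `activation`.
#' @export
top_fraction_mask <- function(activation, fraction = 0.1) {
  if (length(activation) == 0L) stop("`activation` must be nonempty")
  if (length(fraction) != 1L || fraction <= 0 || fraction > 1) {
    stop("`fraction` must be in (0, 1]")
  }
  m <- ceiling(fraction * length(activation))
  ord <- order(-activation, seq_along(activation))  # ties: lowest index
  mask <- logical(length(activation))
  mask[ord[seq_len(m)]] <- TRUE
  mask
}

#' Marker-to-neuron correlation grouped by graph component
#'
#' Correlates each marker (e.g. a cell-type marker gene) with each structured
#' layer neuron across samples, and orders the neuron columns by the learned
#' graph's connected components so that each component's block can be read as
#' one meta-feature. Constant neurons or markers get correlation 0 and are
#' flagged rather than producing `NA`.
#'
#' @param embedding_activations Samples x neurons matrix.
#' @param markers Samples x markers matrix (column names label the rows of
#'   the output).
#' @param components A [connected_components] labeling of the layer's graph.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return An object of class `marker_correlation`: list with `cor`
#'   (markers x neurons, columns reordered), `node_order` (original neuron
#'   index per column), `component` (component label per column), and
#'   `constant` (logical per column: neuron had zero variance).
#' @export
component_marker_correlation <- function(embedding_activations, markers,
                                         components,
                                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(components, "component_labeling"))
  if (!is.matrix(embedding_activations)) {
    embedding_activations <- as.matrix(embedding_activations)
  }
  if (!is.matrix(markers)) markers <- as.matrix(markers)
  if (nrow(markers) != nrow(embedding_activations)) {
    stop(sprintf("row mismatch: %d activation rows vs %d marker rows",
                 nrow(embedding_activations), nrow(markers)))
  }
  n_nodes <- ncol(embedding_activations)
  if (length(components$labels) != n_nodes) {
    stop("component labeling does not match the number of neurons")
  }
  node_order <- order(components$labels, seq_len(n_nodes))
  z <- embedding_activations[, node_order, drop = FALSE]
  const_node <- apply(z, 2L, function(col) stats::sd(col) == 0)
  const_marker <- apply(markers, 2L, function(col) stats::sd(col) == 0)
  cm <- matrix(0, ncol(markers), n_nodes)
  ok_n <- which(!const_node)
  ok_m <- which(!const_marker)
  if (length(ok_n) && length(ok_m)) {
    cm[ok_m, ok_n] <- t(stats::cor(z[, ok_n, drop = FALSE],
                                   markers[, ok_m, drop = FALSE],
                                   method = method))
  }
  rownames(cm) <- colnames(markers)
  colnames(cm) <- paste0("node", node_order - 1L)
  structure(
    list(cor = cm, node_order = node_order,
         component = components$labels[node_order],
         constant = const_node, constant_markers = const_marker),
    class = "marker_correlation")
}

#' Assign samples to graph components ("super nodes")
#'
#' Each connected component of the structured layer's graph is treated as a
#' super node; every sample is assigned to the component with the largest
#' summed activation (ties to the lowest component id). With one component
#' per data cluster this recovers the cluster assignment directly from the
#' layer.
#'
#' @param embedding_activations Samples x neurons matrix.
#' @param graph The layer's `feature_graph`.
#' @param threshold Edge threshold for component extraction (default 0.01).
#' @return Integer vector of 0-based component ids, one per sample, with the
#'   `component_labeling` attached as attribute `"components"`.
#' @export
supernode_assignment <- function(embedding_activations, graph,
                                 threshold = 0.01) {
  stopifnot(is_feature_graph(graph))
  if (!is.matrix(embedding_activations)) {
    embedding_activations <- as.matrix(embedding_activations)
  }
  if (ncol(embedding_activations) != graph$n_nodes) {
    stop("activation columns must match graph nodes")
  }
  comp <- connected_components(graph, threshold)
  if (comp$n_components == 1L) {
    warning("graph has a single component; assignment is degenerate")
  }
  scores <- vapply(0:(comp$n_components - 1L), function(cl) {
    rowSums(embedding_activations[, comp$labels == cl, drop = FALSE])
  }, numeric(nrow(embedding_activations)))
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = 1L)
  assign_ <- max.col(scores, ties.method = "first") - 1L
  attr(assign_, "components") <- comp
  assign_
}

#' Plot an activation map on a grid layout
#'
#' Renders an `activation_map` as an image when the layer is grid-structured.
#'
#' @param map An `activation_map` from [class_average_maps].
#' @param rows,cols Grid layout; `rows * cols` must equal the neuron count.
#' @param ... Passed to [graphics::image].
#' @return Invisibly, the rows x cols matrix that was drawn.
#' @export
plot_activation_map <- function(map, rows, cols, ...) {
  stopifnot(inherits(map, "activation_map"))
  if (rows * cols != length(map$values)) {
    stop("rows * cols must equal the number of neurons")
  }
  m <- matrix(map$values, rows, cols, byrow = TRUE)
  graphics::image(t(m)[, rows:1, drop = FALSE], axes = FALSE,
                  main = paste("class", map$class_id), ...)
  invisible(m)
}
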