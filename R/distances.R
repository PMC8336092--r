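#' Validate a dissimilarity matrix
#'
#' Checks the invariants every downstream step relies on: square, numeric,
#' finite, symmetric up to a relative tolerance, zero diagonal, non-negative.
#' Violations are reported with the offending indices. The returned matrix is
#' exactly symmetrized and labelled.
#'
#' @param values Square numeric matrix.
#' @param labels Optional entity labels; defaults to existing dimnames.
#' @param tol Relative symmetry/diagonal tolerance (default 1e-8).
#' @return The validated matrix with entity labels as dimnames.
#' @export
validate_dissimilarity <- function(values, labels = NULL, tol = 1e-8) {
  values <- as.matrix(values)
  if (!is.numeric(values) || nrow(values) != ncol(values))
    stop("dissimilarity must be a square numeric matrix")
  if (any(!is.finite(values)))
    stop("dissimilarity contains non-finite entries")
  scale <- max(abs(values), 1)
  asym <- abs(values - t(values))
  if (max(asym) > tol * scale) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("asymmetric dissimilarity at (%d, %d): %g vs %g",
                 ij[1], ij[2], values[ij[1], ij[2]], values[ij[2], ij[1]]))
  }
  if (max(abs(diag(values))) > tol * scale)
    stop("non-zero diagonal at index ", which.max(abs(diag(values))))
  if (min(values) < -tol * scale) {
    ij <- which(values == min(values), arr.ind = TRUE)[1, ]
    stop(sprintf("negative dissimilarity at (%d, %d): %g",
                 ij[1], ij[2], values[ij[1], ij[2]]))
  }
  values <- (values + t(values)) / 2
  values[values < 0] <- 0
  diag(values) <- 0
  if (is.null(labels)) labels <- rownames(values)
  if (is.null(labels)) labels <- paste0("ind", seq_len(nrow(values)))
  if (length(labels) != nrow(values))
    stop("labels length does not match matrix dimension")
  dimnames(values) <- list(labels, labels)
  values
}

#' Cophenetic distance matrix of a dendrogram
#'
#' For two leaves the cophenetic distance is the merge height at which their
#' clusters first join. Dendrograms built from a distance with an
#' agglomeration criterion are ultrametric, so the resulting matrix is always
#' Euclidean-embeddable and classical scaling needs no correction.
#'
#' The merge-height convention of [stats::hclust()] is used: the distance is
#' the height itself, not twice the leaf depth (tree libraries differ here).
#'
#' @param tree An `hclust` object (or ultrametric `phylo`, converted via
#'   [stats::as.hclust()]) with leaf labels.
#' @return Symmetric matrix of cophenetic distances, labelled by leaf.
#' @export
cophenetic_distance <- function(tree) {
  tree <- as_dendrogram(tree)
  h <- tree$height
  if (length(h) && any(diff(h) < -1e-8 * max(abs(h), 1)))
    stop("merge heights decrease along the merge sequence; tree is not ultrametric")
  for (i in seq_along(h)) {
    for (child in tree$merge[i, ]) {
      if (child > 0 && h[child] > h[i] + 1e-8 * max(abs(h), 1))
        stop("merge ", i, " is lower than its child cluster; tree is not ultrametric")
    }
  }
  validate_dissimilarity(as.matrix(stats::cophenetic(tree)))
}

as_dendrogram <- function(tree) {
  if (inherits(tree, "phylo")) tree <- stats::as.hclust(tree)
  if (!inherits(tree, "hclust"))
    stop("expected an 'hclust' or ultrametric 'phylo' tree")
  if (is.null(tree$labels))
    stop("tree has no leaf labels; entity labels are required")
  tree
}

#' Shortest-path distance matrix of a graph
#'
#' All-pairs shortest-path costs: for binary graphs the minimum number of
#' edges to cross, for positively weighted graphs the minimum sum of edge
#' weights along a path (weights are treated as costs verbatim).
#'
#' Unreachable pairs have no finite path cost. Under the default policy this
#' is an error naming the connected components; policy `"max_plus_one"`
#' substitutes the largest finite distance plus one, which keeps the matrix
#' usable for scaling at the price of distorting the disconnected geometry.
#'
#' @param graph Undirected `igraph` with named vertices; optional positive
#'   `weight` edge attribute.
#' @param policy `"error"` (default) or `"max_plus_one"`.
#' @return Symmetric matrix of path costs, labelled by node.
#' @export
shortest_path_distance <- function(graph, policy = c("error", "max_plus_one")) {
  policy <- match.arg(policy)
  stopifnot(inherits(graph, "igraph"))
  if (igraph::is_directed(graph)) stop("graph must be undirected")
  if (any(igraph::which_loop(graph))) stop("graph must not contain self-loops")
  weighted <- "weight" %in% igraph::edge_attr_names(graph)
  if (weighted && any(igraph::E(graph)$weight <= 0))
    stop("edge weights must be strictly positive")
  if (is.null(igraph::V(graph)$name))
    stop("graph has unnamed nodes; entity labels are required")
  D <- igraph::distances(graph, weights = if (weighted) NULL else NA)
  if (any(is.infinite(D))) {
    if (policy == "error") {
      comp <- igraph::components(graph)
      sizes <- table(comp$membership)
      stop("graph is disconnected (", comp$no, " components of sizes ",
           paste(sizes, collapse = ", "),
           "); use policy = \"max_plus_one\" or supply connected input")
    }
    D[is.infinite(D)] <- max(D[is.finite(D)]) + 1
  }
  validate_dissimilarity(D)
}

#' Align a set of labelled square matrices to one canonical entity order
#'
#' All objects entering an integration must be built on the same entity set;
#' this reorders every matrix to the row order of the first and fails hard on
#' any label mismatch.
#'
#' @param matrices List of labelled square matrices.
#' @return The list, reordered to a common entity order.
#' @export
align_entities <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  ref <- rownames(matrices[[1]])
  if (is.null(ref)) stop("first matrix has no entity labels")
  out <- lapply(seq_along(matrices), function(i) {
    m <- matrices[[i]]
    lab <- rownames(m)
    if (is.null(lab) || !setequal(lab, ref))
      stop("object ", i, " is not defined on the shared entity set")
    m[ref, ref, drop = FALSE]
  })
  names(out) <- names(matrices)
  out
}
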