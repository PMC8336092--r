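#' Agglomerative hierarchical clustering of a dissimilarity
#'
#' Thin, argument-checked front end to [stats::hclust()] restricted to the
#' two criteria the pipeline uses: `ward.D2` (Ward's variance criterion
#' applied to squared input distances, heights reported on the original
#' scale) and `complete` linkage (cluster-pair maxima).
#'
#' @param delta Dissimilarity matrix.
#' @param linkage `"ward.D2"` (default) or `"complete"`.
#' @return An `hclust` object labelled by entity.
#' @export
hierarchical_cluster <- function(delta, linkage = c("ward.D2", "complete")) {
  linkage <- match.arg(linkage)
  delta <- validate_dissimilarity(delta)
  if (nrow(delta) < 2L) stop("need at least two entities to cluster")
  stats::hclust(stats::as.dist(delta), method = linkage)
}

# Silhouette-scan cut: try k = 2..min(Q-1, k_max), keep cuts respecting
# min_cluster_size, pick the k with the largest mean silhouette width on the
# clustering's own input distances; ties go to the smaller k.
adaptive_cut <- function(hc, D, k_max = 10L, min_cluster_size = 1L) {
  Q <- nrow(D)
  if (max(D) < 1e-12)
    return(list(k = 1L, membership = stats::setNames(rep(1L, Q), rownames(D)),
                method = "degenerate", silhouette = NA_real_))
  ks <- seq(2L, min(Q - 1L, k_max))
  ks <- ks[ks >= 2L & ks <= Q - 1L]
  if (Q <= 2L || length(ks) == 0L) {
    k <- Q
    return(list(k = k, membership = stats::cutree(hc, k = k),
                method = "fallback", silhouette = NA_real_))
  }
  scores <- vapply(ks, function(k) {
    cut <- stats::cutree(hc, k = k)
    if (min(table(cut)) < min_cluster_size) return(-Inf)
    mean(cluster::silhouette(cut, dmatrix = D)[, "sil_width"])
  }, numeric(1))
  if (all(!is.finite(scores)))
    stop("no cut respects min_cluster_size = ", min_cluster_size)
  best <- ks[which.max(scores)]
  list(k = best, membership = stats::cutree(hc, k = best),
       method = "silhouette", silhouette = max(scores))
}

#' Cluster the integrated objects on their MFA group coordinates
#'
#' Builds a ward.D2 dendrogram of the objects from the Euclidean distances
#' between their group-coordinate rows, then cuts it flat: either at a forced
#' number of clusters (`k_override`) or adaptively, scanning k = 2..min(Q-1,
#' `k_max`) and keeping the cut with the best average silhouette width. Two
#' coincident objects collapse to a single cluster; with two distinct objects
#' each becomes its own cluster.
#'
#' @param group_coords Q x L matrix of group coordinates (rownames = object
#'   labels), e.g. from [group_coordinates()].
#' @param min_cluster_size Smallest admissible cluster in the adaptive scan
#'   (default 1).
#' @param k_override Force this many clusters instead of scanning.
#' @param k_max Largest k tried by the scan (default 10).
#' @return Object of class `object_clustering`: list with `labels`,
#'   `dendrogram` (`hclust` over objects), `membership` (named integer
#'   vector), `k`, `linkage`, `cut_method`, `silhouette`.
#' @export
cluster_objects <- function(group_coords, min_cluster_size = 1L,
                            k_override = NULL, k_max = 10L) {
  group_coords <- as.matrix(group_coords)
  Q <- nrow(group_coords)
  if (Q < 2L) stop("need at least two objects to cluster")
  if (is.null(rownames(group_coords)))
    rownames(group_coords) <- paste0("object", seq_len(Q))
  D <- as.matrix(stats::dist(group_coords))
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
  if (!is.null(k_override)) {
    if (k_override > Q || k_override < 1L)
      stop("k_override must lie in 1..", Q)
    cut <- list(k = as.integer(k_override),
                membership = stats::cutree(hc, k = k_override),
                method = "override", silhouette = NA_real_)
  } else {
    cut <- adaptive_cut(hc, D, k_max = k_max, min_cluster_size = min_cluster_size)
  }
  structure(list(labels = rownames(group_coords), dendrogram = hc,
                 membership = cut$membership, k = cut$k,
                 linkage = "ward.D2", cut_method = cut$method,
                 silhouette = cut$silhouette),
            class = "object_clustering")
}

#' @export
print.object_clustering <- function(x, ...) {
  cat("object clustering:", length(x$labels), "objects ->", x$k,
      "cluster(s) [", x$linkage, "linkage,", x$cut_method, "cut ]\n")
  for (g in sort(unique(x$membership)))
    cat("  cluster", g, ":", paste(x$labels[x$membership == g], collapse = ", "), "\n")
  invisible(x)
}

#' Consensus tree of a set of dendrograms
#'
#' Re-runs the full projection-integration chain on exactly the given trees:
#' cophenetic distances, classical MDS per tree, MFA of the coordinate
#' tables; the consensus is the ward.D2 hierarchical clustering of the MFA
#' individual coordinates. With a single tree (or identical copies) the
#' consensus reproduces the input's flat partitions at every cut level.
#'
#' @param trees List of `hclust`/`phylo` trees on shared leaves.
#' @param n_axes_mds,n_axes_mfa Axes retained by the MDS and MFA steps
#'   (`NULL` = all positive / all non-zero).
#' @return An `hclust` consensus dendrogram over the shared entities.
#' @export
consensus_tree <- function(trees, n_axes_mds = NULL, n_axes_mfa = NULL) {
  stopifnot(length(trees) >= 1L)
  deltas <- align_entities(lapply(trees, cophenetic_distance))
  coords <- lapply(deltas, function(d)
    classical_mds(d, n_axes = n_axes_mds)$coordinates)
  names(coords) <- names(trees)
  fit <- mfa_fit(coords, n_axes = n_axes_mfa)
  hierarchical_cluster(as.matrix(stats::dist(fit$individual_coordinates)),
                       linkage = "ward.D2")
}

#' Strict-majority consensus network
#'
#' Keeps exactly the edges present in strictly more than half of the input
#' graphs (an edge in exactly Q/2 of them is dropped). Inputs must be binary;
#' weighted graphs are rejected so the user binarizes deliberately.
#'
#' @param graphs List of undirected binary `igraph` objects on shared named
#'   nodes.
#' @return Undirected binary `igraph` consensus.
#' @export
consensus_network <- function(graphs) {
  stopifnot(length(graphs) >= 1L)
  adjs <- lapply(seq_along(graphs), function(i)
    binary_adjacency(graphs[[i]], paste0("graph ", i)))
  adjs <- align_entities(adjs)
  total <- Reduce(`+`, adjs)
  keep <- (total > length(graphs) / 2) * 1L
  igraph::graph_from_adjacency_matrix(keep, mode = "undirected")
}

#' Flat partitions of a dendrogram over a range of cut sizes
#'
#' @param tree An `hclust` tree.
#' @param ks Cut sizes to evaluate.
#' @return Matrix with one column per k (entities in rows).
#' @export
tree_cuts <- function(tree, ks = 2:10) {
  tree <- as_dendrogram(tree)
  ks <- ks[ks >= 1 & ks <= length(tree$labels)]
  stats::cutree(tree, k = ks)
}

#' Best agreement between a dendrogram and a reference partition
#'
#' Scans flat cuts of the tree over `ks` and returns the maximum adjusted
#' Rand index against the reference partition, the convention used to score
#' a consensus tree whose natural cut size is unknown.
#'
#' @param tree An `hclust` tree.
#' @param partition Named group vector over the tree's leaves.
#' @param ks Cut sizes scanned (default 2..10).
#' @return List with `ari` (the maximum), `k` (the argmax cut size).
#' @export
max_cut_ari <- function(tree, partition, ks = 2:10) {
  cuts <- tree_cuts(tree, ks)
  if (is.null(dim(cuts))) cuts <- matrix(cuts, ncol = 1, dimnames = list(names(cuts), NULL))
  aris <- apply(cuts, 2, function(cc) adjusted_rand_index(cc, partition))
  list(ari = max(aris), k = as.integer(colnames(cuts)[which.max(aris)] %||% ks[which.max(aris)]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
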