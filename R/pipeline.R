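#' Integrate a set of objects: project, analyse, cluster, build consensus
#'
#' The end-to-end two-step procedure. Step 1 (projection) turns every object
#' into a dissimilarity matrix — cophenetic distance for trees,
#' shortest-path distance for networks, identity for precomputed
#' dissimilarities — and embeds each with classical MDS. Numeric tables skip
#' step 1 and enter the integration directly. Step 2 (integration) runs MFA
#' on the coordinate tables, clusters the objects on the MFA group
#' coordinates, and builds consensus artifacts: per-cluster (and global)
#' consensus trees from MFA individual coordinates when the objects are
#' trees, strict-majority consensus networks when they are networks.
#'
#' @param objects Named list of objects, all of one type, on shared
#'   entities: `hclust`/`phylo` trees, `igraph` networks, numeric matrices
#'   (tables) or labelled dissimilarity matrices.
#' @param type `"tree"`, `"network"`, `"table"` or `"dissimilarity"`.
#' @param mds_axes,mfa_axes Axes retained by MDS / MFA (`NULL` = all).
#' @param k Forced number of object clusters (`NULL` = adaptive silhouette
#'   scan).
#' @param min_cluster_size,k_max Adaptive-cut controls, see
#'   [cluster_objects()].
#' @param disconnection Shortest-path policy for disconnected networks, see
#'   [shortest_path_distance()].
#' @param lambda Group-coordinate weight convention, see [mfa_fit()].
#' @param consensus Build consensus artifacts (default `TRUE`; tables and
#'   raw dissimilarities never get one).
#' @return Object of class `integration_result`: list with `type`, `mfa`,
#'   `clustering` (an `object_clustering`), `per_cluster` (per cluster: the
#'   member labels and its consensus artifact or `NULL`), `global_consensus`,
#'   `embeddings`, and `provenance`.
#' @examples
#' cfg <- sim_config(n = 40, Q = 6, p = 50, Ks = c(3, 2), seed = 7)
#' trees <- lapply(simulate_gaussian_tables(cfg),
#'                 function(x) stats::hclust(dist(x), "ward.D2"))
#' res <- integrate_objects(trees, type = "tree")
#' res$clustering$k
#' @export
integrate_objects <- function(objects,
                              type = c("tree", "network", "table", "dissimilarity"),
                              mds_axes = NULL, mfa_axes = NULL, k = NULL,
                              min_cluster_size = 1L, k_max = 10L,
                              disconnection = "error",
                              lambda = "singular", consensus = TRUE) {
  type <- match.arg(type)
  stopifnot(is.list(objects), length(objects) >= 2L)
  if (is.null(names(objects))) names(objects) <- paste0("object", seq_along(objects))
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", label, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  deltas <- NULL
  if (type == "table") {
    coords <- stage("alignment", {
      ref <- rownames(objects[[1]])
      lapply(objects, function(x) as.matrix(x)[ref, , drop = FALSE])
    })
  } else {
    deltas <- stage("distance", switch(type,
      tree = lapply(objects, cophenetic_distance),
      network = lapply(objects, shortest_path_distance, policy = disconnection),
      dissimilarity = lapply(objects, validate_dissimilarity)))
    deltas <- stage("alignment", align_entities(deltas))
    names(deltas) <- names(objects)
    coords <- stage("mds", lapply(deltas, function(d)
      classical_mds(d, n_axes = mds_axes)$coordinates))
  }
  fit <- stage("mfa", mfa_fit(coords, n_axes = mfa_axes, lambda = lambda))
  clustering <- stage("object clustering",
    cluster_objects(group_coordinates(fit), min_cluster_size = min_cluster_size,
                    k_override = k, k_max = k_max))
  build <- function(members) {
    if (!consensus) return(NULL)
    switch(type,
      tree = consensus_tree(objects[members], n_axes_mds = mds_axes,
                            n_axes_mfa = mfa_axes),
      network = consensus_network(objects[members]),
      {
        warning("no consensus artifact is defined for objects of type '",
                type, "'")
        NULL
      })
  }
  per_cluster <- lapply(sort(unique(clustering$membership)), function(g) {
    members <- clustering$labels[clustering$membership == g]
    list(cluster = g, members = members,
         consensus = stage(paste0("consensus (cluster ", g, ")"),
                           build(members)))
  })
  global <- stage("consensus (global)", build(names(objects)))
  structure(list(type = type, mfa = fit, clustering = clustering,
                 per_cluster = per_cluster, global_consensus = global,
                 embeddings = if (type == "table") NULL else coords,
                 dissimilarities = deltas,
                 provenance = list(mds_axes = mds_axes, mfa_axes = mfa_axes,
                                   k = k, min_cluster_size = min_cluster_size,
                                   k_max = k_max, lambda = lambda,
                                   disconnection = disconnection)),
            class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat("integration of", length(x$clustering$labels), x$type, "objects\n")
  print(x$clustering)
  if (!is.null(x$global_consensus)) cat("  global consensus: built\n")
  invisible(x)
}

#' Kernel-combination baseline integration
#'
#' The comparison pathway: each object's dissimilarity is double-centred
#' into a kernel (positive-eigenvalue reconstruction), kernels are compared
#' with the Frobenius-cosine C-coefficient and clustered with complete
#' linkage on the induced dissimilarity; each cluster's kernels are averaged
#' into a consensus kernel. For trees, the consensus artifact is the
#' complete-linkage hierarchical clustering of the consensus kernel's
#' induced distances; for networks, the strict-majority consensus of the
#' member graphs (the consensus rule does not change across pathways).
#'
#' @inheritParams integrate_objects
#' @param trace_normalize Trace-normalize kernels before comparison and
#'   combination (default `TRUE`).
#' @return An `integration_result` whose `pathway` element is `"kernel"`;
#'   `per_cluster` entries additionally carry the consensus kernel.
#' @export
kernel_integrate <- function(objects,
                             type = c("tree", "network", "dissimilarity"),
                             k = NULL, min_cluster_size = 1L, k_max = 10L,
                             disconnection = "error", trace_normalize = TRUE,
                             consensus = TRUE) {
  type <- match.arg(type)
  stopifnot(is.list(objects), length(objects) >= 2L)
  if (is.null(names(objects))) names(objects) <- paste0("object", seq_along(objects))
  deltas <- switch(type,
    tree = lapply(objects, cophenetic_distance),
    network = lapply(objects, shortest_path_distance, policy = disconnection),
    dissimilarity = lapply(objects, validate_dissimilarity))
  deltas <- align_entities(deltas)
  names(deltas) <- names(objects)
  kernels <- lapply(deltas, dissimilarity_to_kernel)
  clustering <- cluster_kernels(kernels, min_cluster_size = min_cluster_size,
                                k_override = k, k_max = k_max,
                                trace_normalize = trace_normalize)
  build <- function(members) {
    ck <- combine_kernels(kernels[members], trace_normalize = trace_normalize)
    artifact <- if (!consensus) NULL else switch(type,
      tree = hierarchical_cluster(kernel_to_dissimilarity(ck), "complete"),
      network = consensus_network(objects[members]),
      NULL)
    list(kernel = ck, consensus = artifact)
  }
  per_cluster <- lapply(sort(unique(clustering$membership)), function(g) {
    members <- clustering$labels[clustering$membership == g]
    b <- build(members)
    list(cluster = g, members = members, consensus = b$consensus,
         kernel = b$kernel)
  })
  global <- build(names(objects))
  structure(list(type = type, pathway = "kernel", kernels = kernels,
                 clustering = clustering, per_cluster = per_cluster,
                 global_consensus = global$consensus,
                 global_kernel = global$kernel,
                 dissimilarities = deltas,
                 provenance = list(k = k, min_cluster_size = min_cluster_size,
                                   k_max = k_max,
                                   trace_normalize = trace_normalize,
                                   disconnection = disconnection)),
            class = "integration_result")
}
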