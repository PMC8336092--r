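# Small in-code fixtures shared across test files.

# ward.D2 tree over n random planar points
random_tree <- function(n = 10, seed = 1) {
  withr::with_seed(seed, {
    pts <- matrix(stats::rnorm(2 * n), n, 2,
                  dimnames = list(paste0("ind", seq_len(n)), NULL))
    stats::hclust(stats::dist(pts), method = "ward.D2")
  })
}

# labelled distance matrix of random planar points, plus the points
random_planar <- function(n = 5, seed = 1) {
  withr::with_seed(seed, {
    pts <- matrix(stats::rnorm(2 * n), n, 2,
                  dimnames = list(paste0("ind", seq_len(n)), NULL))
    list(points = pts, delta = as.matrix(stats::dist(pts)))
  })
}

# random symmetric PSD kernel with labels
random_kernel <- function(n = 6, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * (n + 2)), n)
    K <- tcrossprod(X)
    dimnames(K) <- list(paste0("ind", seq_len(n)), paste0("ind", seq_len(n)))
    K
  })
}

# hand-built two/three leaf dendrograms
tiny_tree2 <- function(h = 2) {
  structure(list(merge = matrix(c(-1L, -2L), 1), height = h, order = 1:2,
                 labels = c("a", "b"), method = "manual"),
            class = "hclust")
}
tiny_tree3 <- function() {
  structure(list(merge = matrix(c(-1L, 1L, -2L, -3L), 2, 2), height = c(1, 3),
                 order = 1:3, labels = c("a", "b", "c"), method = "manual"),
            class = "hclust")
}

# small benchmark: cheap analogue of the simulation studies
small_tree_bench <- function(seed = 7, n = 40, Q = 6, p = 60, Ks = c(3, 2)) {
  cfg <- sim_config(n = n, Q = Q, p = p, Ks = Ks, seed = seed)
  tabs <- simulate_gaussian_tables(cfg)
  trees <- lapply(tabs, function(x) stats::hclust(stats::dist(x), "ward.D2"))
  list(config = cfg, tables = tabs, trees = trees)
}

# unit-edge star (hub plus three leaves) shortest-path metric; the smallest
# standard example of a non-Euclidean dissimilarity
star_metric <- function() {
  delta <- matrix(2, 4, 4)
  delta[1, ] <- delta[, 1] <- 1
  diag(delta) <- 0
  dimnames(delta) <- list(c("hub", "l1", "l2", "l3"),
                          c("hub", "l1", "l2", "l3"))
  delta
}

graph_from_edges <- function(nodes, edges) {
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(nodes)
  if (length(edges)) g <- g + igraph::edges(edges)
  g
}

expect_matrix_equal <- function(a, b, tol = 1e-8) {
  expect_equal(unname(as.matrix(a)), unname(as.matrix(b)), tolerance = tol)
}
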