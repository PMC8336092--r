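test_that("linkage front end reproduces brute-force agglomeration heights", {
  d3 <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  for (link in c("ward.D2", "complete")) {
    hc <- hierarchical_cluster(d3, link)
    expect_equal(hc$height[1], 1)
    expect_equal(sort(unname(cutree(hc, 2)[c("a", "b")])), c(1, 1))
  }

  rp4 <- random_planar(4, seed = 31)
  hc <- hierarchical_cluster(rp4$delta, "complete")
  expect_equal(hc$height, complete_heights_oracle(rp4$delta), tolerance = 1e-10)

  rp5 <- random_planar(5, seed = 32)
  hw <- hierarchical_cluster(rp5$delta, "ward.D2")
  expect_equal(hw$height, ward2_heights_oracle(rp5$delta), tolerance = 1e-10)
})

test_that("adaptive cut finds planted blobs and matches a silhouette-scan oracle", {
  hits <- 0L
  for (s in 1:50) {
    withr::with_seed(s, {
      centers <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
      rows <- centers[rep(1:3, each = 4), ] + matrix(stats::rnorm(24, sd = 0.5), 12)
    })
    rownames(rows) <- paste0("object", 1:12)
    oc <- cluster_objects(rows)
    if (oc$k == 3L) hits <- hits + 1L
    # oracle: exhaustive k scan maximizing hand-computed mean silhouette
    D <- as.matrix(stats::dist(rows))
    hc <- stats::hclust(stats::as.dist(D), "ward.D2")
    scores <- vapply(2:10, function(k) sil_mean_oracle(D, cutree(hc, k)), numeric(1))
    expect_equal(oc$k, (2:10)[which.max(scores)])
  }
  expect_gte(hits, 48L)
})

test_that("object clustering handles degenerate and forced cuts", {
  rows <- matrix(1:6, 2, 3, byrow = TRUE,
                 dimnames = list(c("a", "b"), NULL))
  rows["b", ] <- rows["a", ]
  expect_equal(cluster_objects(rows)$k, 1L)

  withr::with_seed(1, rows8 <- matrix(stats::rnorm(24), 8,
                                      dimnames = list(paste0("o", 1:8), NULL)))
  oc <- cluster_objects(rows8, k_override = 4)
  expect_equal(oc$k, 4L)
  expect_equal(length(unique(oc$membership)), 4L)
  expect_error(cluster_objects(rows8, k_override = 9), "k_override")

  # invariance to object order (memberships permute with the labels)
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  oc2 <- cluster_objects(rows8[perm, ], k_override = 4)
  expect_equal(adjusted_rand_index(oc$membership, oc2$membership), 1)
})

test_that("consensus of identical trees preserves the tree's exact geometry", {
  hc <- random_tree(30, seed = 13)
  cons <- consensus_tree(list(a = hc, b = hc, c = hc))
  # the projection-integration chain is exact on identical inputs: the
  # consensus equals the ward.D2 re-clustering of the tree's own cophenetic
  # matrix at every cut level, and is invariant in the number of copies
  direct <- hierarchical_cluster(cophenetic_distance(hc), "ward.D2")
  single <- consensus_tree(list(hc))
  for (k in 2:15) {
    expect_equal(adjusted_rand_index(cutree(cons, k), cutree(direct, k)), 1)
    expect_equal(adjusted_rand_index(cutree(cons, k), cutree(single, k)), 1)
  }
  # ward re-clustering reshapes merge order only where levels are close; the
  # dominant splits of a well-separated hierarchy are reproduced verbatim
  bench <- small_tree_bench(seed = 7)
  t1 <- bench$trees[[1]]
  cons_b <- consensus_tree(list(t1, t1, t1))
  K <- bench$config$Ks[1]
  expect_equal(adjusted_rand_index(cutree(cons_b, K), cutree(t1, K)), 1)
})

test_that("within-pattern consensus trees recover the planted classification", {
  bench <- small_tree_bench(seed = 7)
  cfg <- bench$config
  for (pat in 1:2) {
    members <- which(cfg$assignment == pat)
    cons <- consensus_tree(bench$trees[members])
    K <- cfg$Ks[pat]
    expect_equal(adjusted_rand_index(cutree(cons, K), cfg$partitions[[pat]]), 1)
  }
  # the global consensus max-over-k agreement matches a cut-scan oracle
  cons_all <- consensus_tree(bench$trees)
  m <- max_cut_ari(cons_all, cfg$partitions[[1]], ks = 2:10)
  oracle <- max(vapply(2:10, function(k)
    ari_pair_oracle(cutree(cons_all, k), cfg$partitions[[1]]), numeric(1)))
  expect_equal(m$ari, oracle, tolerance = 1e-12)
})

test_that("majority consensus keeps exactly the strict-majority edges", {
  nodes <- c("a", "b", "c", "d")
  g_ab <- graph_from_edges(nodes, c("a", "b"))
  g_ab_cd <- graph_from_edges(nodes, c("a", "b", "c", "d"))
  g_cd <- graph_from_edges(nodes, c("c", "d"))
  cons3 <- consensus_network(list(g_ab, g_ab_cd, g_cd))
  expect_true(igraph::are_adjacent(cons3, "a", "b"))  # present in 2 of 3
  expect_true(igraph::are_adjacent(cons3, "c", "d"))
  expect_equal(igraph::ecount(cons3), 2)
  # exactly half is dropped: edge a-b in 2 of 4
  cons4 <- consensus_network(list(g_ab, g_ab, g_cd, g_cd))
  expect_equal(igraph::ecount(cons4), 0)

  # permutation invariance and idempotence, plus a counting oracle
  cfg <- sim_config(n = 25, Q = 5, Ks = 3, assignment = rep(1, 5), seed = 17)
  gs <- simulate_sbm_networks(cfg)
  cons <- consensus_network(gs)
  cons_perm <- consensus_network(gs[c(4, 1, 5, 2, 3)])
  expect_matrix_equal(igraph::as_adjacency_matrix(cons)[cfg$entities, cfg$entities],
                      igraph::as_adjacency_matrix(cons_perm)[cfg$entities, cfg$entities])
  total <- Reduce(`+`, lapply(gs, function(g)
    as.matrix(igraph::as_adjacency_matrix(g))[cfg$entities, cfg$entities]))
  expect_matrix_equal(
    as.matrix(igraph::as_adjacency_matrix(cons))[cfg$entities, cfg$entities],
    (total >= 3) * 1)
  expect_matrix_equal(igraph::as_adjacency_matrix(consensus_network(list(gs[[1]]))),
                      igraph::as_adjacency_matrix(gs[[1]]))

  wg <- igraph::set_edge_attr(g_ab, "weight", value = 2.5)
  expect_error(consensus_network(list(wg, g_ab)), "binarize")
})

test_that("consensus block structure dominates between-block noise", {
  cfg <- sim_config(n = 60, Q = 3, Ks = 4, assignment = rep(1, 3), seed = 23)
  gs <- simulate_sbm_networks(cfg)
  cons <- consensus_network(gs)
  A <- as.matrix(igraph::as_adjacency_matrix(cons))[cfg$entities, cfg$entities]
  part <- cfg$partitions[[1]]
  same <- outer(part, part, "==") & upper.tri(A)
  diff <- !outer(part, part, "==") & upper.tri(A)
  expect_gt(sum(A[same]) / sum(same) - sum(A[diff]) / sum(diff), 0.5)
})
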