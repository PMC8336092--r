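test_that("double centering applies the Torgerson formula exactly", {
  delta <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_matrix_equal(double_center(delta), matrix(c(1, -1, -1, 1), 2))

  rp <- random_planar(7, seed = 2)
  B <- double_center(rp$delta)
  expect_true(all(abs(rowSums(B)) < 1e-8))
  # oracle: inner products of the centred generating coordinates
  pc <- scale(rp$points, center = TRUE, scale = FALSE)
  expect_matrix_equal(B, tcrossprod(pc), tol = 1e-8)
})

test_that("classical MDS recovers Euclidean configurations exactly", {
  pts <- matrix(c(0, 0, 3, 0, 0, 4), 3, 2, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), NULL))
  delta <- as.matrix(stats::dist(pts))
  emb <- classical_mds(delta)
  expect_matrix_equal(as.matrix(stats::dist(emb$coordinates)), delta, tol = 1e-8)

  rp <- random_planar(10, seed = 5)
  emb <- classical_mds(rp$delta)
  expect_matrix_equal(as.matrix(stats::dist(emb$coordinates)), rp$delta,
                      tol = 1e-6)
  expect_true(all(diff(emb$eigenvalues) <= 1e-9))
  # X'X is diagonal with the eigenvalues on the diagonal
  XtX <- crossprod(emb$coordinates)
  expect_matrix_equal(XtX, diag(emb$eigenvalues, ncol(XtX)), tol = 1e-6)
})

test_that("MDS agrees with cmdscale as an independent solver", {
  rp <- random_planar(8, seed = 12)
  emb <- classical_mds(rp$delta, n_axes = 2)
  ref <- stats::cmdscale(rp$delta, k = 2)
  expect_matrix_equal(abs(emb$coordinates), abs(ref), tol = 1e-6)
})

test_that("ultrametric cophenetic input yields a positive semi-definite embedding", {
  hc <- random_tree(12, seed = 4)
  delta <- cophenetic_distance(hc)
  chk <- euclidean_check(delta)
  expect_true(chk$euclidean)
  emb <- classical_mds(delta)
  expect_true(all(emb$eigenvalues > 0))
  expect_matrix_equal(as.matrix(stats::dist(emb$coordinates)), delta, tol = 1e-6)
})

test_that("axis truncation keeps the top eigen-pairs of the full solution", {
  rp <- random_planar(10, seed = 7)
  delta <- as.matrix(stats::dist(cbind(rp$points,
                                       matrix(stats::rnorm(10 * 7), 10))))
  dimnames(delta) <- dimnames(rp$delta)
  full <- classical_mds(delta)
  two <- classical_mds(delta, n_axes = 2)
  expect_equal(ncol(two$coordinates), 2L)
  expect_matrix_equal(abs(two$coordinates), abs(full$coordinates[, 1:2]),
                      tol = 1e-8)
  expect_equal(two$eigenvalues, full$eigenvalues[1:2])
})

test_that("non-Euclidean inputs are detected and clipped with a log entry", {
  # unit-edge star metric: hub at distance 1 from three pairwise-distance-2
  # leaves; the leaves' circumradius 2/sqrt(3) > 1 makes it non-embeddable
  delta <- star_metric()
  chk <- euclidean_check(delta)
  ref_eig <- sort(suppressWarnings(stats::cmdscale(delta, k = 3, eig = TRUE))$eig)
  expect_equal(chk$euclidean, min(ref_eig) >= -1e-9 * max(abs(ref_eig)))
  expect_equal(chk$min_eigenvalue, min(ref_eig), tolerance = 1e-8)
  expect_false(chk$euclidean)
  expect_warning(suppressMessages(classical_mds(delta)),
                 "negative eigenvalue mass")
  expect_message(suppressWarnings(classical_mds(delta)), "discarding")

  expect_true(euclidean_check(matrix(0, 3, 3))$euclidean)
  expect_error(classical_mds(matrix(0, 3, 3)), "degenerate")
})

test_that("discarding negative eigenvalues never increases the strain", {
  delta <- star_metric()
  B <- double_center(delta)
  ee <- eigen(B, symmetric = TRUE)
  X_pos <- suppressWarnings(suppressMessages(classical_mds(delta)))$coordinates
  strain_pos <- sum((tcrossprod(X_pos) - B)^2)
  # clamping negatives to zero gives the same reconstruction; keeping all
  # eigenvalues is impossible in real coordinates, clamped is the comparator
  lam <- pmax(ee$values, 0)
  strain_clamped <- sum((ee$vectors %*% diag(lam) %*% t(ee$vectors) - B)^2)
  expect_lte(strain_pos, strain_clamped + 1e-10)
})
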