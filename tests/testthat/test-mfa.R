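test_that("table scaling is idempotent, scale-invariant and oracle-checked", {
  withr::with_seed(1, X <- matrix(stats::rnorm(24), 6, 4,
                                  dimnames = list(paste0("ind", 1:6), NULL)))
  s <- scale_table(X)
  expect_lt(max(abs(colMeans(s$values))), 1e-10)
  expect_equal(svd(s$values)$d[1], 1, tolerance = 1e-8)
  # idempotence and invariance to positive rescaling
  expect_equal(scale_table(s$values)$values, s$values, tolerance = 1e-10)
  expect_equal(scale_table(7 * X)$values, s$values, tolerance = 1e-10)
  # first singular value against power iteration
  Xc <- scale(X, center = TRUE, scale = FALSE)
  expect_equal(s$first_singular_value, withr::with_seed(2, sigma1_oracle(Xc)),
               tolerance = 1e-6)
  expect_error(scale_table(matrix(1, 5, 3)), "degenerate")
})

test_that("single-table MFA reduces to PCA with unit contribution", {
  withr::with_seed(3, X <- matrix(stats::rnorm(40), 8, 5,
                                  dimnames = list(paste0("ind", 1:8), NULL)))
  fit <- mfa_fit(list(X))
  sc <- scale_table(X)$values
  sv <- svd(sc)
  L <- length(fit$singular_values)
  expect_equal(abs(fit$individual_coordinates),
               abs(sv$u[, 1:L] %*% diag(sv$d[1:L], L)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unname(fit$contributions[1, ]), rep(1, L), tolerance = 1e-8)
  expect_equal(unname(fit$group_coordinates[1, ]), fit$lambda, tolerance = 1e-8)
})

test_that("group coordinates follow the blocked-loadings formula and its invariants", {
  withr::with_seed(4, tabs <- lapply(1:3, function(q)
    matrix(stats::rnorm(8 * 3), 8, 3, dimnames = list(paste0("ind", 1:8), NULL))))
  fit <- mfa_fit(tabs)
  # oracle: build the concatenation explicitly, decompose with eigen() on the
  # crossproduct, and sum squared loadings per block
  Xt <- do.call(cbind, lapply(tabs, function(x) scale_table(x)$values))
  ee <- eigen(crossprod(Xt), symmetric = TRUE)
  lam_sv <- sqrt(pmax(ee$values, 0))
  L <- length(fit$singular_values)
  blocks <- rep(1:3, each = 3)
  ctrb_oracle <- rowsum(ee$vectors[, 1:L]^2, blocks)
  coord_oracle <- sweep(ctrb_oracle, 2, lam_sv[1:L], "*")
  expect_equal(unname(fit$contributions), unname(ctrb_oracle), tolerance = 1e-6)
  expect_equal(unname(fit$group_coordinates), unname(coord_oracle), tolerance = 1e-6)
  # per-axis: contributions sum to 1, coordinates to lambda
  expect_equal(unname(colSums(fit$contributions)), rep(1, L), tolerance = 1e-8)
  expect_equal(unname(colSums(fit$group_coordinates)), fit$lambda, tolerance = 1e-8)
  # loadings columns are unit norm
  expect_equal(unname(colSums(fit$loadings^2)), rep(1, L), tolerance = 1e-8)
})

test_that("MFA is invariant to per-table rescaling and symmetric for duplicates", {
  withr::with_seed(5, X <- matrix(stats::rnorm(36), 6, 6,
                                  dimnames = list(paste0("ind", 1:6), NULL)))
  withr::with_seed(6, Y <- matrix(stats::rnorm(30), 6, 5,
                                  dimnames = list(paste0("ind", 1:6), NULL)))
  f1 <- mfa_fit(list(a = X, b = Y))
  f2 <- mfa_fit(list(a = 13 * X, b = 0.01 * Y))
  expect_equal(f1$singular_values, f2$singular_values, tolerance = 1e-8)
  expect_equal(f1$group_coordinates, f2$group_coordinates, tolerance = 1e-8)
  expect_equal(abs(f1$individual_coordinates), abs(f2$individual_coordinates),
               tolerance = 1e-8)

  dup <- mfa_fit(list(a = X, b = X))
  expect_equal(dup$group_coordinates["a", ], dup$group_coordinates["b", ],
               tolerance = 1e-8)
})

test_that("eigenvalue convention squares the singular values and errors are raised", {
  withr::with_seed(7, tabs <- lapply(1:2, function(q)
    matrix(stats::rnorm(20), 5, 4, dimnames = list(paste0("ind", 1:5), NULL))))
  fs <- mfa_fit(tabs, lambda = "singular")
  fe <- mfa_fit(tabs, lambda = "eigen")
  expect_equal(fe$lambda, fs$lambda^2, tolerance = 1e-10)
  expect_equal(fe$contributions, fs$contributions, tolerance = 1e-10)

  bad <- tabs
  rownames(bad[[2]]) <- paste0("x", 1:5)
  expect_error(mfa_fit(bad), "shared entity set")
  expect_warning(mfa_fit(tabs, n_axes = 50), "rank")
})

test_that("MFA of MDS coordinates matches the kernel eigen-structure", {
  # the Gram matrix of the concatenated scaled tables equals the sum of
  # per-object double-centred matrices over their leading eigenvalues
  trees <- lapply(1:3, function(s) random_tree(9, seed = s))
  deltas <- align_entities(lapply(trees, cophenetic_distance))
  coords <- lapply(deltas, function(d) classical_mds(d)$coordinates)
  fit <- mfa_fit(coords)
  Bsum <- Reduce(`+`, lapply(deltas, function(d) {
    B <- double_center(d)
    B / eigen(B, symmetric = TRUE, only.values = TRUE)$values[1]
  }))
  ind <- fit$individual_coordinates
  expect_equal(unname(tcrossprod(ind)), unname(Bsum), tolerance = 1e-6)
})
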