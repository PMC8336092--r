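#' Kernel (similarity) matrix from a dissimilarity
#'
#' Double-centres the squared dissimilarities (`B = -1/2 J D^2 J`) and, when
#' `B` has negative eigenvalues, reconstructs it from its positive
#' eigen-pairs only, so the result is always a valid (positive semi-definite)
#' kernel. For Euclidean dissimilarities the reconstruction leaves `B`
#' unchanged.
#'
#' @param delta Dissimilarity matrix.
#' @param tol Relative eigenvalue tolerance (default 1e-9).
#' @return Symmetric PSD kernel matrix with entity labels.
#' @export
dissimilarity_to_kernel <- function(delta, tol = 1e-9) {
  B <- double_center(delta)
  ee <- eigen(B, symmetric = TRUE)
  cut <- tol * max(abs(ee$values))
  keep <- ee$values > cut
  if (!any(keep))
    stop("degenerate kernel: dissimilarity has no positive-eigenvalue structure")
  if (all(ee$values > -cut)) {
    K <- B
  } else {
    V <- ee$vectors[, keep, drop = FALSE]
    K <- V %*% (ee$values[keep] * t(V))
    K <- (K + t(K)) / 2
    dimnames(K) <- dimnames(B)
  }
  K
}

#' Dissimilarity induced by a kernel
#'
#' Applies `D[i, i'] = sqrt(S[i, i] + S[i', i'] - 2 S[i, i'])`, the distance
#' in the kernel's feature space. Tiny negative radicands from round-off are
#' clamped to zero; larger ones indicate a non-PSD input and raise an error.
#'
#' @param kernel Symmetric PSD matrix with entity labels.
#' @return Validated dissimilarity matrix.
#' @export
kernel_to_dissimilarity <- function(kernel) {
  kernel <- as.matrix(kernel)
  if (max(abs(kernel - t(kernel))) > 1e-8 * max(abs(kernel), 1))
    stop("kernel must be symmetric")
  d <- diag(kernel)
  sq <- outer(d, d, "+") - 2 * kernel
  scale <- max(abs(kernel), 1)
  if (min(sq) < -1e-12 * scale)
    stop("negative squared distance (", min(sq), "); kernel is not PSD")
  sq[sq < 0] <- 0
  validate_dissimilarity(sqrt(sq), labels = rownames(kernel))
}

#' Frobenius-cosine similarity between two kernels (C-coefficient)
#'
#' `C(K1, K2) = <K1, K2>_F / (||K1||_F ||K2||_F)`, the cosine of the angle
#' between the kernels under the Frobenius inner product; for PSD inputs the
#' value lies in `[0, 1]`, and it is invariant to positive rescaling of
#' either argument.
#'
#' @param k1,k2 Kernel matrices on the same entities.
#' @return Scalar in `[-1, 1]`.
#' @export
similarity_coefficient <- function(k1, k2) {
  k1 <- as.matrix(k1); k2 <- as.matrix(k2)
  stopifnot(all(dim(k1) == dim(k2)))
  if (!is.null(rownames(k1)) && !is.null(rownames(k2))) {
    if (!setequal(rownames(k1), rownames(k2)))
      stop("kernels are defined on different entity sets")
    k2 <- k2[rownames(k1), rownames(k1)]
  }
  n1 <- sqrt(sum(k1^2)); n2 <- sqrt(sum(k2^2))
  if (n1 == 0 || n2 == 0)
    stop("similarity coefficient undefined for a zero kernel")
  sum(k1 * k2) / (n1 * n2)
}

#' Pairwise C-coefficient matrix of a kernel list
#'
#' @param kernels Named list of kernel matrices on shared entities.
#' @param trace_normalize Divide each kernel by its trace before comparison
#'   (default `TRUE`), so object scale cannot drive the similarities.
#' @return Symmetric Q x Q matrix of coefficients with unit diagonal.
#' @export
kernel_similarity_matrix <- function(kernels, trace_normalize = TRUE) {
  stopifnot(length(kernels) >= 1L)
  if (is.null(names(kernels))) names(kernels) <- paste0("object", seq_along(kernels))
  kernels <- align_kernels(kernels, trace_normalize)
  Q <- length(kernels)
  C <- diag(1, Q)
  dimnames(C) <- list(names(kernels), names(kernels))
  if (Q > 1) {
    for (a in seq_len(Q - 1)) for (b in seq(a + 1, Q)) {
      C[a, b] <- C[b, a] <- similarity_coefficient(kernels[[a]], kernels[[b]])
    }
  }
  C
}

align_kernels <- function(kernels, trace_normalize) {
  kernels <- align_entities(kernels)
  if (trace_normalize) {
    kernels <- lapply(kernels, function(K) {
      tr <- sum(diag(K))
      if (tr <= 0) stop("kernel with non-positive trace cannot be normalized")
      K / tr
    })
  }
  kernels
}

#' Consensus kernel by convex combination
#'
#' Combines kernels as a weighted average (uniform by default) of
#' trace-normalized inputs. A convex combination of PSD matrices is PSD, so
#' the result is a valid consensus kernel. The `weights` hook accommodates
#' externally computed schemes (e.g. unsupervised multiple-kernel weights).
#'
#' @param kernels Named list of kernel matrices on shared entities.
#' @param weights Optional non-negative weights summing to 1.
#' @param trace_normalize Normalize each kernel to unit trace first
#'   (default `TRUE`).
#' @return Consensus kernel matrix.
#' @export
combine_kernels <- function(kernels, weights = NULL, trace_normalize = TRUE) {
  stopifnot(length(kernels) >= 1L)
  ks <- align_kernels(kernels, trace_normalize)
  if (is.null(weights)) weights <- rep(1 / length(ks), length(ks))
  if (length(weights) != length(ks) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop("weights must be non-negative and sum to 1")
  out <- Reduce(`+`, Map(`*`, ks, weights))
  dimnames(out) <- dimnames(ks[[1]])
  out
}

#' Cluster objects by their kernel similarities
#'
#' The kernel-pathway counterpart of [cluster_objects()]: the C-coefficient
#' matrix is treated as a similarity matrix and transformed to a
#' dissimilarity with the kernel-to-distance formula (for unit diagonal,
#' `sqrt(2 - 2C)`), then clustered with complete linkage and cut with the
#' same adaptive silhouette scan.
#'
#' @inheritParams kernel_similarity_matrix
#' @inheritParams cluster_objects
#' @return An `object_clustering` (complete linkage).
#' @export
cluster_kernels <- function(kernels, min_cluster_size = 1L, k_override = NULL,
                            k_max = 10L, trace_normalize = TRUE) {
  C <- kernel_similarity_matrix(kernels, trace_normalize = trace_normalize)
  D <- kernel_to_dissimilarity(C)
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  Q <- nrow(D)
  if (!is.null(k_override)) {
    if (k_override > Q || k_override < 1L) stop("k_override must lie in 1..", Q)
    cut <- list(k = as.integer(k_override),
                membership = stats::cutree(hc, k = k_override),
                method = "override", silhouette = NA_real_)
  } else {
    cut <- adaptive_cut(hc, D, k_max = k_max, min_cluster_size = min_cluster_size)
  }
  structure(list(labels = rownames(D), dendrogram = hc,
                 membership = cut$membership, k = cut$k,
                 linkage = "complete", cut_method = cut$method,
                 silhouette = cut$silhouette),
            class = "object_clustering")
}
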