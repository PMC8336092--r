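#' Double-centred Gram matrix of a dissimilarity
#'
#' Computes `B = -1/2 J D^2 J` with `J = I - (1/n) 11'`, the Torgerson
#' transform that converts squared dissimilarities into inner products of
#' centred coordinates. If the dissimilarity is Euclidean, `B` is the Gram
#' matrix of the (centred) generating points and is positive semi-definite.
#'
#' @param delta Validated dissimilarity matrix (see
#'   [validate_dissimilarity()]).
#' @return Symmetric matrix `B` with zero row/column sums.
#' @export
double_center <- function(delta) {
  delta <- validate_dissimilarity(delta)
  n <- nrow(delta)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (delta^2) %*% J
  B <- (B + t(B)) / 2
  dimnames(B) <- dimnames(delta)
  B
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Eigendecomposes the double-centred matrix `B` and returns coordinates
#' `X = Q+ L+^(1/2)` built from the positive eigen-pairs only, the
#' configuration minimizing the strain `||XX' - B||^2`. Eigenvalues below
#' `tol` times the largest are treated as zero; genuinely negative
#' eigenvalues (non-Euclidean curvature) are discarded with a log message,
#' and a warning is raised when their mass exceeds 5% of the positive mass.
#'
#' Each coordinate column is sign-fixed so that its largest-magnitude entry
#' is positive, making serialized embeddings stable across eigensolvers.
#'
#' @param delta Dissimilarity matrix.
#' @param n_axes Number of axes to keep, or `NULL` for all positive axes.
#' @param tol Relative eigenvalue tolerance (default 1e-9).
#' @return Object of class `mds_embedding`: list with `coordinates` (n x d,
#'   columns `MDS1..MDSd`), `eigenvalues` (the d retained, decreasing),
#'   `all_eigenvalues`, and `negative_mass` (absolute negative eigenvalue sum
#'   over positive sum).
#' @export
classical_mds <- function(delta, n_axes = NULL, tol = 1e-9) {
  B <- double_center(delta)
  ee <- eigen(B, symmetric = TRUE)
  lambda <- ee$values
  cut <- tol * max(abs(lambda))
  keep <- lambda > cut
  if (!any(keep))
    stop("degenerate input: no positive eigenvalue (constant or zero dissimilarity)")
  neg <- lambda[lambda < -cut]
  neg_mass <- sum(-neg) / sum(lambda[keep])
  if (length(neg))
    message(sprintf(
      "classical_mds: discarding %d negative eigenvalue(s), mass %.3g of positive mass",
      length(neg), neg_mass))
  if (neg_mass > 0.05)
    warning(sprintf(
      "negative eigenvalue mass is %.1f%% of the positive mass; the dissimilarity is far from Euclidean",
      100 * neg_mass))
  d <- sum(keep)
  if (!is.null(n_axes)) d <- min(d, n_axes)
  lam <- lambda[seq_len(d)]
  X <- ee$vectors[, seq_len(d), drop = FALSE] %*% diag(sqrt(lam), d)
  X <- fix_signs(X)
  dimnames(X) <- list(rownames(delta), paste0("MDS", seq_len(d)))
  structure(list(coordinates = X, eigenvalues = lam, all_eigenvalues = lambda,
                 negative_mass = neg_mass),
            class = "mds_embedding")
}

fix_signs <- function(X) {
  for (j in seq_len(ncol(X))) {
    i <- which.max(abs(X[, j]))
    if (X[i, j] < 0) X[, j] <- -X[, j]
  }
  X
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat("classical MDS embedding:", nrow(x$coordinates), "entities,",
      ncol(x$coordinates), "axes\n")
  cat("  leading eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", "), "\n")
  if (x$negative_mass > 0)
    cat(sprintf("  discarded negative eigenvalue mass: %.3g\n", x$negative_mass))
  invisible(x)
}

#' Is a dissimilarity Euclidean-embeddable?
#'
#' A dissimilarity embeds exactly in Euclidean space iff its double-centred
#' matrix is positive semi-definite. Reports the flag and the most negative
#' eigenvalue.
#'
#' @param delta Dissimilarity matrix.
#' @param tol Relative tolerance on eigenvalue negativity (default 1e-9).
#' @return List with `euclidean` (logical) and `min_eigenvalue`.
#' @export
euclidean_check <- function(delta, tol = 1e-9) {
  B <- double_center(delta)
  lambda <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(lambda), .Machine$double.eps)
  list(euclidean = min(lambda) >= -tol * scale, min_eigenvalue = min(lambda))
}
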