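#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected pair-counting agreement, computed from the
#' contingency table of the two label vectors:
#' `ARI = (Index - Expected) / (MaxIndex - Expected)` with
#' `Index = sum_ij C(n_ij, 2)`. Values near 1 indicate identical groupings,
#' values near 0 the agreement expected by chance.
#'
#' When both vectors are named the second is aligned to the first by entity
#' label; unnamed vectors are compared positionally. Label values themselves
#' are irrelevant (the index is invariant to renaming groups).
#'
#' @param p1,p2 Group-label vectors over the same entities.
#' @return A scalar, at most 1.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 1
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 3)) # 4/7
#' @export
adjusted_rand_index <- function(p1, p2) {
  p1 <- as_group_vector(p1)
  p2 <- as_group_vector(p2)
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2)))
      stop("partitions are over different entity sets")
    p2 <- p2[names(p1)]
  }
  if (length(p1) != length(p2))
    stop("partitions have different lengths (", length(p1), " vs ", length(p2), ")")
  n <- length(p1)
  if (n < 2L) stop("ARI is undefined for fewer than two entities")
  tab <- table(p1, p2)
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  idx <- sum(choose(tab, 2))
  expected <- a * b / choose(n, 2)
  max_idx <- (a + b) / 2
  denom <- max_idx - expected
  if (abs(denom) < 1e-12) {
    # both partitions trivial (all-one-group or all-singletons): agreement is
    # total when they induce the same pair co-memberships, zero otherwise
    return(if (abs(idx - max_idx) < 1e-12) 1 else 0)
  }
  (idx - expected) / denom
}

as_group_vector <- function(p) {
  if (is.factor(p)) p <- as.character(p)
  if (is.list(p)) p <- unlist(p)
  p
}

#' Pair-level confusion rates between two binary graphs
#'
#' Treats every unordered node pair as a prediction problem: an edge in
#' `estimate` is a positive call, an edge in `truth` the reference. Reports
#' the true positive rate `tp/(tp+fn)`, false positive rate `fp/(fp+tn)` and
#' true discovery rate (precision) `tp/(tp+fp)` together with the raw counts.
#' Rates with a zero denominator are returned as `NaN` and flagged in
#' `$undefined`.
#'
#' @param estimate,truth Undirected binary `igraph` objects on the same named
#'   node set.
#' @return An object of class `graph_comparison`: list with `tpr`, `fpr`,
#'   `tdr`, counts `tp`, `fp`, `fn`, `tn`, and `undefined` (character vector
#'   of rate names with empty denominators).
#' @export
compare_graphs <- function(estimate, truth) {
  A_est <- binary_adjacency(estimate, "estimate")
  A_tru <- binary_adjacency(truth, "truth")
  if (!setequal(rownames(A_est), rownames(A_tru)))
    stop("graphs are defined on different node sets")
  A_est <- A_est[rownames(A_tru), rownames(A_tru)]
  ut <- upper.tri(A_tru)
  e <- A_est[ut] > 0
  t_ <- A_tru[ut] > 0
  tp <- sum(e & t_); fp <- sum(e & !t_)
  fn <- sum(!e & t_); tn <- sum(!e & !t_)
  rate <- function(num, den) if (den == 0L) NaN else num / den
  res <- list(tpr = rate(tp, tp + fn), fpr = rate(fp, fp + tn),
              tdr = rate(tp, tp + fp), tp = tp, fp = fp, fn = fn, tn = tn)
  res$undefined <- names(Filter(is.nan, res[c("tpr", "fpr", "tdr")]))
  structure(res, class = "graph_comparison")
}

#' @export
print.graph_comparison <- function(x, ...) {
  cat(sprintf("graph comparison over %d node pairs\n", x$tp + x$fp + x$fn + x$tn))
  cat(sprintf("  tpr = %.4f  fpr = %.4f  tdr = %.4f\n", x$tpr, x$fpr, x$tdr))
  cat(sprintf("  tp = %d  fp = %d  fn = %d  tn = %d\n", x$tp, x$fp, x$fn, x$tn))
  if (length(x$undefined))
    cat("  undefined rates:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

binary_adjacency <- function(graph, what = "graph") {
  stopifnot(inherits(graph, "igraph"))
  if ("weight" %in% igraph::edge_attr_names(graph) &&
      any(abs(igraph::E(graph)$weight - 1) > 1e-12))
    stop(what, " is weighted; binarize it before comparison")
  A <- as.matrix(igraph::as_adjacency_matrix(graph, sparse = TRUE) > 0) * 1L
  if (is.null(rownames(A)))
    stop(what, " has unnamed nodes; entity labels are required")
  A
}
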