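#' Centre a table and normalize it by its first singular value
#'
#' MFA's balancing step: each table is column-centred and divided by its
#' largest singular value, so every table's dominant direction of variation
#' enters the global PCA with the same inertia and no single table can
#' dominate the first axis. Optionally columns are also scaled to unit
#' variance first (useful for raw feature tables; MDS coordinate tables are
#' left unscaled).
#'
#' @param table Numeric matrix (entities x features) with rownames.
#' @param scale_unit_variance Scale columns to unit variance before
#'   normalizing (default `FALSE`).
#' @return List with `values` (the scaled table, first singular value 1) and
#'   `first_singular_value` of the centred table.
#' @export
scale_table <- function(table, scale_unit_variance = FALSE) {
  x <- as.matrix(table)
  if (nrow(x) < 2L) stop("a table needs at least two rows")
  xc <- scale(x, center = TRUE, scale = FALSE)
  attr(xc, "scaled:center") <- NULL
  if (scale_unit_variance) {
    sds <- apply(xc, 2, stats::sd)
    xc[, sds > 0] <- sweep(xc[, sds > 0, drop = FALSE], 2, sds[sds > 0], "/")
  }
  s1 <- svd(xc, nu = 0, nv = 0)$d[1]
  if (s1 < 1e-12 * max(1, max(abs(x))))
    stop("degenerate table: all columns constant (first singular value is zero)")
  list(values = xc / s1, first_singular_value = s1)
}

#' Multiple Factor Analysis of a set of coordinate tables
#'
#' Each table is centred and divided by its first singular value, the scaled
#' tables are concatenated column-wise and a single PCA (the "global PCA") is
#' run on the concatenation via singular value decomposition
#' `X~ = U L V'`. The result carries:
#'
#' * individual coordinates `U L` (entity scores on the global axes),
#' * loadings `V`, blocked by table,
#' * per-table contributions `ctrb[q, l] = sum_j V[(q) l, j]^2` (the share of
#'   axis `l` carried by table `q`; sums to 1 over tables), and
#' * group coordinates `coord[q, l] = lambda_l * ctrb[q, l]`, positioning the
#'   tables themselves on each axis.
#'
#' `lambda` controls whether `lambda_l` is the singular value of the
#' concatenation (default) or its square (the eigenvalue convention of
#' common MFA implementations); the choice rescales group coordinates per
#' axis monotonically and does not change which tables cluster together.
#'
#' @param tables Named list of numeric matrices over the same ordered
#'   entities (rownames must match).
#' @param n_axes Number of global axes to retain; `NULL` keeps every axis of
#'   numerically non-zero inertia.
#' @param lambda `"singular"` or `"eigen"`.
#' @param scale_unit_variance Passed to [scale_table()].
#' @return Object of class `mfa`: list with `entities`, `singular_values`,
#'   `lambda` (per-axis weights under the chosen convention), `loadings`,
#'   `individual_coordinates`, `group_coordinates`, `contributions`,
#'   `table_labels`, `block_sizes`, `lambda_mode`.
#' @export
mfa_fit <- function(tables, n_axes = NULL, lambda = c("singular", "eigen"),
                    scale_unit_variance = FALSE) {
  lambda <- match.arg(lambda)
  stopifnot(is.list(tables), length(tables) >= 1L)
  table_labels <- names(tables)
  if (is.null(table_labels)) table_labels <- paste0("table", seq_along(tables))
  ref <- rownames(tables[[1]])
  if (is.null(ref)) stop("tables must carry entity rownames")
  tables <- lapply(seq_along(tables), function(q) {
    x <- as.matrix(tables[[q]])
    if (is.null(rownames(x)) || !setequal(rownames(x), ref))
      stop("table ", q, " is not defined on the shared entity set")
    x[ref, , drop = FALSE]
  })
  scaled <- lapply(tables, scale_table, scale_unit_variance = scale_unit_variance)
  block_sizes <- vapply(scaled, function(s) ncol(s$values), integer(1))
  Xt <- do.call(cbind, lapply(scaled, `[[`, "values"))
  sv <- svd(Xt)
  rank <- sum(sv$d > 1e-12 * sv$d[1])
  L <- rank
  if (!is.null(n_axes)) {
    if (n_axes > rank)
      warning("requested ", n_axes, " axes but rank is ", rank, "; truncating")
    L <- min(L, n_axes)
  }
  d <- sv$d[seq_len(L)]
  lam <- if (lambda == "singular") d else d^2
  U <- sv$u[, seq_len(L), drop = FALSE]
  V <- sv$v[, seq_len(L), drop = FALSE]
  ind <- U %*% diag(d, L)
  blocks <- rep(seq_along(block_sizes), block_sizes)
  ctrb <- rowsum(V^2, blocks)
  coord <- sweep(ctrb, 2, lam, "*")
  axis_names <- paste0("Dim", seq_len(L))
  dimnames(ind) <- list(ref, axis_names)
  dimnames(ctrb) <- dimnames(coord) <- list(table_labels, axis_names)
  dimnames(V) <- list(NULL, axis_names)
  structure(list(entities = ref, singular_values = d, lambda = lam,
                 loadings = V, individual_coordinates = ind,
                 group_coordinates = coord, contributions = ctrb,
                 table_labels = table_labels, block_sizes = block_sizes,
                 lambda_mode = lambda,
                 first_singular_values = vapply(scaled, `[[`, numeric(1),
                                                "first_singular_value")),
            class = "mfa")
}

#' Group coordinates and contributions of a fitted MFA
#'
#' Accessor for the per-table axis positions `coord[q, l] = lambda_l *
#' ctrb[q, l]`; the contribution matrix rides along as the `"contributions"`
#' attribute. Per axis the contributions sum to 1 and the coordinates to
#' `lambda_l`.
#'
#' @param fit An [mfa_fit()] result.
#' @return Q x L matrix of group coordinates.
#' @export
group_coordinates <- function(fit) {
  stopifnot(inherits(fit, "mfa"))
  structure(fit$group_coordinates, contributions = fit$contributions)
}

#' @export
print.mfa <- function(x, ...) {
  cat("MFA fit:", length(x$table_labels), "tables,", length(x$entities),
      "entities,", length(x$singular_values), "axes\n")
  cat("  singular values:",
      paste(signif(utils::head(x$singular_values, 5), 4), collapse = ", "),
      if (length(x$singular_values) > 5) "..." else "", "\n")
  cat("  axis-1 contributions:",
      paste(sprintf("%s %.2f", x$table_labels, x$contributions[, 1]),
            collapse = ", "), "\n")
  invisible(x)
}
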