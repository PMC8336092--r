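#' Read and write ultrametric trees as Newick
#'
#' Trees are encoded with branch lengths such that every leaf's distance to
#' the root equals the root merge height (leaves at height zero), the usual
#' encoding of an ultrametric dendrogram. Internal nodes are unlabelled;
#' leaf labels carry the entity identity, so alignment across files is by
#' label, never by order.
#'
#' @param tree An `hclust` tree.
#' @param path File path.
#' @return `read_newick()` returns an `hclust` (or list of them for a
#'   multi-tree file); `write_newick()` returns `path` invisibly.
#' @export
write_newick <- function(tree, path) {
  tree <- as_dendrogram(tree)
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  phy <- ape::read.tree(path)
  if (inherits(phy, "multiPhylo")) return(lapply(phy, stats::as.hclust))
  stats::as.hclust(phy)
}

#' Read and write graphs as TSV edge lists
#'
#' Three tab-separated columns `from`, `to`, `weight` with a header row;
#' binary graphs carry weight 1. Isolated nodes survive a round trip through
#' an optional `# nodes:` comment line listing every node.
#'
#' @param graph An undirected `igraph` with named vertices.
#' @param path File path.
#' @return `read_edgelist()` returns an `igraph`; writers return `path`
#'   invisibly.
#' @export
write_edgelist <- function(graph, path) {
  stopifnot(inherits(graph, "igraph"))
  el <- igraph::as_data_frame(graph, what = "edges")
  if (!"weight" %in% names(el)) el$weight <- rep(1, nrow(el))
  el <- el[, c("from", "to", "weight")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# nodes: ", paste(igraph::V(graph)$name, collapse = "\t")),
             con)
  utils::write.table(el, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path) {
  first <- readLines(path, n = 1)
  nodes <- NULL
  if (startsWith(first, "# nodes:"))
    nodes <- strsplit(sub("^# nodes: ?", "", first), "\t")[[1]]
  el <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(el, directed = FALSE, vertices = nodes)
  if (all(abs(igraph::E(g)$weight - 1) < 1e-12))
    g <- igraph::delete_edge_attr(g, "weight")
  g
}

#' Read and write labelled square matrices as CSV
#'
#' First column and header row carry the entity labels; used for adjacency,
#' dissimilarity and kernel matrices.
#'
#' @param m Labelled square matrix.
#' @param path File path.
#' @return `read_matrix_csv()` returns the matrix; the writer returns `path`
#'   invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Read and write numeric tables (entities x features) as CSV
#'
#' @param table Numeric matrix with entity rownames.
#' @param path File path.
#' @return `read_table_csv()` returns the matrix; the writer returns `path`
#'   invisibly.
#' @export
write_table_csv <- function(table, path) write_matrix_csv(table, path)

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) read_matrix_csv(path)

#' Read and write partitions as two-column CSV (entity, group)
#'
#' @param partition Named group vector.
#' @param path File path.
#' @return `read_partition_csv()` returns a named integer vector; the writer
#'   returns `path` invisibly.
#' @export
write_partition_csv <- function(partition, path) {
  utils::write.csv(data.frame(entity = names(partition),
                              group = as.vector(partition)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition_csv
#' @export
read_partition_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$group, df$entity)
}

#' Serialize an MDS embedding as CSV plus an eigenvalue side-car
#'
#' @param embedding An `mds_embedding`.
#' @param path CSV path for the coordinates; eigenvalues go to
#'   `<path>.eigen.json`.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  stopifnot(inherits(embedding, "mds_embedding"))
  write_matrix_csv(embedding$coordinates, path)
  jsonlite::write_json(list(eigenvalues = embedding$eigenvalues,
                            all_eigenvalues = embedding$all_eigenvalues,
                            negative_mass = embedding$negative_mass),
                       paste0(path, ".eigen.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Serialize an MFA fit as a directory of CSV/JSON files
#'
#' Writes `individual_coordinates.csv`, `group_coordinates.csv`,
#' `contributions.csv` and `eigen.json` under `dir`.
#'
#' @param fit An `mfa` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mfa <- function(fit, dir) {
  stopifnot(inherits(fit, "mfa"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_csv(fit$individual_coordinates,
                   file.path(dir, "individual_coordinates.csv"))
  write_matrix_csv(fit$group_coordinates,
                   file.path(dir, "group_coordinates.csv"))
  write_matrix_csv(fit$contributions, file.path(dir, "contributions.csv"))
  jsonlite::write_json(list(singular_values = fit$singular_values,
                            lambda = fit$lambda, lambda_mode = fit$lambda_mode,
                            block_sizes = as.list(stats::setNames(
                              as.integer(fit$block_sizes), fit$table_labels)),
                            first_singular_values = as.list(stats::setNames(
                              fit$first_singular_values, fit$table_labels))),
                       file.path(dir, "eigen.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Write an integration result to a directory
#'
#' Per-cluster and global consensus artifacts go out as Newick or edge-list
#' TSV, the MFA as its CSV directory, and a `summary.json` records the
#' clustering, retained axes and file paths.
#'
#' @param result An `integration_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_integration_result <- function(result, dir) {
  stopifnot(inherits(result, "integration_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  write_artifact <- function(art, stem) {
    if (is.null(art)) return(NULL)
    if (inherits(art, "hclust")) {
      p <- file.path(dir, paste0(stem, ".nwk")); write_newick(art, p)
    } else {
      p <- file.path(dir, paste0(stem, ".tsv")); write_edgelist(art, p)
    }
    p
  }
  for (pc in result$per_cluster)
    files[[paste0("cluster", pc$cluster)]] <-
      write_artifact(pc$consensus, paste0("consensus_cluster", pc$cluster))
  files$global <- write_artifact(result$global_consensus, "consensus_global")
  if (!is.null(result$mfa)) write_mfa(result$mfa, file.path(dir, "mfa"))
  summary <- list(
    type = result$type,
    pathway = if (is.null(result$pathway)) "mfa" else result$pathway,
    n_objects = length(result$clustering$labels),
    k = result$clustering$k,
    cut_method = result$clustering$cut_method,
    clusters = lapply(result$per_cluster, function(pc)
      list(cluster = pc$cluster, members = pc$members)),
    membership = as.list(result$clustering$membership),
    provenance = result$provenance,
    files = files)
  if (!is.null(result$mfa)) summary$lambda <- result$mfa$lambda
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a pipeline configuration file
#'
#' A flat YAML (or JSON) key-value file mirroring the arguments of
#' [run_pipeline()]: `object_type`, `inputs` (vector of file paths or a
#' directory), `mds_axes`, `mfa_axes`, `k`, `min_cluster_size`,
#' `disconnection`, `seed`, `out`.
#'
#' @param path Config file path.
#' @return Named list of settings.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(cfg$object_type))
    stop("config must set 'object_type' (tree|network|table|dissimilarity)")
  cfg
}

#' Run the full integration pipeline from a configuration
#'
#' Loads the objects named by the configuration (Newick trees, edge-list or
#' adjacency-CSV networks, CSV tables or dissimilarities), runs
#' [integrate_objects()] and writes every artifact plus a JSON summary to
#' the output directory. One log line is emitted per stage.
#'
#' @param config A config list (see [read_pipeline_config()]) or the path to
#'   a config file.
#' @param out Output directory (overrides `config$out`).
#' @return The `integration_result`, invisibly.
#' @export
run_pipeline <- function(config, out = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out <- out %||% config$out
  inputs <- config$inputs
  if (length(inputs) == 1L && dir.exists(inputs))
    inputs <- list.files(inputs, full.names = TRUE)
  if (length(inputs) < 2L) stop("need at least two input objects")
  type <- config$object_type
  load_one <- function(p) {
    switch(type,
      tree = read_newick(p),
      network = if (grepl("\\.csv$", p))
        igraph::graph_from_adjacency_matrix(read_matrix_csv(p) > 0,
                                            mode = "undirected")
      else read_edgelist(p),
      table = read_table_csv(p),
      dissimilarity = validate_dissimilarity(read_matrix_csv(p)))
  }
  objects <- lapply(inputs, load_one)
  names(objects) <- sub("\\.[^.]+$", "", basename(inputs))
  message("loaded ", length(objects), " ", type, " object(s)")
  res <- integrate_objects(
    objects, type = type,
    mds_axes = config$mds_axes, mfa_axes = config$mfa_axes,
    k = config$k,
    min_cluster_size = config$min_cluster_size %||% 1L,
    k_max = config$k_max %||% 10L,
    disconnection = config$disconnection %||% "error",
    lambda = config$lambda %||% "singular")
  message("object clustering: k = ", res$clustering$k,
          " (", res$clustering$cut_method, " cut)")
  if (!is.null(res$mfa))
    message("MFA: ", length(res$mfa$singular_values), " axes retained")
  if (!is.null(out)) {
    write_integration_result(res, out)
    message("results written to ", out)
  }
  invisible(res)
}
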