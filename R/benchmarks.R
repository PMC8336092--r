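#' Simulate one replicate of a benchmark study
#'
#' Sets up the standard benchmark conditions — `Q = 9` objects on `n = 100`
#' entities carrying three planted classification patterns with `K = 4, 3, 5`
#' groups (three objects per pattern) — and generates the objects: for the
#' `"trees"` study, Gaussian tables with `p = 1000` features (group means
#' `5k`, table-`q` variance `q^2`) each summarized by a ward.D2 tree on
#' Euclidean distances; for the `"networks"` study, block-model graphs with
#' within-group edge probability 0.8 and between-group probability 0.05.
#'
#' @param study `"trees"` or `"networks"`.
#' @param seed Integer seed.
#' @param n,Q,p,Ks,... Overrides forwarded to [sim_config()].
#' @return List with `config`, `partitions`, `objects` (trees or graphs) and,
#'   for the tree study, the generating `tables`.
#' @export
simulate_benchmark <- function(study = c("trees", "networks"), seed = 1,
                               n = 100, Q = 9, p = 1000, Ks = c(4, 3, 5), ...) {
  study <- match.arg(study)
  cfg <- sim_config(n = n, Q = Q, p = p, Ks = Ks, seed = seed, ...)
  if (study == "trees") {
    tables <- simulate_gaussian_tables(cfg)
    trees <- lapply(tables, function(x) stats::hclust(stats::dist(x), "ward.D2"))
    names(trees) <- sub("^table", "tree", names(tables))
    list(study = study, config = cfg, partitions = cfg$partitions,
         objects = trees, tables = tables)
  } else {
    nets <- simulate_sbm_networks(cfg)
    list(study = study, config = cfg, partitions = cfg$partitions,
         objects = nets)
  }
}

#' Replicate a benchmark study and tabulate consensus quality
#'
#' Runs the requested study `n_reps` times under derived seeds and scores
#' every consensus artifact against the planted structure. For trees each
#' cell is the maximum-over-cut-sizes ARI between a consensus tree (global
#' and per cluster) and a planted classification; for networks each cell is
#' the pair-level tpr/fpr/tdr of a per-cluster consensus network (estimate)
#' against each simulated network (truth). Cluster columns are labelled by
#' the pattern carried by the majority of their members.
#'
#' @param study `"trees"` or `"networks"`.
#' @param n_reps Number of replicates.
#' @param seed Base seed; replicate `r` uses `seed + 1000 * (r - 1)`.
#' @param ks Cut sizes scanned for tree ARIs (default 2..10).
#' @param ... Forwarded to [simulate_benchmark()].
#' @return List with `results` (long per-replicate data frame) and `summary`
#'   (mean and sd per cell across replicates).
#' @export
replicate_benchmark <- function(study = c("trees", "networks"), n_reps = 5,
                                seed = 1, ks = 2:10, ...) {
  study <- match.arg(study)
  rows <- list()
  for (r in seq_len(n_reps)) {
    s <- seed + 1000L * (r - 1L)
    bench <- simulate_benchmark(study, seed = s, ...)
    if (study == "trees") {
      res <- integrate_objects(bench$objects, type = "tree")
      score <- function(tree, cons_label) {
        do.call(rbind, lapply(seq_along(bench$partitions), function(cl) {
          m <- max_cut_ari(tree, bench$partitions[[cl]], ks = ks)
          data.frame(rep = r, seed = s, consensus = cons_label,
                     class = cl, ari = m$ari, best_k = m$k)
        }))
      }
      rows[[length(rows) + 1L]] <- score(res$global_consensus, "global")
      for (pc in res$per_cluster) {
        lab <- paste0("cluster_pattern",
                      majority_pattern(pc$members, bench$config))
        rows[[length(rows) + 1L]] <- score(pc$consensus, lab)
      }
    } else {
      res <- integrate_objects(bench$objects, type = "network")
      for (pc in res$per_cluster) {
        lab <- paste0("cluster_pattern",
                      majority_pattern(pc$members, bench$config))
        for (q in seq_along(bench$objects)) {
          cmp <- compare_graphs(pc$consensus, bench$objects[[q]])
          rows[[length(rows) + 1L]] <- data.frame(
            rep = r, seed = s, consensus = lab,
            network = names(bench$objects)[q],
            within = bench$config$assignment[q] ==
              majority_pattern(pc$members, bench$config),
            tpr = cmp$tpr, fpr = cmp$fpr, tdr = cmp$tdr)
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  num <- names(results)[vapply(results, is.numeric, logical(1))]
  num <- setdiff(num, c("rep", "seed", "class", "best_k"))
  by_cols <- intersect(c("consensus", "class", "network"), names(results))
  agg <- stats::aggregate(results[num], results[by_cols],
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  list(results = results, summary = agg)
}

# pattern index carried by the majority of an object subset; members are the
# generator's names ("tree3", "net5", "table1") whose suffix is the object index
majority_pattern <- function(members, config) {
  q <- as.integer(sub("^\\D+", "", members))
  if (any(is.na(q))) stop("cannot recover object indices from labels: ",
                          paste(members, collapse = ", "))
  as.integer(names(which.max(table(config$assignment[q]))))
}
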