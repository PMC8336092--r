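#' Random partitions with near-zero mutual agreement
#'
#' Draws one partition of `n` entities per requested group count, assigning
#' entities to groups uniformly at random and independently across patterns.
#' The draw is repeated until every group of every partition is non-empty and
#' every pair of partitions (with at least two groups each) has an adjusted
#' Rand index below `max_ari`, so the planted classifications carry
#' essentially independent grouping information.
#'
#' @param n Number of entities.
#' @param Ks Integer vector of group counts, one partition per entry.
#' @param seed Optional integer seed; when given, the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @param max_ari Upper bound on the pairwise ARI between the returned
#'   partitions (default 0.05).
#' @param max_tries Resampling budget before giving up.
#' @return A named list of partitions; each partition is an integer vector of
#'   group ids (1..K) named by entity label (`ind1`, `ind2`, ...).
#' @examples
#' parts <- make_partitions(60, c(4, 3, 5), seed = 1)
#' adjusted_rand_index(parts[[1]], parts[[2]]) < 0.05
#' @export
make_partitions <- function(n, Ks, seed = NULL, max_ari = 0.05, max_tries = 1000L) {
  Ks <- as.integer(Ks)
  if (n < 2L || any(Ks < 1L))
    stop("invalid configuration: need n >= 2 and all group counts >= 1")
  if (n < 2L * max(Ks))
    stop("invalid configuration: n must be at least twice the largest group count ",
         "(n = ", n, ", max K = ", max(Ks), ")")
  draw <- function() {
    lapply(Ks, function(K) {
      repeat {
        g <- sample.int(K, n, replace = TRUE)
        if (length(unique(g)) == K) break
      }
      stats::setNames(g, paste0("ind", seq_len(n)))
    })
  }
  run <- function() {
    for (i in seq_len(max_tries)) {
      parts <- draw()
      ok <- TRUE
      if (length(parts) > 1L) {
        for (a in seq_len(length(parts) - 1L)) {
          for (b in seq(a + 1L, length(parts))) {
            if (Ks[a] < 2L || Ks[b] < 2L) next
            if (adjusted_rand_index(parts[[a]], parts[[b]]) >= max_ari) ok <- FALSE
          }
        }
      }
      if (ok) {
        names(parts) <- paste0("pattern", seq_along(parts))
        return(parts)
      }
    }
    stop("could not draw partitions with pairwise ARI < ", max_ari,
         " in ", max_tries, " tries")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulation configuration for the grouped Gaussian / block-model benchmarks
#'
#' Bundles everything the two generators need: the planted partitions, the
#' mapping from object index to partition, group means (tables) and
#' within/between connection probabilities (networks). Patterns are assigned
#' to objects in consecutive blocks (with `Q = 9` and three patterns, objects
#' 1-3 carry pattern 1, 4-6 pattern 2, 7-9 pattern 3).
#'
#' @param n Number of entities (rows / nodes).
#' @param Q Number of tables or networks to generate.
#' @param p Number of features per table (tables only).
#' @param Ks Group counts of the planted classification patterns.
#' @param group_means Vector of group means `mu_k`, length at least `max(Ks)`;
#'   defaults to `5 * k`, spaced widely enough that the noisiest table
#'   (standard deviation `Q`) still separates the groups once averaged over
#'   `p` features.
#' @param within_prob,between_prob Block-model edge probabilities `pi_kk`
#'   (same group) and `pi_kl` (different groups).
#' @param assignment Optional integer vector of length `Q` mapping each object
#'   to a pattern index; defaults to consecutive blocks.
#' @param seed Integer seed; object `q` uses the derived stream `seed + q` so
#'   objects can be regenerated independently.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n = 100, Q = 9, p = 1000, Ks = c(4, 3, 5),
                       group_means = NULL, within_prob = 0.8,
                       between_prob = 0.05, assignment = NULL, seed = 1) {
  Ks <- as.integer(Ks)
  if (is.null(group_means)) group_means <- 5 * seq_len(max(Ks))
  if (length(group_means) < max(Ks))
    stop("invalid configuration: group_means must cover the largest group count")
  if (anyDuplicated(group_means[seq_len(max(Ks))]))
    stop("invalid configuration: group means must be distinct")
  if (within_prob < 0 || within_prob > 1 || between_prob < 0 || between_prob > 1)
    stop("invalid configuration: connection probabilities must lie in [0, 1]")
  if (is.null(assignment))
    assignment <- rep(seq_along(Ks), each = ceiling(Q / length(Ks)))[seq_len(Q)]
  assignment <- as.integer(assignment)
  if (length(assignment) != Q || any(assignment < 1L) || any(assignment > length(Ks)))
    stop("invalid configuration: assignment must map each of the ", Q,
         " objects to one of ", length(Ks), " patterns")
  partitions <- make_partitions(n, Ks, seed = seed)
  structure(
    list(n = as.integer(n), Q = as.integer(Q), p = as.integer(p), Ks = Ks,
         group_means = group_means, within_prob = within_prob,
         between_prob = between_prob, assignment = assignment,
         partitions = partitions, entities = names(partitions[[1]]),
         seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration:", x$Q, "objects on", x$n, "entities\n")
  cat("  patterns: K =", paste(x$Ks, collapse = "/"),
      "| assignment:", paste(x$assignment, collapse = " "), "\n")
  cat("  tables: p =", x$p, ", group means",
      paste(signif(x$group_means, 3), collapse = ", "), "\n")
  cat("  networks: pi_within =", x$within_prob,
      ", pi_between =", x$between_prob, "\n")
  invisible(x)
}

#' Grouped Gaussian feature tables
#'
#' Generates `Q` numeric tables on the shared entities. Entry `(i, j)` of
#' table `q` is drawn `N(mu_k, q^2)` where `k` is entity `i`'s group in the
#' classification pattern assigned to table `q`: the mean encodes the planted
#' grouping and the variance grows with the (1-based) table index, so later
#' tables are noisier renderings of their pattern.
#'
#' @param config A [sim_config()].
#' @return Named list of `Q` numeric matrices (`n` x `p`, rownames = entity
#'   labels), each with attributes `table_index` and `pattern`.
#' @export
simulate_gaussian_tables <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  out <- vector("list", config$Q)
  for (q in seq_len(config$Q)) {
    part <- config$partitions[[config$assignment[q]]]
    mu <- config$group_means[part]
    Y <- withr::with_seed(config$seed + q,
      matrix(stats::rnorm(config$n * config$p, mean = mu, sd = q),
             nrow = config$n, ncol = config$p))
    dimnames(Y) <- list(config$entities, paste0("V", seq_len(config$p)))
    attr(Y, "table_index") <- q
    attr(Y, "pattern") <- config$assignment[q]
    out[[q]] <- Y
  }
  stats::setNames(out, paste0("table", seq_len(config$Q)))
}

#' Stochastic block-model networks
#'
#' Generates `Q` undirected simple graphs on the shared entities. Each
#' unordered node pair carries an edge with probability `within_prob` when the
#' two nodes share a group in the pattern assigned to network `q`, and
#' `between_prob` otherwise; no self-loops, symmetric by construction.
#'
#' @param config A [sim_config()].
#' @return Named list of `Q` undirected `igraph` objects with vertex names
#'   equal to the entity labels and attributes `table_index` / `pattern`.
#' @export
simulate_sbm_networks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n
  out <- vector("list", config$Q)
  for (q in seq_len(config$Q)) {
    part <- config$partitions[[config$assignment[q]]]
    P <- ifelse(outer(part, part, "=="), config$within_prob, config$between_prob)
    ut <- upper.tri(P)
    A <- matrix(0L, n, n, dimnames = list(config$entities, config$entities))
    A[ut] <- withr::with_seed(config$seed + q,
                              stats::rbinom(sum(ut), 1L, P[ut]))
    A <- A + t(A)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    g <- igraph::set_graph_attr(g, "table_index", q)
    g <- igraph::set_graph_attr(g, "pattern", config$assignment[q])
    out[[q]] <- g
  }
  stats::setNames(out, paste0("net", seq_len(config$Q)))
}
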