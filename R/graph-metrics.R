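#' Modularity of a partition (Q)
#'
#' Q = sum over communities i of (e_ii - a_i^2), where e_ii is the fraction of
#' edges with both endpoints in community i and a_i is the fraction of edge
#' endpoints attached to community i. Undefined (error) on edgeless graphs.
#'
#' @param graph a `binary_graph` with at least one edge.
#' @param partition a `partition` object or an integer membership vector
#'   (one community id per node).
#' @return modularity Q in [-1, 1].
#' @export
modularity_score <- function(graph, partition) {
  mem <- partition_membership(partition, graph$n_nodes)
  e <- graph_edges(graph)
  m <- nrow(e)
  if (m == 0L) stop("modularity undefined on an edgeless graph")
  ids <- sort(unique(mem))
  same <- mem[e[, 1]] == mem[e[, 2]]
  e_ii <- vapply(ids, function(i) sum(same & mem[e[, 1]] == i), numeric(1)) / m
  ends <- c(mem[e[, 1]], mem[e[, 2]])
  a_i <- vapply(ids, function(i) sum(ends == i), numeric(1)) / (2 * m)
  sum(e_ii - a_i^2)
}

# fast path used inside enumeration: Q for one membership vector given a
# precomputed edge list and m
.q_fast <- function(mem, e1, e2, m, n_nodes) {
  same <- mem[e1] == mem[e2]
  within <- tabulate(mem[e1][same], nbins = n_nodes)
  ends <- tabulate(c(mem[e1], mem[e2]), nbins = n_nodes)
  sum(within) / m - sum((ends / (2 * m))^2)
}

#' Community partition
#'
#' Every node is assigned exactly one community; ids are relabeled to be
#' contiguous integers starting at 1 in order of first appearance.
#'
#' @param assignment integer membership vector, one entry per node.
#' @return object of class `partition` with `assignment` and `n_communities`.
#' @export
partition <- function(assignment) {
  assignment <- as.integer(factor(assignment,
                                  levels = unique(assignment)))
  structure(list(assignment = assignment,
                 n_communities = max(assignment)),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d nodes in %d communities\n",
              length(x$assignment), x$n_communities))
  invisible(x)
}

partition_membership <- function(partition, n_nodes) {
  mem <- if (inherits(partition, "partition")) partition$assignment
         else as.integer(partition)
  if (length(mem) != n_nodes) {
    stop("partition must assign every node exactly once")
  }
  if (anyNA(mem)) stop("partition must assign every node exactly once")
  mem
}

# All set partitions of n elements as restricted-growth strings (first
# element always in community 1). Returns a list of integer vectors.
# Bell(10) = 115,975 -- enumeration is restricted to small graphs.
enumerate_partitions <- function(n) {
  if (n > 12L) stop("exact enumeration limited to n <= 12")
  out <- vector("list", 0L)
  rec <- function(prefix, maxid) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (id in seq_len(maxid + 1L)) {
      rec(c(prefix, id), max(maxid, id))
    }
  }
  rec(1L, 1L)
  out
}

#' Community detection by modularity maximization
#'
#' For graphs with at most `exact_below` nodes, enumerates all set partitions
#' and returns the global modularity optimum (ties broken by enumeration
#' order, deterministically). Larger graphs use seeded Louvain greedy
#' maximization with `n_restarts` restarts, keeping the partition with the
#' best Q as evaluated by [modularity_score()].
#'
#' @param graph a `binary_graph` with at least one edge.
#' @param seed integer seed for the Louvain restarts.
#' @param exact_below node-count threshold (inclusive) for the exact mode.
#' @param n_restarts Louvain restarts (default 10).
#' @return a `partition`.
#' @export
detect_communities <- function(graph, seed = 1L, exact_below = 10L,
                               n_restarts = 10L) {
  if (graph_edge_count(graph) == 0L) {
    stop("community detection undefined on an edgeless graph")
  }
  n <- graph$n_nodes
  e <- graph_edges(graph)
  m <- nrow(e)
  if (n <= exact_below) {
    parts <- enumerate_partitions(n)
    qs <- vapply(parts, .q_fast, numeric(1),
                 e1 = e[, 1], e2 = e[, 2], m = m, n_nodes = n)
    return(partition(parts[[which.max(qs)]]))
  }
  g <- as_igraph(graph)
  best <- NULL
  best_q <- -Inf
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      mem <- igraph::membership(igraph::cluster_louvain(g))
      q <- .q_fast(as.integer(mem), e[, 1], e[, 2], m, n)
      if (q > best_q) {
        best_q <- q
        best <- as.integer(mem)
      }
    }
  })
  partition(best)
}

#' Global efficiency (E)
#'
#' Mean inverse shortest-path length over all ordered node pairs:
#' the sum of 1/d(i, j) over i != j divided by n^2 - n, with unreachable
#' pairs contributing 0. Distances are unweighted shortest paths
#' (breadth-first) on the binary graph. E = 1 for a complete graph; E is in
#' [0, 1] always.
#'
#' @param graph a `binary_graph` with at least 2 nodes.
#' @return list-free numeric efficiency value. See also
#'   [compute_graph_metrics()] which records the inverse-distance sum.
#' @export
global_efficiency <- function(graph) {
  if (graph$n_nodes < 2L) stop("efficiency needs at least 2 nodes")
  inverse_distance_sum(graph) / (graph$n_nodes^2 - graph$n_nodes)
}

# sum over ordered pairs of inverse shortest-path length (0 if unreachable)
inverse_distance_sum <- function(graph) {
  d <- igraph::distances(as_igraph(graph), algorithm = "unweighted")
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv)
}

#' Graph metrics for one connectivity matrix
#'
#' Thresholds the matrix (strictly, on the r scale), detects communities,
#' and evaluates global modularity and efficiency. Errors when the threshold
#' leaves no edges.
#'
#' @param matrix a `conn_matrix` of kind `"pearson-r"`.
#' @param r_threshold threshold (default 0.5).
#' @param exact_below exact community detection for graphs at or below this
#'   many nodes.
#' @param seed seed for the community-detection restarts.
#' @return object of class `graph_metrics`: `modularity`, `efficiency`,
#'   `partition`, `n_edges`, `n_nodes`, `n_communities`,
#'   `shortest_path_inverse_sum`.
#' @export
compute_graph_metrics <- function(matrix, r_threshold = 0.5,
                                  exact_below = 10L, seed = 1L) {
  graph <- threshold_graph(matrix, r_threshold)
  if (graph_edge_count(graph) == 0L) {
    stop(sprintf("no edges above r = %g: graph metrics undefined",
                 r_threshold))
  }
  part <- detect_communities(graph, seed = seed, exact_below = exact_below)
  inv_sum <- inverse_distance_sum(graph)
  structure(
    list(modularity = modularity_score(graph, part),
         efficiency = inv_sum / (graph$n_nodes^2 - graph$n_nodes),
         partition = part,
         n_edges = graph_edge_count(graph),
         n_nodes = graph$n_nodes,
         n_communities = part$n_communities,
         shortest_path_inverse_sum = inv_sum),
    class = "graph_metrics"
  )
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat(sprintf("<graph_metrics> n = %d, edges = %d, Q = %.4f (%d communities), E = %.4f\n",
              x$n_nodes, x$n_edges, x$modularity, x$n_communities,
              x$efficiency))
  invisible(x)
}

#' Graph metrics for every subject of a cohort
#'
#' Runs the thresholded-graph analysis per subject on a list of connectivity
#' matrices and returns one row per subject.
#'
#' @param matrices named list of `conn_matrix` objects (names = subject ids).
#' @param r_threshold threshold (default 0.5).
#' @param seed seed for community detection.
#' @return tibble with columns `subject_id`, `modularity`, `efficiency`,
#'   `n_edges`, `n_communities`.
#' @export
cohort_graph_metrics <- function(matrices, r_threshold = 0.5, seed = 1L) {
  rows <- lapply(names(matrices), function(sid) {
    gm <- compute_graph_metrics(matrices[[sid]], r_threshold = r_threshold,
                                seed = seed)
    tibble::tibble(subject_id = sid, modularity = gm$modularity,
                   efficiency = gm$efficiency, n_edges = gm$n_edges,
                   n_communities = gm$n_communities)
  })
  dplyr::bind_rows(rows)
}
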