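# Shared fixtures and independent oracles for the suite.

# small config factory; defaults keep unit tests fast
tiny_config <- function(n_per_group = c("healthy-control" = 3, "no-RT" = 3,
                                        "focal" = 3, "WBRT-high-dose" = 3),
                        n_parcels = 24, n_modules = 3, seed = 101, ...) {
  cohort_config(n_per_group = n_per_group, n_parcels = n_parcels,
                n_modules = n_modules, seed = seed, ...)
}

# a parcel_ts of white noise
white_ts <- function(P = 6, T_ = 200, tr = 1, sd = 1, seed = 1) {
  withr::with_seed(seed, parcel_ts(matrix(rnorm(P * T_, sd = sd), P, T_),
                                   sampling_interval = tr))
}

# random binary graph with at least one edge
random_graph <- function(n, p = 0.4, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      adj <- matrix(runif(n * n) < p, n, n)
      adj <- adj & t(adj)
      diag(adj) <- FALSE
      if (sum(adj) > 0) break
    }
    binary_graph(adj)
  })
}

# --- independent modularity oracle: configuration-model matrix form,
#     Q = sum_{ij in same community} (A_ij - k_i k_j / 2m) / 2m
oracle_modularity <- function(graph, membership) {
  A <- graph$adjacency * 1
  m <- sum(A) / 2
  k <- rowSums(A)
  B <- A - outer(k, k) / (2 * m)
  sum(B[outer(membership, membership, "==")]) / (2 * m)
}

# --- independent set-partition enumerator (iterative lexicographic
#     successor on restricted growth strings, distinct from the package's
#     recursive generator)
oracle_partitions <- function(n) {
  a <- rep(1L, n)
  out <- list(a)
  repeat {
    # find rightmost position that can be incremented
    b <- c(1L, vapply(2:n, function(i) max(a[1:(i - 1)]), integer(1)))
    i <- n
    while (i >= 2L && a[i] > b[i]) i <- i - 1L
    if (i < 2L) break
    a[i] <- a[i] + 1L
    if (i < n) a[(i + 1L):n] <- 1L
    out[[length(out) + 1L]] <- a
  }
  out
}

# brute-force best modularity over all partitions
oracle_best_q <- function(graph) {
  parts <- oracle_partitions(graph$n_nodes)
  qs <- vapply(parts, function(p) oracle_modularity(graph, p), numeric(1))
  list(q = max(qs), partition = parts[[which.max(qs)]])
}

# adjusted Rand index between two labelings (mclust if present, else direct)
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# planted two-block stochastic graph
planted_two_block <- function(n = 20, p_within = 0.9, p_between = 0.05,
                              seed = 1) {
  withr::with_seed(seed, {
    block <- rep(1:2, each = n / 2)
    same <- outer(block, block, "==")
    u <- matrix(runif(n * n), n, n)
    u[lower.tri(u)] <- t(u)[lower.tri(u)]
    adj <- (same & u < p_within) | (!same & u < p_between)
    diag(adj) <- FALSE
    list(graph = binary_graph(adj), block = block)
  })
}
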