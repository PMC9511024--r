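#' Functional connectivity matrix
#'
#' Pairwise Pearson correlation of the parcel time courses: symmetric, unit
#' diagonal. Errors if any parcel has zero variance, naming the parcel.
#'
#' @param ts a [parcel_ts()] with at least 3 timepoints.
#' @return object of class `conn_matrix` with fields `values`, `kind`
#'   (`"pearson-r"`) and `parcel_labels`.
#' @export
correlation_matrix <- function(ts) {
  stopifnot(inherits(ts, "parcel_ts"))
  if (n_timepoints(ts) < 3L) stop("need at least 3 timepoints")
  v <- apply(ts$data, 1, stats::sd)
  if (any(v == 0)) {
    stop(sprintf("zero-variance parcel(s): %s",
                 paste(ts$parcel_labels[v == 0], collapse = ", ")))
  }
  r <- stats::cor(t(ts$data))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  conn_matrix(r, kind = "pearson-r", parcel_labels = ts$parcel_labels)
}

#' @rdname correlation_matrix
#' @param values square symmetric numeric matrix.
#' @param kind `"pearson-r"` or `"fisher-z"`.
#' @param parcel_labels parcel labels.
#' @export
conn_matrix <- function(values, kind = c("pearson-r", "fisher-z"),
                        parcel_labels = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("connectivity matrix must be square")
  if (!isSymmetric(unname(values), tol = 1e-8)) {
    stop("connectivity matrix must be symmetric")
  }
  if (kind == "pearson-r" && (min(values) < -1 - 1e-12 ||
                              max(values) > 1 + 1e-12)) {
    stop("pearson-r values must lie in [-1, 1]")
  }
  if (is.null(parcel_labels)) {
    parcel_labels <- sprintf("parcel_%03d", seq_len(nrow(values)))
  }
  dimnames(values) <- list(parcel_labels, parcel_labels)
  structure(list(values = values, kind = kind,
                 parcel_labels = as.character(parcel_labels)),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %d x %d (%s)\n", nrow(x$values), ncol(x$values),
              x$kind))
  invisible(x)
}

#' Fisher z-transform of a correlation matrix
#'
#' Elementwise `atanh` of the off-diagonal Pearson correlations; the diagonal
#' is set to 0 (its z would be infinite). Errors on any off-diagonal |r| = 1,
#' naming the parcel pair.
#'
#' @param matrix a `conn_matrix` of kind `"pearson-r"`.
#' @return a `conn_matrix` of kind `"fisher-z"`.
#' @export
fisher_z <- function(matrix) {
  stopifnot(inherits(matrix, "conn_matrix"))
  if (matrix$kind != "pearson-r") stop("fisher_z expects a pearson-r matrix")
  r <- matrix$values
  off <- abs(r) >= 1 & upper.tri(r)
  if (any(off)) {
    ij <- which(off, arr.ind = TRUE)[1, ]
    stop(sprintf("|r| = 1 between %s and %s: Fisher z is infinite",
                 matrix$parcel_labels[ij[1]], matrix$parcel_labels[ij[2]]))
  }
  z <- atanh(r)
  diag(z) <- 0
  conn_matrix(z, kind = "fisher-z", parcel_labels = matrix$parcel_labels)
}

#' Threshold a correlation matrix into a binary graph
#'
#' Undirected, unweighted graph with an edge (i, j) iff `r_ij > r_threshold`
#' strictly (so ties at exactly the threshold are excluded, reproducibly).
#' Self-pairs are never edges. Thresholding is on the Pearson-r scale.
#'
#' @param matrix a `conn_matrix` of kind `"pearson-r"`.
#' @param r_threshold correlation threshold (default 0.5, keeping positive
#'   moderate-to-strong connections only).
#' @return object of class `binary_graph` with fields `n_nodes`, `adjacency`
#'   (logical, symmetric, empty diagonal) and `labels`.
#' @export
threshold_graph <- function(matrix, r_threshold = 0.5) {
  stopifnot(inherits(matrix, "conn_matrix"))
  if (matrix$kind != "pearson-r") {
    stop("thresholding applies on the pearson-r scale")
  }
  adj <- matrix$values > r_threshold
  diag(adj) <- FALSE
  adj <- adj & t(adj)
  binary_graph(adj, labels = matrix$parcel_labels)
}

#' @rdname threshold_graph
#' @param adjacency logical symmetric adjacency matrix (diagonal ignored).
#' @param labels node labels.
#' @export
binary_graph <- function(adjacency, labels = NULL) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "logical"
  if (nrow(adjacency) != ncol(adjacency)) stop("adjacency must be square")
  diag(adjacency) <- FALSE
  if (!identical(unname(adjacency), unname(t(adjacency)))) {
    stop("adjacency must be symmetric (undirected graph)")
  }
  if (is.null(labels)) {
    labels <- sprintf("node_%03d", seq_len(nrow(adjacency)))
  }
  structure(list(n_nodes = nrow(adjacency), adjacency = adjacency,
                 labels = as.character(labels)),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d edges\n", x$n_nodes,
              graph_edge_count(x)))
  invisible(x)
}

#' Edge list and edge count of a binary graph
#' @param graph a `binary_graph`.
#' @return `graph_edges`: 2-column integer matrix of node pairs (i < j);
#'   `graph_edge_count`: number of edges.
#' @export
graph_edges <- function(graph) {
  idx <- which(graph$adjacency & upper.tri(graph$adjacency), arr.ind = TRUE)
  unname(idx[order(idx[, 1], idx[, 2]), , drop = FALSE])
}

#' @rdname graph_edges
#' @export
graph_edge_count <- function(graph) sum(graph$adjacency) / 2

# igraph view of a binary graph (for Louvain and BFS distances)
as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected")
}

#' Write a binary graph as an edge-list TSV
#' @param graph a `binary_graph`.
#' @param path output path.
#' @export
write_graph_edges <- function(graph, path) {
  e <- graph_edges(graph)
  df <- data.frame(from = graph$labels[e[, 1]], to = graph$labels[e[, 2]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Seed-based connectivity of a parcel set
#'
#' Correlation of the mean time course over the seed parcels with every
#' parcel's time course -- the parcel-level analog of seed-based voxelwise
#' maps, with the whole atlas-defined network as the seed.
#'
#' @param ts a [parcel_ts()].
#' @param seed_parcels non-empty set of parcel indices or labels.
#' @return named numeric vector of per-parcel correlations.
#' @export
seed_connectivity <- function(ts, seed_parcels) {
  stopifnot(inherits(ts, "parcel_ts"))
  if (length(seed_parcels) == 0L) stop("seed_parcels must be non-empty")
  if (is.character(seed_parcels)) {
    seed_parcels <- match(seed_parcels, ts$parcel_labels)
    if (anyNA(seed_parcels)) stop("unknown seed parcel label")
  }
  seed_course <- colMeans(ts$data[seed_parcels, , drop = FALSE])
  if (stats::sd(seed_course) == 0) stop("seed time course has zero variance")
  out <- as.numeric(stats::cor(seed_course, t(ts$data)))
  names(out) <- ts$parcel_labels
  out
}

#' Write / read a connectivity matrix as square CSV with labeled header
#' @param matrix a `conn_matrix`.
#' @param path file path.
#' @export
write_conn_matrix <- function(matrix, path) {
  df <- data.frame(parcel = matrix$parcel_labels, matrix$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_conn_matrix
#' @param kind matrix kind to assume on read.
#' @export
read_conn_matrix <- function(path, kind = "pearson-r") {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  conn_matrix(m, kind = kind, parcel_labels = df$parcel)
}
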