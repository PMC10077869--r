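#' KNN graph construction settings
#'
#' The number of neighbours \code{k} is the main sparsification control: each
#' region keeps edges to its \code{k} strongest neighbours and the directed
#' selections are merged into an undirected edge set, so degrees can exceed
#' \code{k} after symmetrisation. Neighbour strength is ranked by \code{|z|}
#' by default (connection strength regardless of sign); signed ranking is
#' available. Edge weights stored in the adjacency can be \code{abs_z}
#' (default, nonnegative — required for degree-normalised propagation),
#' \code{signed_z}, or \code{binary}.
#'
#' @param k Positive integer, \code{1 <= k <= R - 1}.
#' @param rank_by \code{"abs_weight"} or \code{"signed_weight"}.
#' @param weight_mode \code{"abs_z"}, \code{"signed_z"} or \code{"binary"}.
#' @return Object of class \code{graph_config}.
#' @export
graph_config <- function(k = 10L,
                         rank_by = c("abs_weight", "signed_weight"),
                         weight_mode = c("abs_z", "signed_z", "binary")) {
  rank_by <- match.arg(rank_by)
  weight_mode <- match.arg(weight_mode)
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L) stop("k must be a positive integer")
  structure(list(k = k, rank_by = rank_by, weight_mode = weight_mode),
            class = "graph_config")
}

#' Sparsify an FC matrix into a weighted undirected KNN graph
#'
#' For every node i the \code{cfg$k} nodes with the largest rank key
#' (\code{|z[i, j]|} under \code{abs_weight}) are selected; the undirected
#' edge set is the union of the directed selections. Ties in the rank key are
#' broken by the lower node index, so the construction is deterministic.
#' Node features are the rows of the FC matrix itself (each node carries its
#' full connectivity profile).
#'
#' @param fc An [fc_matrix] (or a plain symmetric matrix with zero diagonal).
#' @param cfg A [graph_config].
#' @param label Optional class label in \code{\{0, 1\}} attached to the graph.
#' @return Object of class \code{connectome_graph} with fields
#'   \code{subject_id}, \code{n_nodes}, \code{edges} (m x 2 integer matrix,
#'   i < j, 1-based), \code{adjacency} (dense symmetric, zero diagonal),
#'   \code{node_features} (R x R), \code{label}.
#' @export
build_knn_graph <- function(fc, cfg = graph_config(), label = NULL) {
  if (!inherits(fc, "fc_matrix")) fc <- fc_matrix(fc)
  z <- fc$z
  R <- nrow(z)
  if (cfg$k > R - 1L) stop("k must be at most R - 1 = ", R - 1L)

  key <- if (cfg$rank_by == "abs_weight") abs(z) else z
  # ties broken by lower node index: order() is stable, secondary key = index
  sel_i <- integer(0); sel_j <- integer(0)
  for (i in seq_len(R)) {
    cand <- setdiff(seq_len(R), i)
    ord <- cand[order(key[i, cand], -cand, decreasing = TRUE)]
    nb <- ord[seq_len(cfg$k)]
    sel_i <- c(sel_i, rep.int(i, cfg$k)); sel_j <- c(sel_j, nb)
  }
  lo <- pmin(sel_i, sel_j); hi <- pmax(sel_i, sel_j)
  keep <- !duplicated(cbind(lo, hi))
  edges <- cbind(i = lo[keep], j = hi[keep])
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]

  w <- switch(cfg$weight_mode,
              abs_z = abs(z[edges]),
              signed_z = z[edges],
              binary = rep(1, nrow(edges)))
  A <- matrix(0, R, R)
  A[edges] <- w
  A[edges[, c(2L, 1L), drop = FALSE]] <- w

  x <- z
  diag(x) <- 0
  connectome_graph(subject_id = fc$subject_id, edges = edges, adjacency = A,
                   node_features = x, label = label)
}

#' Construct / validate a connectome_graph
#'
#' @param subject_id Subject identifier.
#' @param edges m x 2 integer matrix of unordered node pairs (i < j, 1-based).
#' @param adjacency R x R weighted symmetric matrix, zero diagonal, nonzero
#'   exactly on the edge set.
#' @param node_features R x F numeric matrix (row i = node i's features).
#' @param label Optional class label in \code{\{0, 1\}}.
#' @param validate Check invariants.
#' @return Object of class \code{connectome_graph}.
#' @export
connectome_graph <- function(subject_id, edges, adjacency, node_features,
                             label = NULL, validate = TRUE) {
  edges <- matrix(as.integer(edges), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  if (validate) {
    R <- nrow(adjacency)
    if (ncol(adjacency) != R) stop("adjacency must be square")
    if (any(edges[, 1L] >= edges[, 2L])) stop("edges must satisfy i < j")
    if (any(edges < 1L) || any(edges > R)) stop("edge index out of range")
    if (any(diag(adjacency) != 0)) stop("self-loops are not allowed")
    if (!isTRUE(all.equal(adjacency, t(adjacency), tolerance = 0)))
      stop("adjacency must be symmetric")
    nz <- which(adjacency != 0 & upper.tri(adjacency), arr.ind = TRUE)
    nz <- nz[order(nz[, 1L], nz[, 2L]), , drop = FALSE]
    if (!identical(unname(edges), unname(cbind(nz[, 1L], nz[, 2L]))))
      stop("adjacency support must equal the edge set")
    if (nrow(node_features) != R) stop("node_features must have one row per node")
    if (!is.null(label) && !label %in% c(0, 1)) stop("label must be 0 or 1")
  }
  structure(list(subject_id = as.character(subject_id),
                 n_nodes = nrow(adjacency),
                 edges = edges,
                 adjacency = adjacency,
                 node_features = node_features,
                 label = if (is.null(label)) NULL else as.integer(label)),
            class = "connectome_graph")
}

#' @export
print.connectome_graph <- function(x, ...) {
  cat("<connectome_graph> subject", x$subject_id, "-", x$n_nodes, "nodes,",
      nrow(x$edges), "undirected edges")
  if (!is.null(x$label)) cat(", label", x$label)
  cat("\n")
  invisible(x)
}

#' Node degrees of a connectome graph
#' @param g A [connectome_graph].
#' @return Integer vector of node degrees.
#' @export
graph_degrees <- function(g) {
  tabulate(c(g$edges[, 1L], g$edges[, 2L]), nbins = g$n_nodes)
}

#' Export a graph as a deterministic edge list
#'
#' Rows are sorted by (i, j) with i < j; indices are 0-based to match the
#' on-disk edge-list format. Round-trips exactly with
#' [graph_from_edge_list()].
#'
#' @param g A [connectome_graph].
#' @return data.frame with columns \code{i}, \code{j}, \code{weight}.
#' @export
graph_to_edge_list <- function(g) {
  stopifnot(inherits(g, "connectome_graph"))
  data.frame(i = g$edges[, 1L] - 1L, j = g$edges[, 2L] - 1L,
             weight = g$adjacency[g$edges])
}

#' Rebuild a connectome graph from an edge list
#'
#' @param el data.frame with 0-based columns \code{i}, \code{j},
#'   \code{weight}.
#' @param n_nodes Number of nodes R.
#' @param node_features R x F matrix (defaults to the reconstructed
#'   adjacency, which matches the FC-derived convention only for
#'   \code{weight_mode = "signed_z"}; pass features explicitly otherwise).
#' @param subject_id,label See [connectome_graph()].
#' @return A [connectome_graph] whose adjacency reproduces the edge list.
#' @export
graph_from_edge_list <- function(el, n_nodes, node_features = NULL,
                                 subject_id = "subject", label = NULL) {
  i <- as.integer(el$i) + 1L; j <- as.integer(el$j) + 1L
  if (any(i >= j)) stop("edge list must have i < j")
  A <- matrix(0, n_nodes, n_nodes)
  A[cbind(i, j)] <- el$weight
  A[cbind(j, i)] <- el$weight
  if (is.null(node_features)) node_features <- A
  connectome_graph(subject_id = subject_id, edges = cbind(i, j), adjacency = A,
                   node_features = node_features, label = label)
}

#' Write / read the TSV edge-list format
#'
#' Three tab-separated columns \code{i}, \code{j}, \code{weight} with 0-based
#' node indices and a header row.
#'
#' @param g A [connectome_graph].
#' @param path Output file.
#' @return \code{path} (write) or a data.frame (read).
#' @export
write_edge_list <- function(g, path) {
  utils::write.table(graph_to_edge_list(g), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
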