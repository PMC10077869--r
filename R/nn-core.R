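# Internal neural-network primitives: activations, initialisation, Adam,
# softmax cross-entropy, dropout, and mini-batch assembly of graph batches.
# Everything is plain dense/sparse matrix algebra so that training is
# bit-reproducible given the RNG seed.

.act <- function(x, activation) {
  switch(activation,
         none = x,
         relu = pmax(x, 0),
         elu  = pmax(x, 0) + expm1(pmin(x, 0)))
}

# derivative of the activation expressed through its OUTPUT value o
.act_grad_from_output <- function(o, activation) {
  switch(activation,
         none = 1,
         relu = (o > 0) * 1,
         elu  = (o > 0) + (o <= 0) * (o + 1))
}

# column-bias add without sweep()'s overhead (column-major recycling)
.add_bias <- function(x, b) x + rep(b, each = nrow(x))

.glorot <- function(fan_in, fan_out, nrow = fan_in, ncol = fan_out) {
  a <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -a, a), nrow, ncol)
}

.dropout_mask <- function(n, p) {
  if (p <= 0) return(NULL)
  (stats::runif(n) >= p) / (1 - p)
}

.softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy over graphs; labels in {0,1} -> column y + 1
.ce_loss_grad <- function(logits, labels) {
  p <- .softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  d <- p
  d[idx] <- d[idx] - 1
  list(loss = loss, dlogits = d / n, probs = p)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- per-graph structural caches -------------------------------------------

# GCN propagation operator S = D^{-1/2} (A + I) D^{-1/2}, dense
.gcn_operator <- function(A) {
  if (any(A < 0)) stop("GCN propagation requires a nonnegative adjacency; ",
                       "use weight_mode 'abs_z' or 'binary'")
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  At * tcrossprod(dinv)
}

# row-normalised binary neighbour operator (mean aggregation, no self-loop);
# isolated nodes get an all-zero row
.mean_operator <- function(edges, n_nodes) {
  if (nrow(edges) == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n_nodes, n_nodes)))
  }
  i <- c(edges[, 1L], edges[, 2L])
  j <- c(edges[, 2L], edges[, 1L])
  deg <- tabulate(i, nbins = n_nodes)
  Matrix::sparseMatrix(i = i, j = j, x = 1 / deg[i], dims = c(n_nodes, n_nodes))
}

# directed edge arrays incl. self-loops for attention (receiver, sender)
.attention_edges <- function(edges, n_nodes) {
  list(recv = c(edges[, 1L], edges[, 2L], seq_len(n_nodes)),
       send = c(edges[, 2L], edges[, 1L], seq_len(n_nodes)))
}

.graph_struct <- function(g, arch) {
  switch(arch,
         gcn  = list(S = .gcn_operator(g$adjacency)),
         sage = list(M = as.matrix(.mean_operator(g$edges, g$n_nodes))),
         gat  = .attention_edges(g$edges, g$n_nodes))
}

# ---- batching ---------------------------------------------------------------

# Assemble a list of graphs (with optional precomputed per-graph structures)
# into one block-diagonal batch for full vectorised message passing.
build_graph_batch <- function(graphs, arch, labels = NULL, structs = NULL) {
  if (length(graphs) == 0L) stop("empty batch")
  n_nodes <- vapply(graphs, function(g) g$n_nodes, integer(1))
  if (length(unique(vapply(graphs, function(g) ncol(g$node_features), integer(1)))) != 1L)
    stop("all graphs in a batch must share the feature dimension")
  X <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  offs <- cumsum(c(0L, n_nodes[-length(n_nodes)]))
  graph_id <- rep(seq_along(graphs), n_nodes)
  N <- sum(n_nodes)
  G <- length(graphs)
  pool <- Matrix::sparseMatrix(i = graph_id, j = seq_len(N),
                               x = 1 / n_nodes[graph_id], dims = c(G, N))
  if (is.null(structs)) structs <- lapply(graphs, .graph_struct, arch = arch)
  uniform <- length(unique(n_nodes)) == 1L
  b <- list(X = X, graph_id = graph_id, n_graphs = G, n_nodes = n_nodes,
            labels = labels, pool = pool, pool_t = Matrix::t(pool),
            uniform = uniform)
  if (arch == "gcn") {
    b$S <- Matrix::bdiag(lapply(structs, `[[`, "S"))
    if (uniform)
      b$op_arr <- array(unlist(lapply(structs, `[[`, "S")),
                        dim = c(n_nodes[1L], n_nodes[1L], G))
  } else if (arch == "sage") {
    b$M <- Matrix::bdiag(lapply(structs, `[[`, "M"))
    b$Mt <- Matrix::t(b$M)
    if (uniform)
      b$op_arr <- array(unlist(lapply(structs, `[[`, "M")),
                        dim = c(n_nodes[1L], n_nodes[1L], G))
  } else if (arch == "gat") {
    b$recv <- unlist(lapply(seq_along(structs),
                            function(k) structs[[k]]$recv + offs[k]))
    b$send <- unlist(lapply(seq_along(structs),
                            function(k) structs[[k]]$send + offs[k]))
  }
  b
}
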