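# The three message-passing operators. Exported functions give the
# single-layer functional form (used directly in tests and examples); the
# internal *_fwd / *_bwd pairs additionally return/consume caches for
# backpropagation and are what the training loop uses.

# ---- GCN --------------------------------------------------------------------

#' Graph-convolution layer
#'
#' Spectral-style propagation \eqn{act(D^{-1/2} (A + I) D^{-1/2} X W)}:
#' self-loops are added to the weighted adjacency, rows/columns are
#' degree-normalised, features are propagated and linearly transformed.
#'
#' @param x N x F node-feature matrix.
#' @param adjacency N x N symmetric nonnegative matrix with zero diagonal.
#' @param weights F x F' transform (default identity).
#' @param bias Optional length-F' bias.
#' @param activation \code{"none"}, \code{"relu"} or \code{"elu"}.
#' @return N x F' matrix.
#' @export
gcn_layer <- function(x, adjacency, weights = NULL, bias = NULL,
                      activation = c("none", "relu", "elu")) {
  activation <- match.arg(activation)
  x <- as.matrix(x)
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency) || nrow(adjacency) != nrow(x))
    stop("dimension mismatch between features and adjacency")
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) stop("adjacency must be symmetric")
  if (is.null(weights)) weights <- diag(ncol(x))
  if (ncol(x) != nrow(weights)) stop("dimension mismatch between features and weights")
  S <- .gcn_operator(adjacency)
  out <- .gcn_layer_fwd(S, x, weights,
                        if (is.null(bias)) rep(0, ncol(weights)) else bias,
                        activation)$out
  out
}

.gcn_layer_fwd <- function(S, X, W, b, activation) {
  out <- .act(.add_bias(as.matrix(S %*% (X %*% W)), b), activation)
  list(out = out, cache = list(X = X, out = out))
}

.gcn_layer_bwd <- function(S, cache, W, dout, activation) {
  dZ <- dout * .act_grad_from_output(cache$out, activation)
  SdZ <- as.matrix(S %*% dZ)                    # S is symmetric
  list(dX = tcrossprod(SdZ, W),
       dW = crossprod(cache$X, SdZ),
       db = colSums(dZ))
}

# ---- GraphSAGE --------------------------------------------------------------

#' Neighbourhood-sampling aggregation (GraphSAGE) layer
#'
#' \eqn{act(X W_{self} + mean_{j \in N(i)}(x_j) W_{neigh} + b)}. The mean
#' over an empty neighbourhood is the zero vector, so isolated nodes depend
#' only on their own transform.
#'
#' @param x N x F node-feature matrix.
#' @param edges m x 2 matrix of undirected edges (1-based, i < j).
#' @param w_self,w_neigh F x F' transforms (default identity).
#' @param bias Optional length-F' bias.
#' @param activation \code{"none"}, \code{"relu"} or \code{"elu"}.
#' @return N x F' matrix.
#' @export
sage_layer <- function(x, edges, w_self = NULL, w_neigh = NULL, bias = NULL,
                       activation = c("none", "relu", "elu")) {
  activation <- match.arg(activation)
  x <- as.matrix(x)
  if (is.null(w_self)) w_self <- diag(ncol(x))
  if (is.null(w_neigh)) w_neigh <- diag(ncol(x))
  M <- .mean_operator(matrix(as.integer(edges), ncol = 2L), nrow(x))
  .sage_layer_fwd(M, x, w_self, w_neigh,
                  if (is.null(bias)) rep(0, ncol(w_self)) else bias,
                  activation)$out
}

.sage_layer_fwd <- function(M, X, Ws, Wn, b, activation) {
  MX <- as.matrix(M %*% X)
  out <- .act(.add_bias(X %*% Ws + MX %*% Wn, b), activation)
  list(out = out, cache = list(X = X, MX = MX, out = out))
}

.sage_layer_bwd <- function(Mt, cache, Ws, Wn, dout, activation) {
  dZ <- dout * .act_grad_from_output(cache$out, activation)
  list(dX = tcrossprod(dZ, Ws) + as.matrix(Mt %*% tcrossprod(dZ, Wn)),
       dWs = crossprod(cache$X, dZ),
       dWn = crossprod(cache$MX, dZ),
       db = colSums(dZ))
}

# ---- GAT --------------------------------------------------------------------

#' Graph-attention layer
#'
#' Multi-head attention over each node's neighbourhood plus itself
#' (self-attention is always enabled, so isolated nodes are well defined).
#' Per head, scores \eqn{e_{ij} = LeakyReLU(a_{src} \cdot W x_i + a_{dst}
#' \cdot W x_j)} are softmax-normalised over \eqn{j \in N(i) \cup \{i\}} and
#' the update is the attention-weighted sum of transformed sender features.
#' Heads are concatenated (hidden layers) or averaged (output layer).
#'
#' @param x N x F node-feature matrix.
#' @param edges m x 2 matrix of undirected edges (1-based, i < j); may have
#'   zero rows.
#' @param heads Number of attention heads H.
#' @param out_dim Features per head F' (default \code{ncol(x)}).
#' @param weights Optional list with \code{W} (F x H*F'), \code{a_src},
#'   \code{a_dst} (each F' x H). Random Glorot initialisation when missing
#'   (uses the current RNG state).
#' @param combine \code{"concat"} (N x H*F') or \code{"mean"} (N x F').
#' @param activation Applied after combining heads.
#' @param return_attention Attach the edge attention matrix (one column per
#'   head, rows ordered as (edges forward, edges reverse, self-loops)) as
#'   attribute \code{"alpha"} together with \code{"recv"}/\code{"send"}.
#' @return Node-feature matrix; see \code{combine}.
#' @export
gat_layer <- function(x, edges, heads = 1L, out_dim = NULL, weights = NULL,
                      combine = c("concat", "mean"),
                      activation = c("none", "relu", "elu"),
                      return_attention = FALSE) {
  combine <- match.arg(combine)
  activation <- match.arg(activation)
  x <- as.matrix(x)
  if (is.null(out_dim)) out_dim <- ncol(x)
  if (is.null(weights)) {
    weights <- list(W = .glorot(ncol(x), heads * out_dim),
                    a_src = .glorot(out_dim, 1L, nrow = out_dim, ncol = heads),
                    a_dst = .glorot(out_dim, 1L, nrow = out_dim, ncol = heads))
  }
  stopifnot(ncol(weights$W) == heads * out_dim,
            nrow(weights$a_src) == out_dim, ncol(weights$a_src) == heads)
  ae <- .attention_edges(matrix(as.integer(edges), ncol = 2L), nrow(x))
  fw <- .gat_layer_fwd(x, ae$recv, ae$send, weights$W, weights$a_src,
                       weights$a_dst, combine, activation)
  out <- fw$out
  if (return_attention) {
    attr(out, "alpha") <- fw$cache$alpha
    attr(out, "recv") <- ae$recv
    attr(out, "send") <- ae$send
  }
  out
}

.act_code <- function(activation) {
  match(activation, c("none", "relu", "elu")) - 1L
}

# forward/backward delegate to the compiled edge kernels (src/gat_ops.cpp)
.gat_layer_fwd <- function(X, recv, send, W, a1, a2, combine, activation) {
  recv <- as.integer(recv); send <- as.integer(send)
  fw <- .gat_fwd_cpp(X, W, a1, a2, recv, send, combine == "mean",
                     .act_code(activation))
  list(out = fw$out,
       cache = list(X = X, HA = fw$HA, g = fw$g, alpha = fw$alpha,
                    out = fw$out, recv = recv, send = send,
                    Fh = nrow(a1), H = ncol(a1), combine = combine))
}

.gat_layer_bwd <- function(cache, W, a1, a2, activation, dout) {
  .gat_bwd_cpp(cache$X, W, a1, a2, cache$recv, cache$send, cache$HA,
               cache$g, cache$alpha, cache$out, dout,
               cache$combine == "mean", .act_code(activation))
}
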