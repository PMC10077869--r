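#' Base graph-classifier configuration
#'
#' Architecture hyperparameters for one base model. Defaults follow the
#' study design: GAT uses 3 attention layers with eLU activation, 8 heads
#' and dropout 0.5; GCN uses ReLU and dropout 0.3; GraphSAGE uses K = 3
#' layers of 64 hidden units, ReLU and dropout 0.3. Depth and width not
#' pinned by an architecture's definition default to 3 layers x 64 hidden
#' units for parity across bases.
#'
#' @param arch \code{"gcn"}, \code{"gat"} or \code{"sage"}.
#' @param n_layers Number of message-passing layers.
#' @param hidden_dim Hidden width (for GAT: total width = heads x per-head
#'   features on hidden layers, so \code{heads} must divide it).
#' @param heads Attention heads (GAT only).
#' @param dropout Dropout rate in \code{[0, 1)}, applied to each layer's
#'   input features and to the pooled graph embedding during training.
#' @param activation \code{"relu"} or \code{"elu"}.
#' @param readout Graph-level readout; only \code{"global_mean"} is defined.
#' @return Object of class \code{base_model_config}.
#' @export
base_model_config <- function(arch = c("gcn", "gat", "sage"),
                              n_layers = 3L,
                              hidden_dim = 64L,
                              heads = 8L,
                              dropout = NULL,
                              activation = NULL,
                              readout = "global_mean") {
  arch <- match.arg(arch)
  if (is.null(dropout)) dropout <- if (arch == "gat") 0.5 else 0.3
  if (is.null(activation)) activation <- if (arch == "gat") "elu" else "relu"
  activation <- match.arg(activation, c("relu", "elu"))
  readout <- match.arg(readout, "global_mean")
  n_layers <- as.integer(n_layers); hidden_dim <- as.integer(hidden_dim)
  heads <- as.integer(heads)
  if (n_layers < 1L || hidden_dim < 1L) stop("n_layers and hidden_dim must be positive")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (arch == "gat") {
    if (heads < 1L) stop("heads must be positive")
    if (hidden_dim %% heads != 0L)
      stop("hidden_dim must be divisible by heads for concatenated GAT layers")
  }
  structure(list(arch = arch, n_layers = n_layers, hidden_dim = hidden_dim,
                 heads = if (arch == "gat") heads else NULL,
                 dropout = dropout, activation = activation, readout = readout),
            class = "base_model_config")
}

#' Optimizer configuration
#'
#' Adam with the study's learning rate 0.01 and weight decay 5e-4
#' (L2 penalty added to the gradient), minimising cross-entropy.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay L2 coefficient.
#' @param epochs Training epochs.
#' @param batch_size Graphs per mini-batch.
#' @param seed Integer seed controlling initialisation, batching and dropout.
#' @return Object of class \code{optimizer_config}.
#' @export
optimizer_config <- function(learning_rate = 0.01, weight_decay = 5e-4,
                             epochs = 150L, batch_size = 32L, seed = 1L) {
  stopifnot(learning_rate > 0, weight_decay >= 0, epochs >= 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "optimizer_config")
}

# evaluate expr under a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# ---- parameter initialisation ----------------------------------------------

# GAT layout: hidden layers concatenate heads (width = hidden_dim); the last
# attention layer keeps hidden_dim/heads features per head and averages them.
.gat_dims <- function(cfg, n_features) {
  Fh <- cfg$hidden_dim %/% cfg$heads
  ins <- c(n_features, rep(cfg$hidden_dim, cfg$n_layers - 1L))
  list(Fh = Fh, ins = ins,
       out_dim = if (cfg$n_layers > 1L) Fh else Fh)  # embedding width after averaging
}

.init_params <- function(cfg, n_features, n_classes = 2L) {
  L <- cfg$n_layers; h <- cfg$hidden_dim
  p <- list()
  if (cfg$arch == "gcn") {
    ins <- c(n_features, rep(h, L - 1L))
    for (l in seq_len(L)) {
      p[[paste0("W", l)]] <- .glorot(ins[l], h)
      p[[paste0("b", l)]] <- rep(0, h)
    }
    emb <- h
  } else if (cfg$arch == "sage") {
    ins <- c(n_features, rep(h, L - 1L))
    for (l in seq_len(L)) {
      p[[paste0("Ws", l)]] <- .glorot(ins[l], h)
      p[[paste0("Wn", l)]] <- .glorot(ins[l], h)
      p[[paste0("b", l)]] <- rep(0, h)
    }
    emb <- h
  } else {
    gd <- .gat_dims(cfg, n_features)
    for (l in seq_len(L)) {
      p[[paste0("W", l)]] <- .glorot(gd$ins[l], cfg$heads * gd$Fh)
      p[[paste0("a1_", l)]] <- .glorot(gd$Fh, 1L, nrow = gd$Fh, ncol = cfg$heads)
      p[[paste0("a2_", l)]] <- .glorot(gd$Fh, 1L, nrow = gd$Fh, ncol = cfg$heads)
    }
    emb <- gd$Fh   # final attention layer averages heads
  }
  p$Wfc <- .glorot(emb, n_classes)
  p$bfc <- rep(0, n_classes)
  p
}

# ---- full model forward / backward -----------------------------------------

.model_forward <- function(params, cfg, batch, training = FALSE) {
  L <- cfg$n_layers
  X <- batch$X
  caches <- vector("list", L)
  masks <- vector("list", L + 1L)
  for (l in seq_len(L)) {
    if (training && cfg$dropout > 0) {
      masks[[l]] <- .dropout_mask(length(X), cfg$dropout)
      X <- X * masks[[l]]
    }
    if (cfg$arch == "gcn") {
      fw <- .gcn_layer_fwd(batch$S, X, params[[paste0("W", l)]],
                           params[[paste0("b", l)]], cfg$activation)
    } else if (cfg$arch == "sage") {
      fw <- .sage_layer_fwd(batch$M, X, params[[paste0("Ws", l)]],
                            params[[paste0("Wn", l)]], params[[paste0("b", l)]],
                            cfg$activation)
    } else {
      fw <- .gat_layer_fwd(X, batch$recv, batch$send, params[[paste0("W", l)]],
                           params[[paste0("a1_", l)]], params[[paste0("a2_", l)]],
                           combine = if (l == L) "mean" else "concat",
                           activation = cfg$activation)
    }
    caches[[l]] <- fw$cache
    X <- fw$out
  }
  pooled <- as.matrix(batch$pool %*% X)
  pooled_in <- pooled
  if (training && cfg$dropout > 0) {
    masks[[L + 1L]] <- .dropout_mask(length(pooled), cfg$dropout)
    pooled_in <- pooled * masks[[L + 1L]]
  }
  logits <- .add_bias(pooled_in %*% params$Wfc, params$bfc)
  list(logits = logits,
       cache = list(layers = caches, masks = masks, pooled_in = pooled_in))
}

.model_backward <- function(params, cfg, batch, cache, dlogits) {
  L <- cfg$n_layers
  g <- list(Wfc = crossprod(cache$pooled_in, dlogits),
            bfc = colSums(dlogits))
  dpooled <- tcrossprod(dlogits, params$Wfc)
  if (!is.null(cache$masks[[L + 1L]])) dpooled <- dpooled * cache$masks[[L + 1L]]
  dX <- as.matrix(batch$pool_t %*% dpooled)
  for (l in rev(seq_len(L))) {
    if (cfg$arch == "gcn") {
      bw <- .gcn_layer_bwd(batch$S, cache$layers[[l]], params[[paste0("W", l)]],
                           dX, cfg$activation)
      g[[paste0("W", l)]] <- bw$dW; g[[paste0("b", l)]] <- bw$db
    } else if (cfg$arch == "sage") {
      bw <- .sage_layer_bwd(batch$Mt, cache$layers[[l]], params[[paste0("Ws", l)]],
                            params[[paste0("Wn", l)]], dX, cfg$activation)
      g[[paste0("Ws", l)]] <- bw$dWs; g[[paste0("Wn", l)]] <- bw$dWn
      g[[paste0("b", l)]] <- bw$db
    } else {
      bw <- .gat_layer_bwd(cache$layers[[l]], params[[paste0("W", l)]],
                           params[[paste0("a1_", l)]], params[[paste0("a2_", l)]],
                           cfg$activation, dX)
      g[[paste0("W", l)]] <- bw$dW
      g[[paste0("a1_", l)]] <- bw$da1; g[[paste0("a2_", l)]] <- bw$da2
    }
    dX <- bw$dX
    if (!is.null(cache$masks[[l]])) dX <- dX * cache$masks[[l]]
  }
  g
}

# ---- training ---------------------------------------------------------------

.check_training_set <- function(graphs, labels) {
  if (length(graphs) < 2L) stop("need at least 2 training graphs")
  if (length(labels) != length(graphs)) stop("labels must align with graphs")
  if (any(!labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  if (length(unique(labels)) < 2L)
    stop("training set contains a single class; both classes are required")
}

.make_batches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

# ---- compiled fast path -----------------------------------------------------
# .model_step_cpp runs the whole forward/loss/backward for one mini-batch in
# C++; the R .model_forward/.model_backward pair above implement the same
# computation and serve as the independent reference (and the path used by
# the non-default joint fine-tuning).

.arch_code <- function(arch) match(arch, c("gcn", "sage", "gat")) - 1L

.step_args <- function(cfg, params) {
  L <- cfg$n_layers
  empty <- vector("list", L)
  if (cfg$arch == "gcn") {
    list(Wl = lapply(seq_len(L), function(l) params[[paste0("W", l)]]),
         bl = lapply(seq_len(L), function(l) params[[paste0("b", l)]]),
         Wl2 = empty, a1l = empty, a2l = empty)
  } else if (cfg$arch == "sage") {
    list(Wl = lapply(seq_len(L), function(l) params[[paste0("Ws", l)]]),
         bl = lapply(seq_len(L), function(l) params[[paste0("b", l)]]),
         Wl2 = lapply(seq_len(L), function(l) params[[paste0("Wn", l)]]),
         a1l = empty, a2l = empty)
  } else {
    list(Wl = lapply(seq_len(L), function(l) params[[paste0("W", l)]]),
         bl = empty,
         Wl2 = empty,
         a1l = lapply(seq_len(L), function(l) params[[paste0("a1_", l)]]),
         a2l = lapply(seq_len(L), function(l) params[[paste0("a2_", l)]]))
  }
}

.unpack_grads <- function(cfg, gr) {
  L <- cfg$n_layers
  out <- list(Wfc = gr$Wfc, bfc = as.numeric(gr$bfc))
  for (l in seq_len(L)) {
    if (cfg$arch == "gcn") {
      out[[paste0("W", l)]] <- gr$W[[l]]
      out[[paste0("b", l)]] <- as.numeric(gr$b[[l]])
    } else if (cfg$arch == "sage") {
      out[[paste0("Ws", l)]] <- gr$W[[l]]
      out[[paste0("Wn", l)]] <- gr$W2[[l]]
      out[[paste0("b", l)]] <- as.numeric(gr$b[[l]])
    } else {
      out[[paste0("W", l)]] <- gr$W[[l]]
      out[[paste0("a1_", l)]] <- gr$a1[[l]]
      out[[paste0("a2_", l)]] <- gr$a2[[l]]
    }
  }
  out
}

# one training/evaluation step; flat gradient list on return. Falls back to
# the R reference path when the batch mixes graph sizes (the compiled kernel
# assumes a uniform node count, which all pipeline cohorts satisfy).
.model_step <- function(params, cfg, batch, training, step_seed) {
  if (!isTRUE(batch$uniform)) {
    fw <- .model_forward(params, cfg, batch, training = training)
    if (!training) return(list(logits = fw$logits))
    lg <- .ce_loss_grad(fw$logits, batch$labels)
    grads <- .model_backward(params, cfg, batch, fw$cache, lg$dlogits)
    return(list(logits = fw$logits, loss = lg$loss, grads = grads))
  }
  sa <- .step_args(cfg, params)
  op <- if (cfg$arch == "gat") array(0, c(1, 1, 1)) else batch$op_arr
  recv <- if (cfg$arch == "gat") batch$recv else integer(0)
  send <- if (cfg$arch == "gat") batch$send else integer(0)
  y <- if (is.null(batch$labels)) integer(batch$n_graphs) else batch$labels
  res <- .model_step_cpp(.arch_code(cfg$arch), batch$X, op,
                         as.integer(recv), as.integer(send),
                         batch$n_nodes[1L], batch$n_graphs,
                         sa$Wl, sa$bl, sa$Wl2, sa$a1l, sa$a2l,
                         params$Wfc, params$bfc, as.integer(y),
                         cfg$dropout, .act_code(cfg$activation), training,
                         step_seed)
  if (training) res$grads <- .unpack_grads(cfg, res$grads)
  res
}

.train_model <- function(graphs, labels, cfg, opt, structs = NULL,
                         params = NULL) {
  labels <- as.integer(labels)
  .check_training_set(graphs, labels)
  n_features <- ncol(graphs[[1L]]$node_features)
  if (is.null(structs)) structs <- lapply(graphs, .graph_struct, arch = cfg$arch)
  .with_seed(opt$seed, {
    if (is.null(params)) params <- .init_params(cfg, n_features)
    state <- adam_init(params)
    groups <- .make_batches(length(graphs), opt$batch_size)
    batches <- lapply(groups, function(ix)
      build_graph_batch(graphs[ix], cfg$arch, labels = labels[ix],
                        structs = structs[ix]))
    loss_history <- numeric(opt$epochs)
    for (epoch in seq_len(opt$epochs)) {
      losses <- numeric(length(batches))
      for (b in sample.int(length(batches))) {
        step_seed <- floor(stats::runif(1) * 2^31)   # per-step dropout stream
        res <- .model_step(params, cfg, batches[[b]], training = TRUE,
                           step_seed = step_seed)
        losses[b] <- res$loss
        upd <- adam_step(params, res$grads, state, opt$learning_rate, opt$weight_decay)
        params <- upd$params; state <- upd$state
      }
      loss_history[epoch] <- mean(losses)
    }
    list(params = params, loss_history = loss_history, n_features = n_features)
  })
}

# deterministic evaluation-mode logits, chunked to bound batch size
.model_logits <- function(params, cfg, graphs, structs = NULL, chunk = 256L) {
  if (is.null(structs)) structs <- lapply(graphs, .graph_struct, arch = cfg$arch)
  out <- matrix(0, length(graphs), length(params$bfc))
  for (ix in split(seq_along(graphs), ceiling(seq_along(graphs) / chunk))) {
    batch <- build_graph_batch(graphs[ix], cfg$arch, structs = structs[ix])
    out[ix, ] <- .model_step(params, cfg, batch, training = FALSE,
                             step_seed = 0)$logits
  }
  out
}

# ---- user-facing fit --------------------------------------------------------

#' Fit a single graph neural network classifier
#'
#' Trains one base model (GCN, GAT or GraphSAGE) on labelled connectome
#' graphs by mini-batch Adam on the cross-entropy loss. Training is fully
#' reproducible given \code{optimizer$seed}.
#'
#' @param x List of [connectome_graph] objects, or an \code{fc_cohort}.
#' @param labels Integer vector of class labels in \code{\{0, 1\}} (taken
#'   from the cohort when \code{x} is an \code{fc_cohort}).
#' @param config A [base_model_config()].
#' @param optimizer An [optimizer_config()].
#' @return Object of class \code{gnn_base} with elements \code{params},
#'   \code{config}, \code{optimizer}, \code{loss_history}.
#' @seealso [predict.gnn_base()], [gnn_ensemble()]
#' @export
gnn_base <- function(x, labels = NULL, config = base_model_config("gcn"),
                     optimizer = optimizer_config()) {
  if (inherits(x, "fc_cohort")) { labels <- x$labels; x <- x$graphs }
  fit <- .train_model(x, labels, config, optimizer)
  structure(list(arch = config$arch, params = fit$params, config = config,
                 optimizer = optimizer, loss_history = fit$loss_history,
                 n_features = fit$n_features, classes = c(0L, 1L),
                 call = match.call()),
            class = "gnn_base")
}

#' @export
print.gnn_base <- function(x, ...) {
  cat("<gnn_base>", toupper(x$arch), "classifier -", x$config$n_layers,
      "layers, hidden", x$config$hidden_dim)
  if (x$arch == "gat") cat(",", x$config$heads, "heads")
  cat("\n  trained", x$optimizer$epochs, "epochs; final loss",
      sprintf("%.4f", utils::tail(x$loss_history, 1L)), "\n")
  invisible(x)
}

#' @export
summary.gnn_base <- function(object, ...) {
  cat("Graph neural network base classifier\n")
  cat("  architecture :", toupper(object$arch), "\n")
  cat("  layers       :", object$config$n_layers, "\n")
  cat("  hidden width :", object$config$hidden_dim, "\n")
  if (object$arch == "gat") cat("  heads        :", object$config$heads, "\n")
  cat("  dropout      :", object$config$dropout, "\n")
  cat("  activation   :", object$config$activation, "\n")
  cat("  optimizer    : Adam lr", object$optimizer$learning_rate,
      "wd", object$optimizer$weight_decay, "\n")
  cat("  epochs       :", object$optimizer$epochs,
      " (loss", sprintf("%.4f -> %.4f", object$loss_history[1L],
                        utils::tail(object$loss_history, 1L)), ")\n")
  cat("  parameters   :", sum(vapply(object$params, length, integer(1))), "\n")
  invisible(object)
}

#' Predict from a fitted base classifier
#'
#' Evaluation mode (dropout disabled), hence deterministic: two calls give
#' identical output.
#'
#' @param object A fitted [gnn_base()].
#' @param newdata List of [connectome_graph] or an \code{fc_cohort}.
#' @param type \code{"prob"} (class-probability matrix, rows sum to 1),
#'   \code{"class"} (hard labels; ties go to class 0) or \code{"logits"}.
#' @param ... Unused.
#' @return Matrix (prob/logits) or integer vector (class).
#' @export
predict.gnn_base <- function(object, newdata, type = c("prob", "class", "logits"),
                             ...) {
  type <- match.arg(type)
  if (inherits(newdata, "fc_cohort")) newdata <- newdata$graphs
  logits <- .model_logits(object$params, object$config, newdata)
  switch(type,
         logits = logits,
         prob = .softmax_rows(logits),
         class = object$classes[max.col(.softmax_rows(logits), ties.method = "first")])
}

#' Training-loss curve of a fitted classifier
#'
#' @param x A fitted [gnn_base()] or [gnn_ensemble()].
#' @param ... Passed to [plot()].
#' @export
plot.gnn_base <- function(x, ...) {
  plot(seq_along(x$loss_history), x$loss_history, type = "l",
       xlab = "epoch", ylab = "mean cross-entropy",
       main = paste(toupper(x$arch), "training loss"), ...)
  invisible(x)
}
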