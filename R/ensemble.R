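#' Stacking-ensemble configuration
#'
#' The ensemble trains the three base classifiers independently on the same
#' training data, concatenates their output features (pre-softmax logits by
#' default) and feeds them to a fully connected meta head with a softmax
#' output.
#'
#' @param base_configs List of exactly three [base_model_config()] objects;
#'   defaults to the GCN, GAT, GraphSAGE trio.
#' @param combine Meta input: \code{"concat_logits"} or \code{"concat_probs"}.
#' @param meta_hidden Hidden width of the meta head; \code{0} = a single
#'   linear layer (3C -> C).
#' @param freeze_bases Keep base weights fixed while the meta head trains
#'   (default). When \code{FALSE}, bases are fine-tuned jointly with the
#'   meta head after their independent training.
#' @return Object of class \code{ensemble_config}.
#' @export
ensemble_config <- function(base_configs = list(base_model_config("gcn"),
                                                base_model_config("gat"),
                                                base_model_config("sage")),
                            combine = c("concat_logits", "concat_probs"),
                            meta_hidden = 0L,
                            freeze_bases = TRUE) {
  combine <- match.arg(combine)
  if (length(base_configs) != 3L ||
      !all(vapply(base_configs, inherits, logical(1), "base_model_config")))
    stop("base_configs must be a list of exactly three base_model_config objects")
  structure(list(base_configs = base_configs, combine = combine,
                 meta_hidden = as.integer(meta_hidden),
                 freeze_bases = isTRUE(freeze_bases)),
            class = "ensemble_config")
}

# ---- meta head (small dense net) --------------------------------------------

.init_meta <- function(d_in, meta_hidden, n_classes = 2L) {
  if (meta_hidden > 0L) {
    list(Wm1 = .glorot(d_in, meta_hidden), bm1 = rep(0, meta_hidden),
         Wm2 = .glorot(meta_hidden, n_classes), bm2 = rep(0, n_classes))
  } else {
    list(Wm1 = .glorot(d_in, n_classes), bm1 = rep(0, n_classes))
  }
}

.meta_forward <- function(mp, Z) {
  if (!is.null(mp$Wm2)) {
    Hm <- .act(.add_bias(Z %*% mp$Wm1, mp$bm1), "relu")
    list(logits = .add_bias(Hm %*% mp$Wm2, mp$bm2), H = Hm)
  } else {
    list(logits = .add_bias(Z %*% mp$Wm1, mp$bm1), H = NULL)
  }
}

.meta_backward <- function(mp, Z, fw, dlogits) {
  if (!is.null(mp$Wm2)) {
    g <- list(Wm2 = crossprod(fw$H, dlogits), bm2 = colSums(dlogits))
    dH <- tcrossprod(dlogits, mp$Wm2) * .act_grad_from_output(fw$H, "relu")
    g$Wm1 <- crossprod(Z, dH); g$bm1 <- colSums(dH)
    g$dZ <- tcrossprod(dH, mp$Wm1)
  } else {
    g <- list(Wm1 = crossprod(Z, dlogits), bm1 = colSums(dlogits))
    g$dZ <- tcrossprod(dlogits, mp$Wm1)
  }
  g
}

.base_features <- function(logits, combine) {
  if (combine == "concat_probs") .softmax_rows(logits) else logits
}

# ---- ensemble fit ------------------------------------------------------------

#' Fit the stacking ensemble of three graph neural networks
#'
#' Trains the GCN, GAT and GraphSAGE base classifiers independently on the
#' training graphs (seeds derived from \code{optimizer$seed}), then trains a
#' fully connected meta head on the concatenation of their output features.
#' With \code{freeze_bases = FALSE} the bases are additionally fine-tuned
#' jointly with the meta head.
#'
#' @inheritParams gnn_base
#' @param config An [ensemble_config()].
#' @return Object of class \code{gnn_ensemble}: fitted \code{bases} (list of
#'   three [gnn_base] objects), \code{meta_params}, configs, and the meta
#'   training-loss history.
#' @export
gnn_ensemble <- function(x, labels = NULL, config = ensemble_config(),
                         optimizer = optimizer_config()) {
  if (inherits(x, "fc_cohort")) { labels <- x$labels; x <- x$graphs }
  labels <- as.integer(labels)
  .check_training_set(x, labels)

  bases <- vector("list", 3L)
  for (k in 1:3) {
    opt_k <- optimizer
    opt_k$seed <- optimizer$seed + k
    bases[[k]] <- gnn_base(x, labels, config = config$base_configs[[k]],
                           optimizer = opt_k)
  }
  names(bases) <- vapply(bases, function(b) b$arch, character(1))

  base_logits <- lapply(bases, function(b) predict(b, x, type = "logits"))
  if (length(unique(vapply(base_logits, ncol, integer(1)))) != 1L)
    stop("base output dimension mismatch")
  Z <- do.call(cbind, lapply(base_logits, .base_features, combine = config$combine))

  n <- length(x)
  meta_loss <- numeric(optimizer$epochs)
  mp <- NULL
  .with_seed(optimizer$seed + 99L, {
    mp <- .init_meta(ncol(Z), config$meta_hidden)
    state <- adam_init(mp)
    groups <- .make_batches(n, optimizer$batch_size)
    for (epoch in seq_len(optimizer$epochs)) {
      losses <- numeric(length(groups))
      for (b in sample.int(length(groups))) {
        ix <- groups[[b]]
        fw <- .meta_forward(mp, Z[ix, , drop = FALSE])
        lg <- .ce_loss_grad(fw$logits, labels[ix])
        losses[b] <- lg$loss
        g <- .meta_backward(mp, Z[ix, , drop = FALSE], fw, lg$dlogits)
        g$dZ <- NULL
        upd <- adam_step(mp, g, state, optimizer$learning_rate,
                         optimizer$weight_decay)
        mp <- upd$params; state <- upd$state
      }
      meta_loss[epoch] <- mean(losses)
    }
  })

  obj <- structure(list(bases = bases, meta_params = mp, config = config,
                        optimizer = optimizer, meta_loss_history = meta_loss,
                        classes = c(0L, 1L), call = match.call()),
                   class = "gnn_ensemble")
  if (!config$freeze_bases) obj <- .joint_finetune(obj, x, labels, optimizer)
  obj
}

# joint fine-tuning: gradients of the meta cross-entropy flow through the
# concatenated base logits back into every base's parameters
.joint_finetune <- function(obj, graphs, labels, opt) {
  cfgs <- lapply(obj$bases, `[[`, "config")
  params <- lapply(obj$bases, `[[`, "params")
  structs <- lapply(cfgs, function(cfg) lapply(graphs, .graph_struct, cfg$arch))
  mp <- obj$meta_params
  C <- length(params[[1L]]$bfc)
  .with_seed(opt$seed + 7919L, {
    states <- lapply(params, adam_init)
    mstate <- adam_init(mp)
    groups <- .make_batches(length(graphs), opt$batch_size)
    for (epoch in seq_len(opt$epochs)) {
      for (b in sample.int(length(groups))) {
        ix <- groups[[b]]
        fws <- caches <- vector("list", 3L)
        logit_list <- vector("list", 3L)
        batches <- lapply(1:3, function(k)
          build_graph_batch(graphs[ix], cfgs[[k]]$arch, labels = labels[ix],
                            structs = structs[[k]][ix]))
        for (k in 1:3) {
          fws[[k]] <- .model_forward(params[[k]], cfgs[[k]], batches[[k]],
                                     training = TRUE)
          logit_list[[k]] <- fws[[k]]$logits
        }
        Z <- do.call(cbind, lapply(logit_list, .base_features, obj$config$combine))
        mfw <- .meta_forward(mp, Z)
        lg <- .ce_loss_grad(mfw$logits, labels[ix])
        mg <- .meta_backward(mp, Z, mfw, lg$dlogits)
        dZ <- mg$dZ; mg$dZ <- NULL
        upd <- adam_step(mp, mg, mstate, opt$learning_rate, opt$weight_decay)
        mp <- upd$params; mstate <- upd$state
        for (k in 1:3) {
          dlog <- dZ[, ((k - 1L) * C + 1L):(k * C), drop = FALSE]
          if (obj$config$combine == "concat_probs") {
            p <- .softmax_rows(logit_list[[k]])
            dlog <- p * (dlog - rowSums(dlog * p))
          }
          g <- .model_backward(params[[k]], cfgs[[k]], batches[[k]],
                               fws[[k]]$cache, dlog)
          updk <- adam_step(params[[k]], g, states[[k]], opt$learning_rate,
                            opt$weight_decay)
          params[[k]] <- updk$params; states[[k]] <- updk$state
        }
      }
    }
  })
  for (k in 1:3) obj$bases[[k]]$params <- params[[k]]
  obj$meta_params <- mp
  obj
}

#' Predict from a fitted ensemble
#'
#' Deterministic (evaluation mode). Hard labels are the probability argmax
#' with ties resolved to class 0.
#'
#' @param object A fitted [gnn_ensemble()].
#' @param newdata List of [connectome_graph] or an \code{fc_cohort}.
#' @param type \code{"prob"}, \code{"class"} or \code{"logits"}.
#' @param ... Unused.
#' @return Matrix (prob/logits) or integer vector (class).
#' @export
predict.gnn_ensemble <- function(object, newdata,
                                 type = c("prob", "class", "logits"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "fc_cohort")) newdata <- newdata$graphs
  Z <- do.call(cbind, lapply(object$bases, function(b)
    .base_features(predict(b, newdata, type = "logits"), object$config$combine)))
  logits <- .meta_forward(object$meta_params, Z)$logits
  switch(type,
         logits = logits,
         prob = .softmax_rows(logits),
         class = object$classes[max.col(.softmax_rows(logits), ties.method = "first")])
}

#' @export
print.gnn_ensemble <- function(x, ...) {
  cat("<gnn_ensemble> stacking ensemble of",
      paste(toupper(names(x$bases)), collapse = " + "), "\n")
  cat("  meta input:", x$config$combine,
      "| meta hidden:", x$config$meta_hidden,
      "| bases frozen:", x$config$freeze_bases, "\n")
  invisible(x)
}

#' @export
summary.gnn_ensemble <- function(object, ...) {
  print(object)
  cat("  meta loss:", sprintf("%.4f -> %.4f", object$meta_loss_history[1L],
                              utils::tail(object$meta_loss_history, 1L)), "\n")
  for (b in object$bases) {
    cat("  --\n"); summary(b)
  }
  invisible(object)
}

#' @export
plot.gnn_ensemble <- function(x, ...) {
  plot(seq_along(x$meta_loss_history), x$meta_loss_history, type = "l",
       xlab = "epoch", ylab = "mean cross-entropy",
       main = "Ensemble meta-head training loss", ...)
  invisible(x)
}
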