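test_that("GCN layer equals the dense normalised-adjacency oracle", {
  set.seed(20)
  for (rep in 1:8) {
    R <- sample(3:9, 1); Fdim <- sample(2:6, 1)
    g <- rand_graphs(1, R, k = 2, seed = 20 + rep)[[1]]
    x <- matrix(rnorm(R * Fdim), R, Fdim)
    W <- matrix(rnorm(Fdim * 4), Fdim, 4)
    # independent dense oracle, written out from the definition
    At <- g$adjacency + diag(R)
    D <- diag(1 / sqrt(rowSums(At)))
    expect_equal(gcn_layer(x, g$adjacency, W),
                 D %*% At %*% D %*% x %*% W, tolerance = 1e-6)
  }
})

test_that("GCN layer on an edgeless graph reduces to the self-loop identity", {
  x <- matrix(rnorm(12), 4, 3)
  A <- matrix(0, 4, 4)
  expect_equal(gcn_layer(x, A), x, tolerance = 1e-12)
})

test_that("GCN layer rejects invalid inputs", {
  x <- matrix(rnorm(12), 4, 3)
  A <- matrix(abs(rnorm(16)), 4, 4); A <- A + t(A); diag(A) <- 0
  expect_error(gcn_layer(x[1:3, ], A), "dimension mismatch")
  expect_error(gcn_layer(x, A, weights = matrix(0, 5, 2)), "dimension mismatch")
  expect_error(gcn_layer(x, -A), "nonnegative")
})

test_that("SAGE layer equals a loop-based mean-aggregation oracle", {
  set.seed(21)
  for (rep in 1:8) {
    R <- sample(4:8, 1)
    g <- rand_graphs(1, R, k = 2, seed = 30 + rep)[[1]]
    x <- matrix(rnorm(R * 3), R, 3)
    Ws <- matrix(rnorm(9), 3, 3); Wn <- matrix(rnorm(9), 3, 3)
    nb <- lapply(seq_len(R), function(i)
      sort(unique(c(g$edges[g$edges[, 1] == i, 2], g$edges[g$edges[, 2] == i, 1]))))
    oracle <- t(vapply(seq_len(R), function(i) {
      agg <- if (length(nb[[i]]) == 0) rep(0, 3)
             else colMeans(x[nb[[i]], , drop = FALSE])
      as.numeric(x[i, ] %*% Ws + agg %*% Wn)
    }, numeric(3)))
    expect_equal(sage_layer(x, g$edges, Ws, Wn), oracle, tolerance = 1e-6)
  }
})

test_that("SAGE handles isolated nodes and identical-neighbour stars", {
  # isolated node: output depends only on the self transform
  x <- matrix(rnorm(6), 3, 2)
  edges <- cbind(1L, 2L)                 # node 3 isolated
  Ws <- diag(2); Wn <- matrix(1, 2, 2)
  out <- sage_layer(x, edges, Ws, Wn)
  expect_equal(out[3, ], x[3, ], tolerance = 1e-12)
  # star: centre aggregates the shared leaf feature exactly
  f <- c(1.5, -2)
  xs <- rbind(c(0.3, 0.7), f, f, f)
  es <- cbind(1L, 2:4)
  outs <- sage_layer(xs, es, diag(2) * 0, diag(2))
  expect_equal(outs[1, ], f, tolerance = 1e-12)
})

test_that("GAT attention is a proper softmax over neighbourhoods", {
  set.seed(22)
  g <- rand_graphs(1, 7, k = 2, seed = 40)[[1]]
  x <- matrix(rnorm(7 * 3), 7, 3)
  out <- gat_layer(x, g$edges, heads = 4, out_dim = 2, return_attention = TRUE)
  alpha <- attr(out, "alpha")
  recv <- attr(out, "recv")
  sums <- rowsum(alpha, recv)
  expect_equal(unname(sums), matrix(1, 7, 4), tolerance = 1e-6)
})

test_that("GAT self-attention makes isolated and single nodes well defined", {
  x <- matrix(c(0.4, -1.2), 1, 2)
  W <- matrix(rnorm(4), 2, 2)
  wts <- list(W = W, a_src = matrix(0.3, 2, 1), a_dst = matrix(-0.2, 2, 1))
  out <- gat_layer(x, matrix(integer(0), 0, 2), heads = 1, out_dim = 2,
                   weights = wts, return_attention = TRUE)
  expect_equal(unname(attr(out, "alpha")), matrix(1, 1, 1))
  expect_equal(matrix(out, 1, 2), x %*% W, tolerance = 1e-12)
})

test_that("GAT gives uniform attention for identical features", {
  x <- rbind(c(1, 2), c(1, 2))
  wts <- list(W = matrix(rnorm(4), 2, 2),
              a_src = matrix(rnorm(2), 2, 1), a_dst = matrix(rnorm(2), 2, 1))
  out <- gat_layer(x, cbind(1L, 2L), heads = 1, out_dim = 2, weights = wts,
                   return_attention = TRUE)
  expect_equal(unname(attr(out, "alpha")), matrix(0.5, 4, 1), tolerance = 1e-10)
})

test_that("all three layer operators are permutation-equivariant", {
  set.seed(23)
  R <- 8
  g <- rand_graphs(1, R, k = 2, seed = 50)[[1]]
  x <- matrix(rnorm(R * 4), R, 4)
  W <- matrix(rnorm(16), 4, 4)
  p <- sample(R)
  Ap <- g$adjacency[p, p]
  ep_raw <- matrix(match(as.vector(g$edges), p), ncol = 2)   # relabelled edges
  ep <- cbind(pmin(ep_raw[, 1], ep_raw[, 2]), pmax(ep_raw[, 1], ep_raw[, 2]))
  expect_equal(gcn_layer(x[p, ], Ap, W), gcn_layer(x, g$adjacency, W)[p, ],
               tolerance = 1e-10)
  expect_equal(sage_layer(x[p, ], ep, W, W), sage_layer(x, g$edges, W, W)[p, ],
               tolerance = 1e-10)
  wts <- list(W = matrix(rnorm(8), 4, 2),
              a_src = matrix(rnorm(2), 2, 1), a_dst = matrix(rnorm(2), 2, 1))
  o1 <- gat_layer(x, g$edges, heads = 1, out_dim = 2, weights = wts)
  o2 <- gat_layer(x[p, ], ep, heads = 1, out_dim = 2, weights = wts)
  expect_equal(unname(o2), unname(o1[p, ]), tolerance = 1e-10)
})

test_that("analytic gradients match finite differences for every architecture", {
  set.seed(24)
  graphs <- rand_graphs(4, 6, k = 2, seed = 60)
  labels <- c(0L, 1L, 0L, 1L)
  for (arch in c("gcn", "sage", "gat")) {
    cfg <- base_model_config(arch, hidden_dim = if (arch == "gat") 4 else 5,
                             heads = if (arch == "gat") 2 else 8, dropout = 0)
    set.seed(70)
    params <- fcgnn:::.init_params(cfg, 6)
    batch <- fcgnn:::build_graph_batch(graphs, cfg$arch, labels = labels)
    loss_of <- function(p) {
      fw <- fcgnn:::.model_forward(p, cfg, batch, training = FALSE)
      fcgnn:::.ce_loss_grad(fw$logits, labels)$loss
    }
    fw <- fcgnn:::.model_forward(params, cfg, batch, training = FALSE)
    lg <- fcgnn:::.ce_loss_grad(fw$logits, labels)
    grads <- fcgnn:::.model_backward(params, cfg, batch, fw$cache, lg$dlogits)
    eps <- 1e-6
    for (nm in names(params)) {
      idx <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
      for (i in idx) {
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
        p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - eps
        fd <- (loss_of(p2) - loss_of(p3)) / (2 * eps)
        expect_equal(grads[[nm]][i], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("compiled training step agrees with the R reference implementation", {
  set.seed(25)
  graphs <- rand_graphs(6, 7, k = 2, seed = 80)
  labels <- c(0L, 1L, 0L, 1L, 1L, 0L)
  for (arch in c("gcn", "sage", "gat")) {
    cfg <- base_model_config(arch, hidden_dim = if (arch == "gat") 6 else 5,
                             heads = if (arch == "gat") 3 else 8, dropout = 0)
    set.seed(90)
    params <- fcgnn:::.init_params(cfg, 7)
    batch <- fcgnn:::build_graph_batch(graphs, cfg$arch, labels = labels)
    res <- fcgnn:::.model_step(params, cfg, batch, training = TRUE, step_seed = 1)
    fw <- fcgnn:::.model_forward(params, cfg, batch, training = FALSE)
    lg <- fcgnn:::.ce_loss_grad(fw$logits, labels)
    gr_r <- fcgnn:::.model_backward(params, cfg, batch, fw$cache, lg$dlogits)
    expect_equal(res$logits, fw$logits, tolerance = 1e-10)
    expect_equal(res$loss, lg$loss, tolerance = 1e-10)
    for (nm in names(gr_r))
      expect_equal(unname(as.matrix(res$grads[[nm]])),
                   unname(as.matrix(gr_r[[nm]])), tolerance = 1e-9)
  }
})

test_that("graph-level readout is permutation-invariant", {
  set.seed(26)
  g <- rand_graphs(1, 8, k = 2, seed = 100)[[1]]
  p <- sample(8)
  gp <- connectome_graph(g$subject_id,
                         edges = {
                           e <- matrix(match(as.vector(g$edges), p), ncol = 2)
                           e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
                           e[order(e[, 1], e[, 2]), ]
                         },
                         adjacency = g$adjacency[p, p],
                         node_features = g$node_features[p, p])
  cfg <- base_model_config("gcn", dropout = 0)
  set.seed(101)
  params <- fcgnn:::.init_params(cfg, 8)
  b1 <- fcgnn:::build_graph_batch(list(g), "gcn")
  # permuted features must also permute columns consistently: use the same
  # permutation on rows and columns of the FC profile, as build_knn_graph does
  b2 <- fcgnn:::build_graph_batch(list(gp), "gcn")
  l1 <- fcgnn:::.model_step(params, cfg, b1, FALSE, 0)$logits
  # align parameter input dimension: first-layer weights permuted to match
  params_p <- params
  params_p$W1 <- params$W1[p, ]
  l2 <- fcgnn:::.model_step(params_p, cfg, b2, FALSE, 0)$logits
  expect_equal(l1, l2, tolerance = 1e-8)
})
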