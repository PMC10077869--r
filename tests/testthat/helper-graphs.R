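# shared fixture builders: everything is generated in code at test time

rand_fc <- function(R, sd = 0.4, subject_id = "s1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::rnorm(R * R, 0, sd), R, R)
  z <- (z + t(z)) / 2
  diag(z) <- 0
  fc_matrix(z, subject_id = subject_id)
}

rand_graphs <- function(n, R, k = 2, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(s)
    build_knn_graph(rand_fc(R, subject_id = paste0("s", s)),
                    graph_config(k = k)))
}

tiny_cohort <- function(n_per_group = c(12L, 12L), R = 10L, effect = 2,
                        noise = 0.3, seed = 7L, k = 3L) {
  generate_cohort(
    synthetic_cohort_spec(n_per_group = n_per_group, n_regions = R,
                          effect_size = effect, noise_sd = noise,
                          n_effect_edges = min(10L, R * (R - 1L) %/% 4L),
                          seed = seed),
    graph_config(k = k))
}

fast_opt <- function(epochs = 10L, seed = 1L, batch_size = 16L) {
  optimizer_config(epochs = epochs, batch_size = batch_size, seed = seed)
}

# exhaustive KNN edge enumeration: independent of the implementation
brute_knn_edges <- function(z, k) {
  R <- nrow(z)
  sel <- matrix(0L, 0L, 2L)
  for (i in seq_len(R)) {
    cand <- setdiff(seq_len(R), i)
    key <- abs(z[i, cand])
    ord <- cand[order(-key, cand)]       # ties -> lower index first
    for (j in ord[seq_len(k)]) sel <- rbind(sel, c(min(i, j), max(i, j)))
  }
  sel <- unique(sel)
  sel[order(sel[, 1L], sel[, 2L]), , drop = FALSE]
}

# O(n^2) pairwise AUC oracle (ties count 1/2)
brute_auc <- function(truth, scores, positive = 1L) {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
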