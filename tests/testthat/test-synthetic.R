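test_that("cohort generation is bitwise seed-deterministic", {
  spec <- synthetic_cohort_spec(n_per_group = c(5L, 5L), n_regions = 12L,
                                effect_size = 0.6, noise_sd = 0.3,
                                n_effect_edges = 8L, seed = 42L)
  c1 <- generate_cohort(spec, graph_config(k = 3))
  c2 <- generate_cohort(spec, graph_config(k = 3))
  expect_identical(lapply(c1$fc, `[[`, "z"), lapply(c2$fc, `[[`, "z"))
  expect_identical(c1$truth$effect_edges, c2$truth$effect_edges)
  spec2 <- spec; spec2$seed <- 43L
  c3 <- generate_cohort(spec2, graph_config(k = 3))
  expect_false(identical(c1$fc[[1]]$z, c3$fc[[1]]$z))
})

test_that("generated matrices satisfy every FC-matrix invariant", {
  ch <- tiny_cohort(n_per_group = c(4L, 4L), R = 15L, seed = 1)
  for (fc in ch$fc) {
    expect_identical(fc$z, t(fc$z))
    expect_identical(diag(fc$z), rep(0, 15))
    expect_true(all(is.finite(fc$z)))
  }
  expect_identical(ch$labels, rep(c(0L, 1L), each = 4L))
})

test_that("zero effect size produces no group difference", {
  spec <- synthetic_cohort_spec(n_per_group = c(40L, 40L), n_regions = 20L,
                                effect_size = 0, noise_sd = 0.3,
                                n_effect_edges = 20L, seed = 2L)
  ch <- generate_cohort(spec, graph_config(k = 3))
  e <- ch$truth$effect_edges
  vals <- t(vapply(ch$fc, function(f) f$z[e], numeric(nrow(e))))
  diff <- mean(vals[ch$labels == 1L, ]) - mean(vals[ch$labels == 0L, ])
  # 3 sigma band for the mean of 40*20 independent noise draws per group
  expect_lt(abs(diff), 3 * 0.3 * sqrt(2 / (40 * 20)))
})

test_that("degenerate noiseless generation gives identical group-0 subjects", {
  spec <- synthetic_cohort_spec(n_per_group = c(3L, 3L), n_regions = 10L,
                                effect_size = 1, noise_sd = 0, seed = 3L)
  ch <- generate_cohort(spec, graph_config(k = 2))
  expect_identical(ch$fc[[1]]$z, ch$fc[[2]]$z)
  expect_identical(ch$fc[[1]]$z, ch$fc[[3]]$z)
  expect_false(identical(ch$fc[[1]]$z, ch$fc[[4]]$z))  # group 1 shifted
})

test_that("the injected effect is recovered from the edge means", {
  spec <- synthetic_cohort_spec(n_per_group = c(100L, 100L), n_regions = 30L,
                                effect_size = 1.0, noise_sd = 0.3,
                                n_effect_edges = 50L, seed = 4L)
  ch <- generate_cohort(spec, graph_config(k = 5))
  e <- ch$truth$effect_edges
  expect_identical(nrow(e), 50L)
  vals <- t(vapply(ch$fc, function(f) f$z[e], numeric(50L)))
  diff <- mean(vals[ch$labels == 1L, ]) - mean(vals[ch$labels == 0L, ])
  expect_equal(diff, 1.0, tolerance = 0.1)
})

test_that("effect edges form a connected subgraph over their touched nodes", {
  spec <- synthetic_cohort_spec(n_per_group = c(2L, 2L), n_regions = 25L,
                                n_effect_edges = 30L, seed = 5L)
  ch <- generate_cohort(spec, graph_config(k = 2))
  e <- ch$truth$effect_edges
  nodes <- sort(unique(as.vector(e)))
  # breadth-first reachability over the effect edges
  reach <- nodes[1]
  repeat {
    nxt <- unique(c(e[e[, 1] %in% reach, 2], e[e[, 2] %in% reach, 1]))
    grown <- union(reach, nxt)
    if (length(grown) == length(reach)) break
    reach <- grown
  }
  expect_setequal(reach, nodes)
})

test_that("site offsets shift whole matrices per acquisition site", {
  spec <- synthetic_cohort_spec(n_per_group = c(10L, 10L), n_regions = 10L,
                                effect_size = 0, noise_sd = 0.05,
                                n_sites = 2L, site_sd = 1.0, seed = 6L)
  ch <- generate_cohort(spec, graph_config(k = 2))
  expect_true(all(ch$site %in% 1:2))
  m1 <- mean(vapply(ch$fc[ch$site == 1L], function(f) mean(f$z[upper.tri(f$z)]),
                    numeric(1)))
  m2 <- mean(vapply(ch$fc[ch$site == 2L], function(f) mean(f$z[upper.tri(f$z)]),
                    numeric(1)))
  expect_gt(abs(m1 - m2), 0.1)        # site_sd = 1 dominates the tiny noise
})

test_that("presets encode the intended study conditions", {
  ps <- preset_cohorts()
  expect_named(ps, c("separable", "moderate", "null", "imbalanced"))
  expect_identical(ps$separable$effect_size, 1.5)
  expect_identical(ps$separable$noise_sd, 0.2)
  expect_identical(ps$moderate$effect_size, 0.4)
  expect_identical(ps$moderate$noise_sd, 0.3)
  expect_identical(ps$null$effect_size, 0)
  expect_identical(ps$imbalanced$n_per_group, c(110L, 55L))
})

test_that("imbalanced preset plus upsampling balances training folds exactly", {
  ps <- preset_cohorts(n_regions = 10L)
  spec <- ps$imbalanced
  spec$n_per_group <- c(22L, 11L)          # scaled-down, same 2:1 imbalance
  ch <- generate_cohort(spec, graph_config(k = 3))
  plan <- stratified_kfold(ch$labels, n_folds = 3, seed = 1)
  for (f in 1:3) {
    train <- which(plan$assignments != f)
    res <- apply_resampling(train, ch$labels,
                            resampling_policy("upsample", seed = f))
    expect_identical(sum(ch$labels[res] == 0L), sum(ch$labels[res] == 1L))
    expect_true(all(train %in% res))
  }
})
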