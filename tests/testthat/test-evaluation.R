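test_that("stratified folds split a divisible cohort exactly evenly", {
  labels <- rep(c(1L, 0L), c(60L, 40L))
  plan <- stratified_kfold(labels, n_folds = 10, seed = 1)
  for (f in 1:10) {
    expect_identical(sum(plan$assignments == f & labels == 1L), 6L)
    expect_identical(sum(plan$assignments == f & labels == 0L), 4L)
  }
})

test_that("stratified folds partition the cohort and respect class balance", {
  set.seed(30)
  labels <- rbinom(137, 1, 0.4)
  plan <- stratified_kfold(labels, n_folds = 10, seed = 2)
  expect_identical(sort(unique(plan$assignments)), 1:10)
  expect_identical(length(plan$assignments), length(labels))
  for (cl in 0:1) {
    counts <- table(plan$assignments[labels == cl])
    expect_lte(max(counts) - min(counts), 1)
  }
  expect_identical(stratified_kfold(labels, 10, seed = 2)$assignments,
                   plan$assignments)
  expect_false(identical(stratified_kfold(labels, 10, seed = 3)$assignments,
                         plan$assignments))
})

test_that("a 821/765 cohort yields the ceiling/floor per-fold class counts", {
  labels <- rep(c(1L, 0L), c(821L, 765L))
  plan <- stratified_kfold(labels, n_folds = 10, seed = 4)
  pos <- table(plan$assignments[labels == 1L])
  neg <- table(plan$assignments[labels == 0L])
  expect_true(all(pos %in% c(82L, 83L)))
  expect_true(all(neg %in% c(76L, 77L)))
  expect_identical(sum(pos), 821L)
  expect_identical(sum(neg), 765L)
})

test_that("classes smaller than the fold count are rejected", {
  expect_error(stratified_kfold(c(rep(0L, 30), rep(1L, 5)), n_folds = 10),
               "at least n_folds")
})

test_that("upsampling duplicates minority subjects without removing anyone", {
  labels <- rep(c(0L, 1L), c(10L, 6L))
  ids <- seq_along(labels)
  out <- apply_resampling(ids, labels, resampling_policy("upsample", seed = 1))
  expect_identical(sum(labels[out] == 0L), 10L)
  expect_identical(sum(labels[out] == 1L), 10L)
  expect_true(all(ids %in% out))                       # nobody removed
  expect_true(all(out %in% ids))                       # only copies
  extras <- out[-seq_along(ids)]
  expect_true(all(labels[extras] == 1L))               # copies are minority
})

test_that("downsampling subsets the majority without duplication", {
  labels <- rep(c(0L, 1L), c(10L, 6L))
  ids <- seq_along(labels)
  out <- apply_resampling(ids, labels, resampling_policy("downsample", seed = 1))
  expect_identical(sum(labels[out] == 0L), 6L)
  expect_identical(sum(labels[out] == 1L), 6L)
  expect_identical(anyDuplicated(out), 0L)
  expect_true(all(out %in% ids))
  expect_true(all(ids[labels == 1L] %in% out))         # minority untouched
})

test_that("balanced input is a fixed point of both resampling modes", {
  labels <- rep(c(0L, 1L), each = 8L)
  ids <- seq_along(labels)
  expect_identical(apply_resampling(ids, labels, resampling_policy("upsample")),
                   ids)
  expect_identical(apply_resampling(ids, labels, resampling_policy("downsample")),
                   ids)
  expect_identical(apply_resampling(ids, labels, resampling_policy("none")), ids)
})

test_that("confusion counts follow the TP/TN/FP/FN definitions", {
  truth <- c(1, 1, 1, 1, 1, 0, 0, 0)
  pred <- c(1, 1, 1, 0, 0, 0, 0, 1)
  cc <- compute_confusion(truth, pred)
  expect_identical(cc[c("TP", "FN", "TN", "FP")],
                   list(TP = 3L, FN = 2L, TN = 2L, FP = 1L))
  perfect <- compute_confusion(truth, truth)
  expect_identical(perfect$FP + perfect$FN, 0L)
  inverted <- compute_confusion(truth, 1 - truth)
  expect_identical(inverted$TP + inverted$TN, 0L)
  expect_identical(inverted$FN, 5L)
  expect_identical(inverted$FP, 3L)
  expect_error(compute_confusion(c(0, 2), c(0, 1)), "0 or 1")
})

test_that("ACC/SEN/SPE are exact ratios with undefined cases reported as NA", {
  m <- compute_metrics(compute_confusion(c(1, 1, 1, 1, 1, 0, 0, 0),
                                         c(1, 1, 1, 0, 0, 0, 0, 1)))
  expect_identical(m$ACC, 0.625)
  expect_identical(m$SEN, 0.6)
  expect_equal(m$SPE, 2 / 3, tolerance = 1e-15)
  perfect <- compute_metrics(compute_confusion(c(1, 0), c(1, 0)))
  expect_identical(unlist(perfect), c(ACC = 1, SEN = 1, SPE = 1))
  allmiss <- compute_metrics(compute_confusion(rep(1, 5), rep(0, 5)))
  expect_identical(allmiss$SEN, 0)
  expect_true(is.na(allmiss$SPE))                    # no negatives scored
})

test_that("trapezoidal AUC equals the pairwise Mann-Whitney oracle", {
  expect_identical(compute_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_identical(compute_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    truth <- c(0L, 1L, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n), sample(0:2, 1))       # induce ties
    expect_equal(compute_auc(truth, scores), brute_auc(truth, scores),
                 tolerance = 1e-12)
  }
  expect_error(compute_auc(rep(1, 4), rnorm(4)), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(32)
  truth <- rbinom(40, 1, 0.5); truth[1:2] <- c(0L, 1L)
  scores <- rnorm(40)
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(compute_auc(truth, scores), ref, tolerance = 1e-10)
})

test_that("the accuracy identity ACC*(P+N) = SEN*P + SPE*N holds", {
  set.seed(33)
  for (rep in 1:50) {
    cc <- structure(as.list(rmultinom(1, 60, rep(0.25, 4))[, 1] + 1L),
                    names = c("TP", "TN", "FP", "FN"),
                    class = "confusion_counts")
    m <- compute_metrics(cc)
    P <- cc$TP + cc$FN; N <- cc$TN + cc$FP
    expect_equal(m$ACC * (P + N), m$SEN * P + m$SPE * N, tolerance = 1e-12)
  }
})

test_that("run_cv scores every subject once and reports per-model metrics", {
  ch <- tiny_cohort(n_per_group = c(12L, 12L), R = 10L, seed = 8)
  cfg <- ensemble_config(base_configs = list(
    base_model_config("gcn", hidden_dim = 8),
    base_model_config("gat", hidden_dim = 8, heads = 2),
    base_model_config("sage", hidden_dim = 8)))
  rep3 <- run_cv(ch, config = cfg, optimizer = fast_opt(epochs = 3),
                 n_folds = 3, fold_seed = 1,
                 policy = resampling_policy("upsample", seed = 1))
  expect_s3_class(rep3, "cv_report")
  expect_identical(sort(unique(rep3$per_fold$model)),
                   c("ensemble", "gat", "gcn", "sage"))
  expect_identical(nrow(rep3$per_fold), 4L * 3L)
  ens_pred <- rep3$predictions[rep3$predictions$model == "ensemble", ]
  expect_identical(sort(ens_pred$subject_id), sort(ch$subject_ids))
  expect_identical(rep3$leakage_count, 0)            # leak-free default
  expect_true(all(rep3$summary$ACC >= 0 & rep3$summary$ACC <= 1))
  # unweighted mean aggregation
  expect_equal(rep3$summary$ACC[rep3$summary$model == "ensemble"],
               mean(rep3$per_fold$ACC[rep3$per_fold$model == "ensemble"]),
               tolerance = 1e-12)
})

test_that("run_cv is reproducible given its seeds", {
  ch <- tiny_cohort(n_per_group = c(10L, 10L), R = 8L, seed = 9)
  cfg <- ensemble_config(base_configs = list(
    base_model_config("gcn", hidden_dim = 8),
    base_model_config("gat", hidden_dim = 8, heads = 2),
    base_model_config("sage", hidden_dim = 8)))
  r1 <- run_cv(ch, config = cfg, optimizer = fast_opt(epochs = 2), n_folds = 2,
               fold_seed = 3, policy = resampling_policy("downsample", seed = 4))
  r2 <- run_cv(ch, config = cfg, optimizer = fast_opt(epochs = 2), n_folds = 2,
               fold_seed = 3, policy = resampling_policy("downsample", seed = 4))
  expect_identical(r1$per_fold, r2$per_fold)
  expect_identical(r1$predictions, r2$predictions)
})

test_that("report_tables writes stable, consistent CSVs", {
  ch <- tiny_cohort(n_per_group = c(10L, 10L), R = 8L, seed = 10)
  cfg <- ensemble_config(base_configs = list(
    base_model_config("gcn", hidden_dim = 8),
    base_model_config("gat", hidden_dim = 8, heads = 2),
    base_model_config("sage", hidden_dim = 8)))
  rep2 <- run_cv(ch, config = cfg, optimizer = fast_opt(epochs = 2),
                 n_folds = 2, fold_seed = 1, policy = resampling_policy("none"))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  report_tables(rep2, d1)
  report_tables(rep2, d2)
  for (f in c("metrics_summary.csv", "metrics_per_fold.csv", "predictions.csv",
              "run_config.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  per_fold <- utils::read.csv(file.path(d1, "metrics_per_fold.csv"))
  expect_identical(nrow(per_fold), 8L)               # 4 models x 2 folds
  summary_csv <- utils::read.csv(file.path(d1, "metrics_summary.csv"))
  for (m in summary_csv$model) {
    expect_equal(summary_csv$ACC[summary_csv$model == m],
                 mean(per_fold$ACC[per_fold$model == m]), tolerance = 1e-9)
  }
  echo <- jsonlite::fromJSON(file.path(d1, "run_config.json"))
  expect_equal(echo$optimizer$seed, 1L)
  expect_equal(echo$n_folds, 2L)
})

test_that("before-split resampling can leak duplicates across folds", {
  ch <- tiny_cohort(n_per_group = c(20L, 10L), R = 8L, seed = 11)
  cfg <- ensemble_config(base_configs = list(
    base_model_config("gcn", hidden_dim = 8),
    base_model_config("gat", hidden_dim = 8, heads = 2),
    base_model_config("sage", hidden_dim = 8)))
  leaky <- run_cv(ch, config = cfg, optimizer = fast_opt(epochs = 1),
                  n_folds = 2, fold_seed = 1,
                  policy = resampling_policy("upsample", "before_split", seed = 2))
  clean <- run_cv(ch, config = cfg, optimizer = fast_opt(epochs = 1),
                  n_folds = 2, fold_seed = 1,
                  policy = resampling_policy("upsample", "train_folds_only",
                                             seed = 2))
  expect_gt(leaky$leakage_count, 0)
  expect_identical(clean$leakage_count, 0)
})
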