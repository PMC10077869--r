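#' Stratified k-fold assignment
#'
#' Splits subjects into \code{n_folds} folds so that each class's members are
#' spread as evenly as possible: per-fold class counts differ by at most one
#' from each other and the class proportions match the global ones up to one
#' subject. Deterministic given \code{seed}.
#'
#' @param labels Vector of class labels in \code{\{0, 1\}}.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return Object of class \code{fold_plan}: list with \code{assignments}
#'   (fold index per subject), \code{n_folds}, \code{seed}.
#' @export
stratified_kfold <- function(labels, n_folds = 10L, seed = 1L) {
  labels <- as.integer(labels)
  if (any(!labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  n_folds <- as.integer(n_folds)
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts < n_folds))
    stop("every class needs at least n_folds = ", n_folds, " members")
  assignments <- integer(length(labels))
  .with_seed(seed, {
    for (cl in c(0L, 1L)) {
      ids <- which(labels == cl)
      ids <- ids[sample.int(length(ids))]
      start <- sample.int(n_folds, 1L)   # rotate so fold 1 isn't always largest
      assignments[ids] <- ((seq_along(ids) - 1L + start) %% n_folds) + 1L
    }
  })
  structure(list(assignments = assignments, n_folds = n_folds, seed = seed),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("<fold_plan>", x$n_folds, "stratified folds over",
      length(x$assignments), "subjects (seed", paste0(x$seed, ")\n"))
  print(table(fold = x$assignments))
  invisible(x)
}

#' Class-balance resampling policy
#'
#' \code{upsample} duplicates randomly chosen minority-class subjects until
#' the classes are equal (every original subject is kept at least once);
#' \code{downsample} keeps a random majority-class subset of minority size
#' (no subject duplicated); \code{none} is the identity. \code{scope}
#' controls where balancing happens in cross-validation:
#' \code{train_folds_only} (leak-free default) resamples within each
#' training split, \code{before_split} balances the whole cohort before the
#' folds are drawn, so duplicated subjects may straddle the train/test
#' boundary — [run_cv()] counts and reports that leakage.
#'
#' @param mode \code{"upsample"}, \code{"downsample"} or \code{"none"}.
#' @param scope \code{"train_folds_only"} or \code{"before_split"}.
#' @param seed Integer seed.
#' @return Object of class \code{resampling_policy}.
#' @export
resampling_policy <- function(mode = c("upsample", "downsample", "none"),
                              scope = c("train_folds_only", "before_split"),
                              seed = 1L) {
  structure(list(mode = match.arg(mode), scope = match.arg(scope),
                 seed = as.integer(seed)),
            class = "resampling_policy")
}

#' Apply a resampling policy to a set of subject ids
#'
#' @param ids Integer subject indices to resample.
#' @param labels Class labels for ALL subjects (indexed by \code{ids}).
#' @param policy A [resampling_policy()].
#' @return Integer multiset of ids with equal class counts (for
#'   \code{upsample}/\code{downsample}), or \code{ids} unchanged for
#'   \code{mode = "none"}.
#' @export
apply_resampling <- function(ids, labels, policy) {
  if (policy$mode == "none") return(ids)
  lab <- as.integer(labels[ids])
  if (length(unique(lab)) < 2L) stop("both classes must be present")
  n0 <- sum(lab == 0L); n1 <- sum(lab == 1L)
  if (n0 == n1) return(ids)
  minority <- if (n0 < n1) 0L else 1L
  .with_seed(policy$seed, {
    if (policy$mode == "upsample") {
      pool <- ids[lab == minority]
      extra <- pool[sample.int(length(pool), abs(n0 - n1), replace = TRUE)]
      out <- c(ids, extra)
    } else {
      keep_min <- ids[lab == minority]
      pool <- ids[lab != minority]
      keep_maj <- pool[sample.int(length(pool), min(n0, n1))]
      out <- sort(c(keep_min, keep_maj))
    }
    out
  })
}

#' Confusion counts for binary predictions
#'
#' @param truth,predicted Vectors of labels in \code{\{0, 1\}}.
#' @param positive_class Which label counts as "positive" for TP/FN
#'   (default 1, i.e. patients).
#' @return Object of class \code{confusion_counts} with fields TP, TN, FP,
#'   FN; their sum equals the number of scored subjects.
#' @export
compute_confusion <- function(truth, predicted, positive_class = 1L) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (length(truth) != length(predicted)) stop("length mismatch")
  if (any(!c(truth, predicted) %in% c(0L, 1L))) stop("labels must be 0 or 1")
  pos <- truth == positive_class
  hit <- predicted == truth
  structure(list(TP = sum(pos & hit), TN = sum(!pos & hit),
                 FP = sum(!pos & !hit), FN = sum(pos & !hit)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' ACC = (TP + TN) / (TP + FP + FN + TN), SEN = TP / (TP + FN),
#' SPE = TN / (TN + FP). A metric whose denominator is zero is undefined and
#' reported as \code{NA}, never silently as 0.
#'
#' @param counts A [compute_confusion()] result.
#' @return Named list with \code{ACC}, \code{SEN}, \code{SPE}.
#' @export
compute_metrics <- function(counts) {
  with(counts, {
    total <- TP + FP + FN + TN
    list(ACC = if (total > 0) (TP + TN) / total else NA_real_,
         SEN = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
         SPE = if (TN + FP > 0) TN / (TN + FP) else NA_real_)
  })
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the ROC generated by sweeping a threshold over the
#' positive-class scores; identical to the Mann-Whitney U statistic divided
#' by \code{n_pos * n_neg}, with tied score pairs counted 1/2.
#'
#' @param truth Labels in \code{\{0, 1\}}; both classes must be present.
#' @param scores Finite numeric scores for the positive class.
#' @param positive_class Label treated as positive (default 1).
#' @return AUC in \code{[0, 1]}.
#' @export
compute_auc <- function(truth, scores, positive_class = 1L) {
  truth <- as.integer(truth)
  if (length(truth) != length(scores)) stop("length mismatch")
  if (any(!is.finite(scores))) stop("scores must be finite")
  pos <- truth == positive_class
  P <- sum(pos); N <- sum(!pos)
  if (P == 0L || N == 0L) stop("both classes must be present to compute AUC")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- pos[ord]
  # collapse tied thresholds, then trapezoid over (FPR, TPR)
  last <- cumsum(rle(s)$lengths)
  ctp <- cumsum(y)[last] / P
  cfp <- cumsum(!y)[last] / N
  tpr <- c(0, ctp); fpr <- c(0, cfp)
  sum(diff(fpr) * (tpr[-length(tpr)] + tpr[-1L]) / 2)
}

# count test-set subjects whose id also occurs in the fold's training multiset
.leakage_count <- function(fold_train_ids, fold_test_ids) {
  sum(vapply(seq_along(fold_test_ids), function(f)
    sum(fold_test_ids[[f]] %in% fold_train_ids[[f]]), numeric(1)))
}

#' Cross-validated evaluation of the ensemble and its base models
#'
#' Runs stratified k-fold cross-validation: per fold, the training subjects
#' are optionally class-balanced (see [resampling_policy()]), the three base
#' models and the stacking ensemble are trained on the training portion, and
#' the untouched test fold is scored. ACC/SEN/SPE/AUC are reported per fold
#' and as their unweighted mean over folds, for the ensemble and for every
#' base model. AUC uses the positive-class softmax probability as the score.
#' Fully reproducible given \code{fold_seed}, \code{policy$seed} and
#' \code{optimizer$seed}.
#'
#' With \code{policy$scope = "before_split"}, balancing happens before the
#' fold split (duplicated subjects may then straddle folds); the resulting
#' cross-fold duplicate count is reported as \code{leakage_count}, which is
#' zero by construction under \code{train_folds_only}.
#'
#' @param cohort An \code{fc_cohort} (see [generate_cohort()] /
#'   [read_cohort()]).
#' @param config An [ensemble_config()].
#' @param optimizer An [optimizer_config()]; per-fold training seeds are
#'   derived from \code{optimizer$seed}.
#' @param n_folds Number of folds (default 10).
#' @param fold_seed Seed for the stratified fold assignment.
#' @param policy A [resampling_policy()].
#' @return Object of class \code{cv_report}: \code{per_fold} (data.frame:
#'   model, fold, TP/TN/FP/FN, ACC/SEN/SPE/AUC), \code{summary} (mean over
#'   folds per model), \code{predictions} (per-subject: subject_id, fold,
#'   true, prob_positive, pred, model), \code{leakage_count}, and a config
#'   echo with all seeds.
#' @export
run_cv <- function(cohort, config = ensemble_config(),
                   optimizer = optimizer_config(), n_folds = 10L,
                   fold_seed = 1L, policy = resampling_policy()) {
  stopifnot(inherits(cohort, "fc_cohort"))
  labels <- as.integer(cohort$labels)
  graphs <- cohort$graphs
  positive <- if (is.null(cohort$positive_class)) 1L else cohort$positive_class
  ids <- seq_along(graphs)
  orig_of <- ids                       # maps working index -> original subject

  if (policy$scope == "before_split" && policy$mode != "none") {
    res <- apply_resampling(ids, labels, policy)
    orig_of <- res
    labels <- labels[res]
    graphs <- graphs[res]
  }

  plan <- stratified_kfold(labels, n_folds = n_folds, seed = fold_seed)
  fold_train_orig <- fold_test_orig <- vector("list", n_folds)

  models <- c("ensemble", "gcn", "gat", "sage")
  per_fold <- list(); preds <- list()
  for (f in seq_len(n_folds)) {
    test_ix <- which(plan$assignments == f)
    train_ix <- which(plan$assignments != f)
    if (policy$scope == "train_folds_only" && policy$mode != "none") {
      pol_f <- policy
      pol_f$seed <- policy$seed + f * 1009L
      train_ix <- apply_resampling(train_ix, labels, pol_f)
    }
    fold_train_orig[[f]] <- orig_of[train_ix]
    fold_test_orig[[f]] <- orig_of[test_ix]

    opt_f <- optimizer
    opt_f$seed <- optimizer$seed + f * 7919L
    fit <- tryCatch(
      gnn_ensemble(graphs[train_ix], labels[train_ix], config = config,
                   optimizer = opt_f),
      error = function(e) stop("fold ", f, ": ", conditionMessage(e), call. = FALSE))

    test_graphs <- graphs[test_ix]
    truth <- labels[test_ix]
    prob_list <- c(list(ensemble = predict(fit, test_graphs, type = "prob")),
                   lapply(fit$bases, function(b) predict(b, test_graphs, type = "prob")))
    for (m in models) {
      p <- prob_list[[m]]
      prob_pos <- p[, positive + 1L]
      pred <- c(0L, 1L)[max.col(p, ties.method = "first")]
      cc <- compute_confusion(truth, pred, positive_class = positive)
      met <- compute_metrics(cc)
      per_fold[[length(per_fold) + 1L]] <- data.frame(
        model = m, fold = f, TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN,
        ACC = met$ACC, SEN = met$SEN, SPE = met$SPE,
        AUC = compute_auc(truth, prob_pos, positive_class = positive))
      preds[[length(preds) + 1L]] <- data.frame(
        model = m, fold = f,
        subject_id = vapply(test_graphs, function(g) g$subject_id, character(1)),
        true = truth, prob_positive = prob_pos, pred = pred)
    }
  }
  per_fold <- do.call(rbind, per_fold)
  preds <- do.call(rbind, preds)
  summary_df <- do.call(rbind, lapply(models, function(m) {
    sub <- per_fold[per_fold$model == m, ]
    data.frame(model = m, sampling = policy$mode,
               ACC = mean(sub$ACC), SEN = mean(sub$SEN), SPE = mean(sub$SPE),
               AUC = mean(sub$AUC))
  }))
  structure(list(per_fold = per_fold, summary = summary_df, predictions = preds,
                 leakage_count = .leakage_count(fold_train_orig, fold_test_orig),
                 n_folds = n_folds, positive_class = positive,
                 config_echo = list(fold_seed = fold_seed,
                                    optimizer = unclass(optimizer),
                                    policy = unclass(policy),
                                    ensemble = .echo_ensemble_config(config))),
            class = "cv_report")
}

.echo_ensemble_config <- function(config) {
  list(combine = config$combine, meta_hidden = config$meta_hidden,
       freeze_bases = config$freeze_bases,
       base_configs = lapply(config$base_configs, unclass))
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report>", x$n_folds, "-fold cross-validation; sampling:",
      x$config_echo$policy$mode, "(", x$config_echo$policy$scope, ")\n")
  cat("  cross-fold duplicate leakage:", x$leakage_count, "subjects\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.cv_report <- function(object, ...) {
  print(object)
  cat("\nPer-fold ensemble metrics:\n")
  print(object$per_fold[object$per_fold$model == "ensemble",
                        c("fold", "ACC", "SEN", "SPE", "AUC")],
        row.names = FALSE, digits = 4)
  invisible(object)
}

#' Write cross-validation reports as CSV tables
#'
#' Writes \code{metrics_summary.csv} (one row per model with mean
#' ACC/SEN/SPE/AUC), \code{metrics_per_fold.csv} (one row per model x fold),
#' \code{predictions.csv} (per-subject fold predictions and probabilities)
#' and \code{run_config.json} (config echo with all seeds) into \code{dir}.
#' Byte-identical across re-runs on the same report.
#'
#' @param report A [run_cv()] result.
#' @param dir Output directory (created if missing).
#' @return Character vector of file paths, invisibly.
#' @export
report_tables <- function(report, dir) {
  stopifnot(inherits(report, "cv_report"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  paths <- file.path(dir, c("metrics_summary.csv", "metrics_per_fold.csv",
                            "predictions.csv", "run_config.json"))
  .write_csv <- function(df, path) {
    num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf("%.10g", v))
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  }
  .write_csv(report$summary, paths[1L])
  .write_csv(report$per_fold, paths[2L])
  .write_csv(report$predictions, paths[3L])
  echo <- c(report$config_echo, list(leakage_count = report$leakage_count,
                                     n_folds = report$n_folds))
  writeLines(jsonlite::toJSON(echo, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), paths[4L])
  invisible(paths)
}
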