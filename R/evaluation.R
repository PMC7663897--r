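#' Confusion counts
#'
#' Standard 2x2 tally with `"positive"` as the class of interest.
#'
#' @param y_true,y_pred Equal-length binary label vectors
#'   (`"positive"`/`"negative"`, 0/1, or logical).
#' @return List with integer `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have the same length", call. = FALSE)
  }
  yt <- as_binary(y_true)
  yp <- as_binary(y_pred)
  structure(
    list(
      TP = sum(yt == 1 & yp == 1),
      TN = sum(yt == 0 & yp == 0),
      FP = sum(yt == 0 & yp == 1),
      FN = sum(yt == 1 & yp == 0)
    ),
    class = "confusion_counts"
  )
}

#' ROC curve points and trapezoidal AUROC
#'
#' Thresholds are placed only between distinct score values, so tied scores
#' are processed as a block; the area is the trapezoidal integral of TPR over
#' FPR.
#'
#' @param scores Numeric scores in `[0,1]` (higher = more positive).
#' @param y_true Binary truth labels.
#' @return List with `points` (data frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_curve <- function(scores, y_true) {
  yt <- as_binary(y_true)
  check_scores(scores)
  np <- sum(yt == 1)
  nn <- sum(yt == 0)
  if (np == 0L || nn == 0L) {
    stop("ROC requires both classes present", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  ord <- order(scores, decreasing = TRUE)
  ys <- yt[ord]
  ss <- scores[ord]
  cum_tp <- cumsum(ys)
  cum_fp <- cumsum(1 - ys)
  last_of_block <- c(ss[-1] != ss[-length(ss)], TRUE)
  tpr <- c(0, cum_tp[last_of_block] / np)
  fpr <- c(0, cum_fp[last_of_block] / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(
    points = data.frame(fpr = fpr, tpr = tpr, threshold = c(Inf, thr)),
    auc = auc
  )
}

#' Precision-recall curve and step-wise AUPRC
#'
#' Uses the step-wise (precision-at-recall) summation
#' \eqn{\sum_i (R_i - R_{i-1}) P_i} over descending score thresholds (the
#' average-precision convention), not linear interpolation.
#'
#' @inheritParams roc_curve
#' @return List with `points` (data frame `recall`, `precision`, `threshold`)
#'   and `auc`.
#' @export
pr_curve <- function(scores, y_true) {
  yt <- as_binary(y_true)
  check_scores(scores)
  np <- sum(yt == 1)
  if (np == 0L) stop("PR curve requires at least one positive", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  ys <- yt[ord]
  ss <- scores[ord]
  cum_tp <- cumsum(ys)
  n_pred <- seq_along(ys)
  last_of_block <- c(ss[-1] != ss[-length(ss)], TRUE)
  recall <- cum_tp[last_of_block] / np
  precision <- (cum_tp / n_pred)[last_of_block]
  auc <- sum(diff(c(0, recall)) * precision)
  list(
    points = data.frame(
      recall = recall, precision = precision,
      threshold = ss[last_of_block]
    ),
    auc = auc
  )
}

check_scores <- function(scores) {
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1)) {
    stop("scores must lie in [0,1]", call. = FALSE)
  }
}

#' Metrics report from confusion counts
#'
#' Computes accuracy, sensitivity, specificity, their harmonic mean, precision
#' and F1 from the 2x2 counts:
#' Acc = (TP+TN)/(TP+TN+FP+FN), Sn = TP/(TP+FN), Sp = TN/(TN+FP),
#' Hm = 2 Sn Sp / (Sn+Sp), F1 = 2 PRE Sn / (PRE+Sn) with PRE = TP/(TP+FP).
#' A metric whose denominator is zero is reported as `NA` (absent) with a
#' warning, never coerced to 0. When probability scores are supplied, AUROC
#' (trapezoidal) and AUPRC (step-wise) are added.
#'
#' @param counts A [confusion()] result.
#' @param scores Optional per-record probabilities for the threshold-free
#'   metrics.
#' @param y_true Truth labels matching `scores` (required with `scores`).
#' @return A `metrics_report` list: `counts`, `acc`, `sn`, `sp`, `hm`, `pre`,
#'   `f1`, and (when scores given) `auroc`, `auprc`, `scores`, `y_true`.
#' @export
metrics_from_counts <- function(counts, scores = NULL, y_true = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); reported as NA", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  tp <- counts$TP
  tn <- counts$TN
  fp <- counts$FP
  fn <- counts$FN
  acc <- safe_div(tp + tn, tp + tn + fp + fn, "accuracy")
  sn <- safe_div(tp, tp + fn, "sensitivity")
  sp <- safe_div(tn, tn + fp, "specificity")
  hm <- if (is.na(sn) || is.na(sp)) {
    NA_real_
  } else if (sn + sp == 0) {
    warning("harmonic mean undefined (Sn + Sp = 0); reported as NA", call. = FALSE)
    NA_real_
  } else {
    2 * sn * sp / (sn + sp)
  }
  pre <- safe_div(tp, tp + fp, "precision")
  f1 <- if (is.na(pre) || is.na(sn)) {
    NA_real_
  } else if (pre + sn == 0) {
    warning("F1 undefined (PRE + Sn = 0); reported as NA", call. = FALSE)
    NA_real_
  } else {
    2 * pre * sn / (pre + sn)
  }
  out <- list(
    counts = counts, acc = acc, sn = sn, sp = sp, hm = hm, pre = pre, f1 = f1,
    auroc = NA_real_, auprc = NA_real_, scores = scores, y_true = y_true
  )
  if (!is.null(scores)) {
    if (is.null(y_true)) stop("y_true is required alongside scores", call. = FALSE)
    out$auroc <- roc_curve(scores, y_true)$auc
    out$auprc <- pr_curve(scores, y_true)$auc
  }
  class(out) <- "metrics_report"
  out
}

#' Evaluate probability predictions against truth labels
#'
#' Thresholds the scores (`>= threshold` is positive), tallies the confusion
#' matrix and returns the full [metrics_from_counts()] report.
#'
#' @param scores Probabilities in `[0,1]`.
#' @param y_true Truth labels.
#' @param threshold Decision threshold (default 0.5).
#' @return A `metrics_report`.
#' @export
evaluate_predictions <- function(scores, y_true, threshold = 0.5) {
  check_scores(scores)
  pred <- as.numeric(scores >= threshold)
  metrics_from_counts(confusion(y_true, pred), scores = scores, y_true = y_true)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> TP=%d TN=%d FP=%d FN=%d\n", x$counts$TP, x$counts$TN,
    x$counts$FP, x$counts$FN
  ))
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat(sprintf(
    "  acc=%s sn=%s sp=%s hm=%s f1=%s auroc=%s auprc=%s\n",
    fmt(x$acc), fmt(x$sn), fmt(x$sp), fmt(x$hm), fmt(x$f1),
    fmt(x$auroc), fmt(x$auprc)
  ))
  invisible(x)
}

metric_names <- c("acc", "sn", "sp", "hm", "pre", "f1", "auroc", "auprc")

report_row <- function(r) {
  vapply(metric_names, function(m) r[[m]], numeric(1))
}

#' Fivefold-style cross-validation of the full pipeline
#'
#' Runs the training protocol per fold: (1) class-mean profiles are fitted on
#' the training folds only (never on test data); (2) training positives are
#' augmented by [weighted_bagging()] when a bagging configuration is given;
#' (3) training negatives are randomly down-sampled to the size of the
#' (augmented) positive training set; (4) the CNN is trained; (5) the held-out
#' fold is evaluated untouched, at its natural class imbalance.
#'
#' @param pos,neg Labeled positive and negative [dataset()]s; each must have
#'   at least `n_folds` records.
#' @param n_folds Number of folds (default 5).
#' @param bagging Optional [bagging_config()]; `NULL` disables augmentation.
#' @param cnn A [cnn_config()].
#' @param seed Integer seed; per-fold seeds are derived from it.
#' @param k_range,pseudocount Passed to [fit_class_means()].
#' @return A `cv_result`: `per_fold` (list of `metrics_report`), `summary`
#'   (data frame of per-fold metric rows plus a mean row), `plan_pos`,
#'   `plan_neg`, `fold_details` (train ids and profile per fold), `seed`.
#' @export
run_cross_validation <- function(pos, neg, n_folds = 5L, bagging = NULL,
                                 cnn = cnn_config(), seed = 1L,
                                 k_range = 1:6, pseudocount = 1e-6) {
  pos$label <- "positive"
  neg$label <- "negative"
  plan_pos <- stratified_kfold(pos, n_folds, seed = seed)
  plan_neg <- stratified_kfold(neg, n_folds, seed = seed + 1L)
  per_fold <- vector("list", n_folds)
  fold_details <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    fseed <- as.integer(seed + f * 1009L)
    pos_test <- dataset_subset(pos, plan_pos$fold[pos$id] == f)
    pos_train <- dataset_subset(pos, plan_pos$fold[pos$id] != f)
    neg_test <- dataset_subset(neg, plan_neg$fold[neg$id] == f)
    neg_train <- dataset_subset(neg, plan_neg$fold[neg$id] != f)

    profile <- fit_class_means(pos_train, neg_train,
      k_range = k_range, pseudocount = pseudocount
    )
    train_pos <- if (!is.null(bagging)) {
      cfg_b <- bagging
      cfg_b$seed <- fseed
      weighted_bagging(pos_train, cfg_b)
    } else {
      pos_train
    }
    if (nrow(train_pos) > nrow(neg_train)) {
      stop(
        "fold ", f, ": ", nrow(neg_train), " training negatives cannot match ",
        nrow(train_pos), " (augmented) positives",
        call. = FALSE
      )
    }
    train_neg <- downsample_negatives(neg_train, nrow(train_pos), seed = fseed + 1L)

    X_train <- rbind(
      featurize_dataset(train_pos, profile),
      featurize_dataset(train_neg, profile)
    )
    y_train <- rep(c(1, 0), c(nrow(train_pos), nrow(train_neg)))
    cnn_f <- cnn
    cnn_f$seed <- fseed + 2L
    model <- train_cnn(build_model(cnn_f), X_train, y_train,
      profile = profile
    )

    test <- dataset_bind(pos_test, neg_test, name = paste0("fold", f))
    scores <- predict_proba(model, test)
    per_fold[[f]] <- evaluate_predictions(scores, test$label, model$threshold)
    fold_details[[f]] <- list(
      fold = f,
      train_pos_ids = pos_train$id,
      train_neg_ids = train_neg$id,
      test_ids = test$id,
      profile = profile,
      seed = fseed
    )
  }
  rows <- t(vapply(per_fold, report_row, numeric(length(metric_names))))
  summary <- as.data.frame(rows)
  summary$fold <- seq_len(n_folds)
  mean_row <- as.data.frame(t(colMeans(rows)))
  mean_row$fold <- NA_integer_
  summary <- rbind(summary, mean_row)
  summary <- summary[, c("fold", metric_names)]
  structure(
    list(
      per_fold = per_fold, summary = summary, plan_pos = plan_pos,
      plan_neg = plan_neg, fold_details = fold_details, seed = seed
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d fold(s)\n", length(x$per_fold)))
  print(format(x$summary, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Mean of one metric over CV folds
#'
#' @param cv A `cv_result`.
#' @param metric Metric name (e.g. `"auroc"`).
#' @return The across-fold mean.
#' @export
cv_mean <- function(cv, metric = "auroc") {
  mean(vapply(cv$per_fold, function(r) r[[metric]], numeric(1)))
}

#' Write a CV result as TSV
#'
#' @param cv A `cv_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_result <- function(cv, path) {
  utils::write.table(cv$summary, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Leave-gene-out validation
#'
#' Holds out every variant of one gene as the positive test set and trains on
#' all remaining positives. The run is repeated `reps` times; in repetition r,
#' the negatives of fold `((r-1) mod n_folds) + 1` of a stratified negative
#' split serve as the negative test data and the remaining negatives are the
#' down-sampling pool for training, so each repetition sees a fresh random
#' negative training sample.
#'
#' @param pos Positive [dataset()] with gene labels.
#' @param neg Negative [dataset()].
#' @param gene Gene to hold out.
#' @param reps Repetitions (default 5).
#' @param n_folds Folds of the negative split plan (default 5).
#' @param bagging Optional [bagging_config()] applied to the training
#'   positives.
#' @param cnn A [cnn_config()].
#' @param seed Integer seed.
#' @param k_range,pseudocount Passed to [fit_class_means()].
#' @return A `logo_result`: `per_rep` (list of `metrics_report`),
#'   `mean_auroc`, `gene`, `n_test_pos`.
#' @export
run_leave_gene_out <- function(pos, neg, gene, reps = 5L, n_folds = 5L,
                               bagging = NULL, cnn = cnn_config(), seed = 1L,
                               k_range = 1:6, pseudocount = 1e-6) {
  pos$label <- "positive"
  neg$label <- "negative"
  split <- leave_gene_out_split(pos, gene)
  plan_neg <- stratified_kfold(neg, n_folds, seed = seed + 1L)
  per_rep <- vector("list", reps)
  for (r in seq_len(reps)) {
    rseed <- as.integer(seed + r * 2003L)
    f <- ((r - 1L) %% n_folds) + 1L
    neg_test <- dataset_subset(neg, plan_neg$fold[neg$id] == f)
    neg_pool <- dataset_subset(neg, plan_neg$fold[neg$id] != f)

    profile <- fit_class_means(split$train, neg_pool,
      k_range = k_range, pseudocount = pseudocount
    )
    train_pos <- if (!is.null(bagging)) {
      cfg_b <- bagging
      cfg_b$seed <- rseed
      weighted_bagging(split$train, cfg_b)
    } else {
      split$train
    }
    train_neg <- downsample_negatives(neg_pool, nrow(train_pos), seed = rseed + 1L)
    X_train <- rbind(
      featurize_dataset(train_pos, profile),
      featurize_dataset(train_neg, profile)
    )
    y_train <- rep(c(1, 0), c(nrow(train_pos), nrow(train_neg)))
    cnn_r <- cnn
    cnn_r$seed <- rseed + 2L
    model <- train_cnn(build_model(cnn_r), X_train, y_train, profile = profile)

    test <- dataset_bind(split$test, neg_test, name = paste0("logo_rep", r))
    scores <- predict_proba(model, test)
    per_rep[[r]] <- evaluate_predictions(scores, test$label, model$threshold)
  }
  structure(
    list(
      per_rep = per_rep,
      mean_auroc = mean(vapply(per_rep, function(x) x$auroc, numeric(1))),
      gene = gene,
      n_test_pos = nrow(split$test)
    ),
    class = "logo_result"
  )
}

#' @export
print.logo_result <- function(x, ...) {
  cat(sprintf(
    "<logo_result gene=%s> %d rep(s), %d test positives, mean AUROC %.4f\n",
    x$gene, length(x$per_rep), x$n_test_pos, x$mean_auroc
  ))
  invisible(x)
}

#' Export probability-score distributions
#'
#' Writes the per-record predicted probabilities with their truth labels, the
#' data behind score-distribution plots.
#'
#' @param scores Named probability vector.
#' @param y_true Truth labels aligned with `scores`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_score_distribution <- function(scores, y_true, path) {
  utils::write.table(
    data.frame(
      id = if (is.null(names(scores))) seq_along(scores) else names(scores),
      score = unname(scores), label = as.character(y_true)
    ),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
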