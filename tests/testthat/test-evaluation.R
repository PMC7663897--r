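test_that("confusion tallies the 2x2 table with positive as class of interest", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(cm$TP, 1L)
  expect_equal(cm$FN, 1L)
  expect_equal(cm$TN, 1L)
  expect_equal(cm$FP, 1L)

  perfect <- confusion(c("positive", "negative"), c("positive", "negative"))
  expect_equal(perfect$FP + perfect$FN, 0L)

  allpos <- confusion(rep(0, 5), rep(1, 5))
  expect_equal(allpos$TN, 0L)
  expect_equal(allpos$FP, 5L)

  expect_error(confusion(c(1, 0), c(1, 0, 1)), "same length")
})

test_that("closed-form metrics follow their defining identities", {
  cm <- confusion(rep(c(1, 0), c(10, 10)), rep(c(1, 0, 1, 0), c(9, 1, 2, 8)))
  expect_equal(unlist(cm[c("TP", "FN", "FP", "TN")]), c(TP = 9, FN = 1, FP = 2, TN = 8))
  r <- metrics_from_counts(cm)
  expect_equal(r$sn, 0.9)
  expect_equal(r$sp, 0.8)
  expect_equal(r$acc, 0.85)
  expect_equal(r$hm, 2 * 0.9 * 0.8 / 1.7)
  expect_equal(r$pre, 9 / 11)
  expect_equal(r$f1, 2 * (9 / 11) * 0.9 / ((9 / 11) + 0.9))
})

test_that("metric identities hold against an independent tally on random labels", {
  withr::with_seed(30, {
    for (i in 1:100) {
      n <- sample(10:60, 1)
      yt <- rbinom(n, 1, 0.5)
      yp <- rbinom(n, 1, 0.5)
      if (length(unique(yt)) < 2 || length(unique(yp)) < 2) next
      cm <- confusion(yt, yp)
      # independent tally via table()
      tab <- table(truth = yt, pred = yp)
      expect_equal(cm$TP, unname(tab["1", "1"]))
      expect_equal(cm$TN, unname(tab["0", "0"]))
      r <- suppressWarnings(metrics_from_counts(cm))
      P <- sum(yt == 1)
      N <- sum(yt == 0)
      # accuracy is the prevalence-weighted average of sn and sp
      expect_equal(r$acc, (r$sn * P + r$sp * N) / (P + N))
      expect_lte(r$hm, max(r$sn, r$sp) + 1e-12)
    }
  })
  # hm = sn when sn = sp
  r <- metrics_from_counts(confusion(c(1, 1, 0, 0), c(1, 0, 0, 1)))
  expect_equal(r$sn, r$sp)
  expect_equal(r$hm, r$sn)
})

test_that("undefined-denominator metrics are reported absent, not zero", {
  w <- capture_warnings(r <- metrics_from_counts(confusion(rep(0, 4), rep(0, 4))))
  expect_true(any(grepl("undefined", w)))
  expect_true(is.na(r$sn))
  expect_true(is.na(r$pre))
  expect_equal(r$sp, 1)
})

test_that("AUROC is 1 for perfect separation, 0.5 for constant scores", {
  y <- rep(c(1, 0), c(5, 5))
  expect_equal(roc_curve(c(rep(0.9, 5), rep(0.1, 5)), y)$auc, 1)
  expect_equal(roc_curve(rep(0.5, 10), y)$auc, 0.5)
  expect_equal(pr_curve(c(rep(0.9, 5), rep(0.1, 5)), y)$auc, 1)
  expect_error(roc_curve(c(1.2, 0.5), c(1, 0)), "0,1")
})

test_that("trapezoidal AUROC equals the rank-statistic formulation", {
  withr::with_seed(31, {
    for (i in 1:25) {
      n <- sample(20:80, 1)
      y <- rbinom(n, 1, 0.4)
      if (length(unique(y)) < 2) next
      s <- runif(n) # continuous, ties almost surely absent
      expect_equal(roc_curve(s, y)$auc, rank_auroc(s, y), tolerance = 1e-9)
    }
  })
})

test_that("AUROC with ties agrees with pROC", {
  withr::with_seed(32, {
    for (i in 1:10) {
      n <- 50
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      s <- round(runif(n), 1) # heavy ties
      ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
      expect_equal(roc_curve(s, y)$auc, ref, tolerance = 1e-9)
    }
  })
})

test_that("step-wise AUPRC equals the average-precision oracle", {
  withr::with_seed(33, {
    for (i in 1:25) {
      n <- sample(20:60, 1)
      y <- rbinom(n, 1, 0.3)
      if (sum(y) == 0) next
      s <- runif(n)
      expect_equal(pr_curve(s, y)$auc, ap_oracle(s, y), tolerance = 1e-12)
    }
  })
})

test_that("evaluate_predictions composes thresholding and curve metrics", {
  y <- rep(c(1, 0), c(4, 6))
  s <- c(0.9, 0.8, 0.6, 0.4, 0.7, 0.3, 0.2, 0.55, 0.1, 0.05)
  r <- evaluate_predictions(s, y, threshold = 0.5)
  expect_equal(r$counts$TP, 3L)
  expect_equal(r$counts$FP, 2L)
  expect_equal(r$auroc, rank_auroc(s, y))
})

test_that("cross-validation partitions test data and guards profile leakage", {
  sets <- tiny_gap_data(n_pos = 15, n_neg = 25, len = 50)
  cv <- suppressWarnings(run_cross_validation(sets$pos, sets$neg,
    n_folds = 5,
    cnn = quick_cnn(epochs = 4, seed = 1), seed = 5
  ))
  expect_length(cv$per_fold, 5L)
  test_ids <- unlist(lapply(cv$fold_details, function(fd) fd$test_ids))
  expect_setequal(test_ids, c(sets$pos$id, sets$neg$id))
  expect_equal(length(test_ids), nrow(sets$pos) + nrow(sets$neg))

  # leakage guard: the stored fold profile is exactly the profile refitted on
  # that fold's training records alone
  fd <- cv$fold_details[[2]]
  pos_train <- sets$pos[sets$pos$id %in% fd$train_pos_ids, ]
  neg_train <- sets$neg[!(sets$neg$id %in% fd$test_ids), ]
  refit <- fit_class_means(
    dataset(pos_train$id, pos_train$seq),
    dataset(neg_train$id, neg_train$seq)
  )
  expect_equal(fd$profile$M_pos, refit$M_pos, tolerance = 1e-14)
  expect_equal(fd$profile$M_neg, refit$M_neg, tolerance = 1e-14)

  # summary holds one row per fold plus the mean row
  expect_equal(nrow(cv$summary), 6L)
  expect_equal(
    cv$summary$auroc[6],
    mean(vapply(cv$per_fold, function(x) x$auroc, numeric(1)))
  )
})

test_that("cross-validation supports bagging and negative sizing to augmented count", {
  withr::with_seed(44, {
    pos <- dataset(
      sprintf("p%02d", 1:15),
      random_dna(15, 50, probs = c(.1, .4, .4, .1)),
      label = "positive",
      subtype = rep(c("strong", "weak"), c(10, 5))
    )
    neg <- dataset(
      sprintf("n%03d", 1:150),
      random_dna(150, 50, probs = c(.4, .1, .1, .4)),
      label = "negative"
    )
  })
  cv <- suppressWarnings(run_cross_validation(pos, neg,
    n_folds = 5, bagging = bagging_config(seed = 1),
    cnn = quick_cnn(epochs = 4, seed = 1), seed = 2
  ))
  # 12 training positives per fold, tripled to 36 negatives down-sampled to match
  expect_equal(length(cv$fold_details[[1]]$train_neg_ids), 36L)
  # test folds keep the full imbalance
  expect_equal(length(cv$fold_details[[1]]$test_ids), 3L + 30L)
})

test_that("leave-gene-out produces one report per repetition", {
  sets <- tiny_gap_data(n_pos = 15, n_neg = 40, len = 50)
  res <- suppressWarnings(run_leave_gene_out(sets$pos, sets$neg,
    gene = "G01", reps = 3,
    cnn = quick_cnn(epochs = 4, seed = 1), seed = 3
  ))
  expect_length(res$per_rep, 3L)
  expect_equal(res$n_test_pos, sum(sets$pos$gene == "G01"))
  expect_equal(
    res$mean_auroc,
    mean(vapply(res$per_rep, function(x) x$auroc, numeric(1)))
  )
  expect_error(
    run_leave_gene_out(sets$pos, sets$neg, gene = "NOPE", cnn = quick_cnn()),
    "available"
  )
})

test_that("score distributions export as plain TSV", {
  f <- tempfile(fileext = ".tsv")
  write_score_distribution(c(a = 0.9, b = 0.2), c("positive", "negative"), f)
  tab <- read.delim(f)
  expect_equal(tab$id, c("a", "b"))
  expect_equal(tab$score, c(0.9, 0.2))
})
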