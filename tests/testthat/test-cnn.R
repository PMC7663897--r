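test_that("configuration validates stage arithmetic against the contract", {
  cfg <- cnn_config()
  lens <- triplexpot:::conv_stage_lengths(cfg)
  expect_equal(lens$pooled[length(lens$pooled)], 15L)
  # an architecture that cannot reach length 15 is rejected with the lengths
  expect_error(cnn_config(kernel_sizes = c(7L, 6L)), "feature-map length")
  expect_error(cnn_config(kernel_sizes = c(95L, 5L)), "exceeds")
  expect_error(cnn_config(kernel_sizes = c(7L, 13L, 3L)), "equal length")
  # a single-stage network is a valid configuration
  one <- cnn_config(
    filters_per_layer = 8L, kernel_sizes = 16L, pool_sizes = 5L
  )
  expect_equal(one$n_conv_layers, 1L)
})

test_that("weight initialization is seeded and reproducible", {
  m1 <- build_model(quick_cnn(seed = 11))
  m2 <- build_model(quick_cnn(seed = 11))
  expect_identical(m1$params, m2$params)
  m3 <- build_model(quick_cnn(seed = 12))
  expect_false(identical(m1$params, m3$params))
})

test_that("training is deterministic and the loss trends downward", {
  withr::with_seed(20, {
    X <- matrix(runif(200 * 90), 200, 90)
    y <- rep(c(1, 0), 100)
    X[y == 1, 1:10] <- X[y == 1, 1:10] + 1
  })
  cfg <- quick_cnn(epochs = 15, seed = 5)
  m1 <- train_cnn(build_model(cfg), X, y)
  m2 <- train_cnn(build_model(cfg), X, y)
  expect_identical(m1$params, m2$params)
  expect_identical(predict_proba(m1, X), predict_proba(m2, X))
  expect_lt(mean(utils::tail(m1$history, 3)), mean(utils::head(m1$history, 3)))
})

test_that("the network fits linearly separable features to high accuracy", {
  withr::with_seed(21, {
    X <- matrix(runif(120 * 90), 120, 90)
    y <- rep(c(1, 0), 60)
    X[y == 1, ] <- X[y == 1, ] + 0.8
  })
  m <- train_cnn(build_model(quick_cnn(epochs = 50, seed = 3, dropout_rate = 0)), X, y)
  acc <- mean((predict_proba(m, X) >= 0.5) == (y == 1))
  expect_gte(acc, 0.99)
})

test_that("zero-epoch training returns the initial weights", {
  withr::with_seed(22, {
    X <- matrix(runif(20 * 90), 20, 90)
    y <- rep(c(1, 0), 10)
  })
  handle <- build_model(quick_cnn(epochs = 0))
  m <- train_cnn(handle, X, y)
  expect_identical(m$params, handle$params)
  expect_length(m$history, 0L)
})

test_that("training rejects degenerate inputs", {
  X <- matrix(runif(10 * 90), 10, 90)
  handle <- build_model(quick_cnn(epochs = 1))
  expect_error(train_cnn(handle, X, rep(1, 10)), "single class")
  Xbad <- X
  Xbad[3, 5] <- NA
  expect_error(train_cnn(handle, Xbad, rep(c(1, 0), 5)), "row")
  expect_error(
    train_cnn(handle, X[, 1:50], rep(c(1, 0), 5)),
    "expected 90"
  )
})

test_that("predictions lie in [0,1], are order-aligned and duplicate-consistent", {
  sets <- tiny_gap_data()
  pr <- fit_class_means(sets$pos, sets$neg)
  X <- rbind(
    featurize_dataset(sets$pos, pr),
    featurize_dataset(sets$neg, pr)
  )
  y <- rep(c(1, 0), c(nrow(sets$pos), nrow(sets$neg)))
  m <- train_cnn(build_model(quick_cnn(epochs = 25, seed = 2)), X, y, profile = pr)

  p <- predict_proba(m, sets$pos)
  expect_equal(names(p), sets$pos$id)
  expect_true(all(p >= 0 & p <= 1))
  dup <- dataset(c("d1", "d2"), rep(sets$pos$seq[1], 2))
  pd <- predict_proba(m, dup)
  expect_equal(unname(pd[1]), unname(pd[2]))

  # held-out separation sanity: positive median above negative median
  hold <- tiny_gap_data(seed = 99)
  expect_gt(
    median(predict_proba(m, hold$pos)),
    median(predict_proba(m, hold$neg))
  )
})

test_that("classification applies the >= threshold convention monotonically", {
  sets <- tiny_gap_data()
  pr <- fit_class_means(sets$pos, sets$neg)
  X <- rbind(featurize_dataset(sets$pos, pr), featurize_dataset(sets$neg, pr))
  y <- rep(c(1, 0), c(nrow(sets$pos), nrow(sets$neg)))
  m <- train_cnn(build_model(quick_cnn(epochs = 10, seed = 2)), X, y, profile = pr)
  all_data <- triplexpot:::dataset_bind(sets$pos, sets$neg)
  p <- predict_proba(m, all_data)

  m$threshold <- unname(p[4]) # exact boundary: >= maps to positive
  cl <- classify(m, all_data)
  expect_equal(unname(cl[4]), "positive")

  m$threshold <- 1.0
  expect_true(all(classify(m, all_data)[p < 1] == "negative"))

  counts <- vapply(c(0.9, 0.5, 0.1), function(th) {
    m$threshold <- th
    sum(classify(m, all_data) == "positive")
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("save/load round trip reproduces predictions and metadata", {
  sets <- tiny_gap_data()
  pr <- fit_class_means(sets$pos, sets$neg)
  X <- rbind(featurize_dataset(sets$pos, pr), featurize_dataset(sets$neg, pr))
  y <- rep(c(1, 0), c(nrow(sets$pos), nrow(sets$neg)))
  m <- train_cnn(build_model(quick_cnn(epochs = 5, seed = 4)), X, y,
    profile = pr, model_role = "lncRNA"
  )
  dir <- tempfile()
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_equal(m2$model_role, "lncRNA")
  expect_equal(m2$threshold, m$threshold)
  probe <- dataset(
    sprintf("t%d", 1:20),
    random_dna(20, 40, seed = 31)
  )
  expect_equal(predict_proba(m2, probe), predict_proba(m, probe), tolerance = 1e-12)

  expect_error(load_model(tempfile()), "manifest")
})

test_that("feature-map export has the contracted shape and class semantics", {
  sets <- tiny_gap_data()
  pr <- fit_class_means(sets$pos, sets$neg)
  X <- rbind(featurize_dataset(sets$pos, pr), featurize_dataset(sets$neg, pr))
  y <- rep(c(1, 0), c(nrow(sets$pos), nrow(sets$neg)))
  cfg <- quick_cnn(epochs = 5, seed = 4)
  m <- train_cnn(build_model(cfg), X, y, profile = pr)
  all_data <- triplexpot:::dataset_bind(sets$pos, sets$neg)

  maps2 <- export_feature_maps(m, all_data, layer = 2)
  expect_named(maps2, c("negative", "positive"))
  expect_equal(nrow(maps2$positive), 15L)
  expect_equal(ncol(maps2$positive), cfg$filters_per_layer[2])

  # layer 0 on identical positives equals that record's feature vector
  rep_pos <- dataset(c("r1", "r2"), rep(sets$pos$seq[1], 2), label = "positive")
  one_neg <- dataset("n", sets$neg$seq[1], label = "negative")
  maps0 <- export_feature_maps(m, triplexpot:::dataset_bind(rep_pos, one_neg), layer = 0)
  expect_equal(
    unname(maps0$positive[1, ]),
    unname(featurize(sets$pos$seq[1], pr))
  )

  # identical records in both classes give identical class means at any layer
  mirror <- dataset(c("a", "b"), rep(sets$pos$seq[2], 2),
    label = c("positive", "negative")
  )
  for (layer in 0:2) {
    mm <- export_feature_maps(m, mirror, layer = layer)
    expect_equal(unname(mm$positive), unname(mm$negative))
  }

  tsv <- tempfile(fileext = ".tsv")
  export_feature_maps(m, all_data, layer = 1, path = tsv)
  expect_true(file.exists(tsv))
  expect_error(export_feature_maps(m, dataset("u", "ACGTACG"), layer = 1), "labeled")
})
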