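# One well-separated dataset shared across model tests.
sep_data <- local({
  d <- generate_dataset(small_spec(seed = 21, effect_size = 3,
                                   n_active = 200, n_inactive = 200))
  split <- split_stratified(d$labels, 0.2, seed = 21)
  list(d = d, split = split,
       X_train = d$descriptors[split$train, ], y_train = d$labels[split$train],
       X_test = d$descriptors[split$test, ], y_test = d$labels[split$test])
})

test_that("random forest separates linearly separable synthetic data", {
  m <- train_model(fast_rf_config(seed = 2), sep_data$X_train, sep_data$y_train)
  p <- predict_proba(m, sep_data$X_train)
  expect_equal(mean(hard_label(p) == sep_data$y_train), 1.0)
})

test_that("training is reproducible: same config and seed, identical predictions", {
  for (algo in c("svm", "random_forest", "xgboost", "knn")) {
    cfg <- model_config(algo, seed = 31)
    m1 <- train_model(cfg, sep_data$X_train, sep_data$y_train)
    m2 <- train_model(cfg, sep_data$X_train, sep_data$y_train)
    expect_identical(predict_proba(m1, sep_data$X_test),
                     predict_proba(m2, sep_data$X_test), label = algo)
  }
})

test_that("1-nearest-neighbour reproduces training labels on the training set", {
  cfg <- model_config("knn", list(k = 1), seed = 1)
  m <- train_model(cfg, sep_data$X_train, sep_data$y_train)
  p <- predict_proba(m, sep_data$X_train)
  expect_identical(as.character(hard_label(p)), as.character(sep_data$y_train))
  expect_true(all(p %in% c(0, 1)))
})

test_that("probabilities are bounded and complementary for every model", {
  b <- train_ensemble(sep_data$X_train, sep_data$y_train, seed = 5)
  for (m in b$models) {
    p <- predict_proba(m, sep_data$X_test)
    expect_true(all(p >= 0 & p <= 1))
    # two-class probabilities: p(active) + p(inactive) = 1 by construction
    expect_equal(p + (1 - p), rep(1, length(p)), ignore_attr = TRUE)
  }
})

test_that("each model reaches held-out AUC >= 0.85 on effect-size-2 data", {
  d <- generate_dataset(synthetic_spec(seed = 27))  # 400 compounds, d = 2
  split <- split_stratified(d$labels, 0.2, seed = 27)
  b <- train_ensemble(d$descriptors[split$train, ], d$labels[split$train],
                      seed = 27)
  for (m in b$models) {
    p <- predict_proba(m, d$descriptors[split$test, ])
    expect_gte(roc_auc(d$labels[split$test], p)$auc, 0.85)
  }
})

test_that("consensus is the unanimity rule and shrinks with the threshold", {
  b <- train_ensemble(sep_data$X_train, sep_data$y_train, seed = 7)
  pr <- predict_ensemble(b, sep_data$X_test)
  P <- as.matrix(pr[, c("p_svm", "p_rf", "p_xgb", "p_knn")])
  expect_equal(pr$consensus_active, rowSums(P >= 0.5) == 4)
  # consensus-active set is a subset of each model's active set
  for (col in colnames(P)) {
    expect_true(all(P[pr$consensus_active, col] >= 0.5))
  }
  # count non-increasing as any per-model threshold rises
  for (thr in c(0.5, 0.6, 0.8, 0.9)) {
    expect_lte(sum(rowSums(P >= thr) == 4), sum(rowSums(P >= 0.5) == 4))
  }
})

test_that("ensemble construction rejects duplicate or incomplete configs", {
  cfgs <- default_ensemble_configs(1)
  expect_error(train_ensemble(sep_data$X_train, sep_data$y_train,
                              configs = cfgs[c(1, 1, 2, 3)]), "duplicate")
  expect_error(train_ensemble(sep_data$X_train, sep_data$y_train,
                              configs = cfgs[1:3]), "exactly one")
})

test_that("prediction validates descriptor names and finiteness", {
  m <- train_model(fast_rf_config(), sep_data$X_train, sep_data$y_train)
  expect_error(predict_proba(m, sep_data$X_test[, -1]),
               colnames(sep_data$X_test)[1])
  Xbad <- sep_data$X_test
  Xbad[2, 3] <- NA
  expect_error(predict_proba(m, Xbad), rownames(Xbad)[2])
  # column order is irrelevant
  perm <- rev(seq_len(ncol(sep_data$X_test)))
  expect_identical(predict_proba(m, sep_data$X_test),
                   predict_proba(m, sep_data$X_test[, perm]))
})

test_that("single-class training data is rejected", {
  X <- sep_data$X_train[1:10, ]
  expect_error(train_model(fast_rf_config(), X, rep("active", 10)),
               "both classes")
})
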