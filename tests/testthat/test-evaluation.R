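test_that("confusion counts follow the standard definitions", {
  y <- rep(c("active", "inactive"), each = 10)
  cc <- confusion_counts(y, y)
  expect_equal(unclass(cc)[c("tp", "fp", "tn", "fn")],
               list(tp = 10L, fp = 0L, tn = 10L, fn = 0L))

  y5 <- c(rep("active", 5), rep("inactive", 15))
  cc2 <- confusion_counts(y5, rep("active", 20))
  expect_equal(unclass(cc2)[c("tp", "fp", "tn", "fn")],
               list(tp = 5L, fp = 15L, tn = 0L, fn = 0L))
  expect_equal(cc2$tp + cc2$fp + cc2$tn + cc2$fn, 20L)

  expect_error(confusion_counts(y, y[-1]), "equal length")
})

test_that("metrics match hand arithmetic and a perfect classifier scores 1", {
  m <- classification_metrics(list(tp = 8, fp = 2, tn = 8, fn = 2))
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$f1, 0.8)

  perfect <- classification_metrics(list(tp = 7, fp = 0, tn = 3, fn = 0))
  expect_equal(unlist(perfect[c("precision", "recall", "accuracy", "f1")]),
               c(precision = 1, recall = 1, accuracy = 1, f1 = 1))
})

test_that("zero-denominator metrics are undefined with a reason, not zero", {
  m <- classification_metrics(list(tp = 0, fp = 0, tn = 5, fn = 5))
  expect_true(is.na(m$precision))
  expect_match(m$undefined[["precision"]], "TP \\+ FP")
  expect_equal(m$recall, 0)
  expect_true(is.na(m$f1))

  m2 <- classification_metrics(list(tp = 0, fp = 3, tn = 7, fn = 0))
  expect_true(is.na(m2$recall))
  expect_equal(m2$precision, 0)

  expect_error(classification_metrics(list(tp = 0, fp = 0, tn = 0, fn = 0)),
               "all counts zero")
})

test_that("metrics agree with direct formulas on enumerated confusion matrices", {
  # all matrices with n <= 12 here; the full n <= 30 sweep runs in the
  # acceptance suite
  for (n in 1:12) {
    for (tp in 0:n) for (fp in 0:(n - tp)) for (tn in 0:(n - tp - fp)) {
      fn <- n - tp - fp - tn
      m <- classification_metrics(list(tp = tp, fp = fp, tn = tn, fn = fn))
      expect_equal(m$accuracy, (tp + tn) / n)
      if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
      if (tp + fn > 0) expect_equal(m$recall, tp / (tp + fn))
    }
  }
})

test_that("rank-based AUC matches separation, ties and the all-pairs oracle", {
  y <- c(rep("active", 3), rep("inactive", 3))
  expect_equal(roc_auc(y, c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1))$auc, 1.0)
  expect_equal(roc_auc(y, rep(0.5, 6))$auc, 0.5)
  expect_error(roc_auc(rep("active", 4), runif(4)), "both classes")

  withr::with_seed(13, {
    y2 <- sample(c("active", "inactive"), 60, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(y2)) == 1) y2[1] <- setdiff(c("active", "inactive"), y2)[1]
    s <- round(runif(60), 2)  # rounding forces ties
  })
  expect_equal(roc_auc(y2, s)$auc, auc_brute(y2, s), tolerance = 1e-12)
})

test_that("AUC is antisymmetric under score reversal and matches pROC", {
  skip_if_not_installed("pROC")
  withr::with_seed(14, {
    y <- sample(c("active", "inactive"), 80, replace = TRUE)
    y[1:2] <- c("active", "inactive")
    s <- runif(80)
  })
  a <- roc_auc(y, s)$auc
  expect_equal(a + roc_auc(y, 1 - s)$auc, 1)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = s, levels = c("inactive", "active"),
    direction = "<", quiet = TRUE)))
  expect_equal(a, ref, tolerance = 1e-12)
})

test_that("cumulative gain captures all actives at depth one and is monotone", {
  # perfect ranking, prevalence 0.2: all actives in the top quintile
  y <- c(rep("active", 20), rep("inactive", 80))
  s <- seq(1, 0.01, length.out = 100)
  g <- cumulative_gain(y, s, depths = c(0.2, 0.5, 1))
  expect_equal(g$gain, c(1, 1, 1))

  withr::with_seed(15, s2 <- runif(100))
  g2 <- cumulative_gain(y, s2)
  expect_true(all(diff(g2$gain) >= 0))
  expect_equal(g2$gain[g2$depth == 1], 1)
  # random scores track the diagonal within sampling error
  expect_lt(max(abs(g2$gain - g2$depth)), 0.3)

  expect_error(cumulative_gain(y, s, depths = numeric()), "non-empty")
  expect_error(cumulative_gain(y, s, depths = c(0, 0.5)), "\\(0, 1\\]")
})

test_that("outcome-stratified probabilities respect the 0.5 hard-label rule", {
  withr::with_seed(16, {
    y <- sample(c("active", "inactive"), 100, replace = TRUE)
    p <- runif(100)
  })
  out <- probability_by_outcome(y, p)
  expect_true(all(out$tp$values >= 0.5))
  expect_true(all(out$fp$values >= 0.5))
  expect_true(all(out$tn$values < 0.5))
  expect_true(all(out$fn$values < 0.5))
  expect_gte(out$tp$mean, 0.5)
  expect_equal(out$tp$n + out$tn$n + out$fp$n + out$fn$n, 100L)

  # empty groups are reported as empty, not dropped
  clean <- probability_by_outcome(c("active", "inactive"), c(0.9, 0.1))
  expect_equal(clean$fp$n, 0L)
  expect_true(is.na(clean$fp$mean))
})

test_that("a well-separated model scores confident TPs above its FPs", {
  d <- generate_dataset(synthetic_spec(seed = 33))
  split <- split_stratified(d$labels, 0.2, seed = 33)
  m <- train_model(fast_rf_config(seed = 33),
                   d$descriptors[split$train, ], d$labels[split$train])
  p <- predict_proba(m, d$descriptors[split$test, ])
  out <- probability_by_outcome(d$labels[split$test], p)
  expect_gt(out$tp$mean, 0.5)
  if (out$fp$n > 0) expect_gt(out$tp$mean, out$fp$mean)
  if (out$tn$n > 0) expect_lt(out$tn$mean, 0.5)
})
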