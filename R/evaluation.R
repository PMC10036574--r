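#' Confusion-matrix counts for binary activity predictions
#'
#' Tabulates true/false positives/negatives with "active" as the positive
#' class.
#'
#' @param y_true,y_pred equal-length vectors of "active"/"inactive" labels.
#' @return object of class `confusion_counts`: list(tp, fp, tn, fn).
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  y_true <- as_activity_factor(y_true)
  y_pred <- as_activity_factor(y_pred)
  structure(list(
    tp = sum(y_true == "active" & y_pred == "active"),
    fp = sum(y_true == "inactive" & y_pred == "active"),
    tn = sum(y_true == "inactive" & y_pred == "inactive"),
    fn = sum(y_true == "active" & y_pred == "inactive")
  ), class = "confusion_counts")
}

#' Precision, recall, accuracy and F1 from confusion counts
#'
#' Standard definitions: precision = TP/(TP+FP), recall = TP/(TP+FN),
#' accuracy = (TP+TN)/(TP+TN+FP+FN), F1 = 2PR/(P+R) (the harmonic mean of
#' precision and recall). A ratio with zero denominator is *undefined*, not
#' zero: the corresponding metric is returned as `NA` and the reason is
#' listed in the `undefined` field.
#'
#' @param counts a [confusion_counts()] object, or a list with tp/fp/tn/fn.
#' @return object of class `metrics_report`: precision, recall, accuracy,
#'   f1, auc (`NA` here; fill from [roc_auc()]), counts, and `undefined`
#'   (named character vector of reasons for NA metrics).
#' @examples
#' m <- classification_metrics(list(tp = 8, fp = 2, tn = 8, fn = 2))
#' m$precision  # 0.8
#' @export
classification_metrics <- function(counts) {
  counts <- lapply(counts[c("tp", "fp", "tn", "fn")], as.numeric)
  if (any(vapply(counts, function(x) is.na(x) || x < 0, logical(1)))) {
    stop("counts must be non-negative numbers", call. = FALSE)
  }
  n <- with(counts, tp + fp + tn + fn)
  if (n == 0) stop("no evaluated compounds (all counts zero)", call. = FALSE)

  undefined <- character()
  precision <- recall <- f1 <- NA_real_
  if (counts$tp + counts$fp > 0) {
    precision <- counts$tp / (counts$tp + counts$fp)
  } else {
    undefined["precision"] <- "no predicted actives (TP + FP = 0)"
  }
  if (counts$tp + counts$fn > 0) {
    recall <- counts$tp / (counts$tp + counts$fn)
  } else {
    undefined["recall"] <- "no true actives (TP + FN = 0)"
  }
  accuracy <- (counts$tp + counts$tn) / n
  if (is.na(precision) || is.na(recall)) {
    undefined["f1"] <- "precision or recall undefined"
  } else if (precision + recall == 0) {
    undefined["f1"] <- "precision + recall = 0"
  } else {
    f1 <- 2 * precision * recall / (precision + recall)
  }
  structure(list(
    precision = precision, recall = recall, accuracy = accuracy, f1 = f1,
    auc = NA_real_, counts = counts, undefined = undefined
  ), class = "metrics_report")
}

#' ROC AUC by the rank (Mann-Whitney) formulation
#'
#' The AUC is computed as the probability that a randomly chosen active
#' outscores a randomly chosen inactive, with ties counted one half —
#' i.e. the Mann-Whitney U statistic over midranks, which is exactly the
#' area under the empirical ROC curve with trapezoidal tie handling.
#' ROC curve points are returned for plotting.
#'
#' @param y_true "active"/"inactive" labels, both classes present.
#' @param scores numeric scores (higher = more active).
#' @return list with `auc` and `curve` (data.frame: threshold, fpr, tpr).
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- check_both_classes(y_true)
  if (length(y_true) != length(scores)) {
    stop("y_true and scores must have equal length", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  pos <- y_true == "active"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(pos & scores >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(!pos & scores >= t) / n0, numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  list(auc = auc, curve = curve)
}

#' Cumulative gain curve
#'
#' Fraction of all true actives captured within the top-scoring fraction of
#' the set: compounds are sorted by score descending (stable — ties keep
#' input order) and `gain(d)` is the number of actives among the top
#' `ceiling(d * n)` compounds divided by the total number of actives.
#'
#' @param y_true "active"/"inactive" labels, both classes present.
#' @param scores numeric scores.
#' @param depths fractions in `(0, 1]` at which to evaluate the gain.
#' @return data.frame (depth, n_top, n_active_captured, gain); gain at
#'   depth 1 is always 1.
#' @export
cumulative_gain <- function(y_true, scores,
                            depths = seq(0.05, 1, by = 0.05)) {
  y_true <- check_both_classes(y_true)
  if (length(y_true) != length(scores)) {
    stop("y_true and scores must have equal length", call. = FALSE)
  }
  if (length(depths) == 0) stop("depths must be non-empty", call. = FALSE)
  if (any(depths <= 0 | depths > 1)) stop("depths must lie in (0, 1]", call. = FALSE)
  n <- length(scores)
  ord <- order(-scores, seq_len(n))  # stable: ties by input position
  is_active <- (y_true == "active")[ord]
  cum_act <- cumsum(is_active)
  total <- sum(is_active)
  n_top <- ceiling(depths * n)
  data.frame(
    depth = depths, n_top = n_top,
    n_active_captured = cum_act[n_top],
    gain = cum_act[n_top] / total
  )
}

#' Probability-score distributions stratified by prediction outcome
#'
#' Splits compounds into TP/TN/FP/FN groups using the hard-label rule
#' (active iff probability >= 0.5) against the true labels, and summarises
#' the probability scores within each group. High mean TP and low mean TN
#' probabilities indicate confident correct predictions; FP/FN means near
#' 0.5 indicate that errors are borderline calls.
#'
#' @param y_true "active"/"inactive" labels, both classes present.
#' @param probabilities probability of the active class in `[0, 1]`.
#' @return list with one element per outcome (`tp`, `tn`, `fp`, `fn`), each
#'   a list of `values`, `n`, `mean`, `quartiles`; empty groups have
#'   `n = 0` and `NA` summaries.
#' @export
probability_by_outcome <- function(y_true, probabilities) {
  y_true <- check_both_classes(y_true)
  p <- as.numeric(probabilities)
  if (length(y_true) != length(p)) {
    stop("y_true and probabilities must have equal length", call. = FALSE)
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  pred <- hard_label(p)
  grp <- list(
    tp = y_true == "active" & pred == "active",
    tn = y_true == "inactive" & pred == "inactive",
    fp = y_true == "inactive" & pred == "active",
    fn = y_true == "active" & pred == "inactive"
  )
  lapply(grp, function(g) {
    v <- p[g]
    if (length(v) == 0) {
      list(values = numeric(), n = 0L, mean = NA_real_,
           quartiles = c(`25%` = NA_real_, `50%` = NA_real_, `75%` = NA_real_))
    } else {
      list(values = v, n = length(v), mean = mean(v),
           quartiles = quantile(v, c(0.25, 0.5, 0.75)))
    }
  })
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  cat("Classification metrics (positive class = active):\n")
  cat(sprintf("  precision %s  recall %s  accuracy %s  F1 %s  AUC %s\n",
              fmt(x$precision), fmt(x$recall), fmt(x$accuracy),
              fmt(x$f1), fmt(x$auc)))
  with(x$counts, cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", tp, fp, tn, fn)))
  if (length(x$undefined)) {
    for (nm in names(x$undefined)) cat("  note:", nm, "-", x$undefined[[nm]], "\n")
  }
  invisible(x)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts: TP %d  FP %d  TN %d  FN %d (n = %d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}
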