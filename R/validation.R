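#' Fit a PCA applicability domain
#'
#' Defines the applicability domain (AD) of a model as an axis-aligned box
#' in the space of the first `n_components` principal components of the
#' standardised training descriptors. A query compound is inside the AD iff
#' each of its component scores lies within the training-score range for
#' that component, optionally expanded by `margin` times the range on each
#' side. The box criterion mirrors the usual PC1/PC2 scatter-plot argument
#' for training/test chemical-space overlap while staying deterministic.
#'
#' @param X_train training descriptor matrix (>= 3 compounds). Zero-variance
#'   descriptors are dropped with a warning.
#' @param n_components number of principal components (default 2).
#' @param margin fractional expansion of each bound (default 0, the exact
#'   training range).
#' @return object of class `ad_model`: standardisation vectors, loadings
#'   (descriptors x components, orthonormal), per-component `bounds`
#'   (components x 2), component standard deviations, descriptor names.
#' @export
fit_ad <- function(X_train, n_components = 2L, margin = 0) {
  X_train <- descriptor_matrix(X_train)
  if (nrow(X_train) < 3) stop("need at least 3 training compounds", call. = FALSE)
  if (margin < 0) stop("margin must be >= 0", call. = FALSE)
  sds <- apply(X_train, 2, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance descriptor(s): ",
            paste(colnames(X_train)[sds == 0], collapse = ", "), call. = FALSE)
    X_train <- X_train[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  n_components <- as.integer(n_components)
  pca <- prcomp(X_train, center = TRUE, scale. = TRUE)
  rank_x <- sum(pca$sdev > max(pca$sdev) * 1e-8)
  if (n_components < 1L || n_components > rank_x) {
    stop("n_components must lie in [1, rank(X)] = [1, ", rank_x, "]", call. = FALSE)
  }
  scores <- pca$x[, seq_len(n_components), drop = FALSE]
  rng <- apply(scores, 2, range)           # 2 x k (min; max)
  width <- rng[2, ] - rng[1, ]
  bounds <- cbind(lower = rng[1, ] - margin * width,
                  upper = rng[2, ] + margin * width)
  structure(list(
    center = pca$center, scale_sd = pca$scale,
    loadings = pca$rotation[, seq_len(n_components), drop = FALSE],
    sdev = pca$sdev[seq_len(n_components)],
    bounds = bounds, margin = margin,
    n_components = n_components,
    descriptor_names = colnames(X_train)
  ), class = "ad_model")
}

#' Applicability-domain membership of query compounds
#'
#' Projects query compounds onto the AD's principal components (using the
#' training standardisation) and flags each as inside iff every component
#' score lies within its bounds. Matching is by descriptor name, so the
#' query column order is irrelevant.
#'
#' @param ad an [fit_ad()] model.
#' @param X_query descriptor matrix covering the AD's descriptor names.
#' @return data.frame: compound_id, inside (logical), and one `PCk` score
#'   column per component (for chemical-space plotting).
#' @export
in_ad <- function(ad, X_query) {
  stopifnot(inherits(ad, "ad_model"))
  X_query <- as.matrix(X_query)
  missing <- setdiff(ad$descriptor_names, colnames(X_query))
  if (length(missing) > 0) {
    stop("missing descriptor(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  Xq <- X_query[, ad$descriptor_names, drop = FALSE]
  if (any(!is.finite(Xq))) stop("non-finite descriptor values in query", call. = FALSE)
  Z <- sweep(sweep(Xq, 2, ad$center), 2, ad$scale_sd, "/")
  scores <- Z %*% ad$loadings
  inside <- rep(TRUE, nrow(scores))
  for (k in seq_len(ad$n_components)) {
    inside <- inside & scores[, k] >= ad$bounds[k, "lower"] &
      scores[, k] <= ad$bounds[k, "upper"]
  }
  out <- data.frame(
    compound_id = rownames(Xq) %||% as.character(seq_len(nrow(Xq))),
    inside = inside, row.names = NULL, stringsAsFactors = FALSE
  )
  colnames(scores) <- paste0("PC", seq_len(ad$n_components))
  cbind(out, as.data.frame(scores, row.names = NULL))
}

# Train one model and score it on the test partition. Shared by the
# reference fit and every scrambled run so that a degenerate run (full
# resample, no permutation) reproduces the reference exactly.
train_and_score <- function(config, X, y, X_test, y_test) {
  m <- train_model(config, X, y)
  p <- predict_proba(m, X_test)
  list(
    accuracy = mean(hard_label(p) == y_test),
    auc = roc_auc(y_test, p)$auc
  )
}

#' Y-randomization robustness test
#'
#' Retrains the model on scrambled activity labels to check that its
#' performance cannot arise from chance correlation. Each run draws
#' `ceiling(resample_fraction * n)` training compounds without replacement,
#' permutes their labels, retrains with the identical configuration
#' (hyperparameters and training seed), and records accuracy and AUC on the
#' untouched test set against the true test labels. The reference model is
#' trained once on the unscrambled training set under the same protocol. A
#' genuine structure-activity relationship shows as a reference accuracy
#' clearly above the whole scrambled distribution, whose mean should sit at
#' chance level.
#'
#' Run `i` derives its sampling/permutation seed as `seed + i`, so any
#' single run is independently reproducible.
#'
#' @param X,y training descriptors and labels.
#' @param config [model_config()] used for every fit.
#' @param X_test,y_test held-out evaluation partition (true labels).
#' @param n_runs number of scrambled runs (default 500).
#' @param resample_fraction fraction of training compounds drawn per run,
#'   in `(0, 1]` (default 0.5).
#' @param seed master seed for the per-run draws.
#' @param permute permute the drawn labels (default TRUE). `FALSE` is a
#'   diagnostic mode: with `resample_fraction = 1` it reproduces the
#'   reference scores exactly.
#' @return object of class `y_randomization_result`: `runs` (data.frame:
#'   run, accuracy, auc), `mean_accuracy`, `max_accuracy`, `mean_auc`,
#'   `max_auc`, `reference` (accuracy, auc), `n_redraws`.
#' @export
y_randomization <- function(X, y, config, X_test, y_test,
                            n_runs = 500L, resample_fraction = 0.5,
                            seed = 1L, permute = TRUE) {
  X <- descriptor_matrix(X)
  y <- check_both_classes(y)
  y_test <- check_both_classes(y_test)
  if (resample_fraction <= 0 || resample_fraction > 1) {
    stop("resample_fraction must lie in (0, 1]", call. = FALSE)
  }
  n <- nrow(X)
  m <- ceiling(resample_fraction * n)
  reference <- train_and_score(config, X, y, X_test, y_test)

  acc <- auc <- numeric(n_runs)
  n_redraws <- 0L
  for (i in seq_len(n_runs)) {
    run <- with_seed(seed + i, {
      repeat {
        idx <- sort(sample.int(n, m))
        y_sub <- y[idx]
        if (length(unique(y_sub)) == 2L) break
        n_redraws <- n_redraws + 1L
      }
      if (permute) y_sub <- sample(y_sub)
      train_and_score(config, X[idx, , drop = FALSE], y_sub, X_test, y_test)
    })
    acc[i] <- run$accuracy
    auc[i] <- run$auc
  }
  structure(list(
    runs = data.frame(run = seq_len(n_runs), accuracy = acc, auc = auc),
    mean_accuracy = mean(acc), max_accuracy = max(acc),
    mean_auc = mean(auc), max_auc = max(auc),
    reference = reference, n_redraws = n_redraws,
    n_runs = n_runs, resample_fraction = resample_fraction
  ), class = "y_randomization_result")
}

#' @export
print.y_randomization_result <- function(x, ...) {
  cat(sprintf("Y-randomization: %d runs, %.0f%% of training compounds resampled per run\n",
              x$n_runs, 100 * x$resample_fraction))
  cat(sprintf("  scrambled accuracy: mean %.3f, max %.3f\n",
              x$mean_accuracy, x$max_accuracy))
  cat(sprintf("  scrambled AUC:      mean %.3f, max %.3f\n",
              x$mean_auc, x$max_auc))
  cat(sprintf("  reference model:    accuracy %.3f, AUC %.3f\n",
              x$reference$accuracy, x$reference$auc))
  invisible(x)
}

#' @export
print.ad_model <- function(x, ...) {
  cat(sprintf("PCA applicability domain: %d components over %d descriptors (margin %.2g)\n",
              x$n_components, length(x$descriptor_names), x$margin))
  invisible(x)
}
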