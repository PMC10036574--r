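#' Configuration for one classifier of the ensemble
#'
#' The four algorithms of the consensus ensemble. Hyperparameter defaults:
#' random forest 500 trees; XGBoost 300 rounds, depth 6, learning rate 0.1;
#' SVM radial kernel, cost 1, with Platt probability calibration; kNN k = 5
#' with inverse-distance-weighted vote fraction as the probability.
#' Descriptors are standardised (training mean/SD) inside the SVM and kNN
#' paths; the tree models consume raw values.
#'
#' @param algorithm one of `"svm"`, `"random_forest"`, `"xgboost"`, `"knn"`.
#' @param hyperparameters named list overriding the defaults above.
#' @param seed integer seed making training reproducible.
#' @return object of class `model_config`.
#' @export
model_config <- function(algorithm = c("svm", "random_forest", "xgboost", "knn"),
                         hyperparameters = list(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    svm = list(kernel = "radial", cost = 1),
    random_forest = list(ntree = 500L),
    xgboost = list(nrounds = 300L, max_depth = 6L, eta = 0.1),
    knn = list(k = 5L)
  )
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(algorithm = algorithm, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Default configuration set for the four-model ensemble
#'
#' @param seed master seed; model `i` uses `seed + i - 1`.
#' @return named list of four [model_config()]s.
#' @export
default_ensemble_configs <- function(seed = 1L) {
  algos <- c("svm", "random_forest", "xgboost", "knn")
  stats::setNames(
    lapply(seq_along(algos), function(i) model_config(algos[i], seed = seed + i - 1L)),
    algos
  )
}

#' Train one probabilistic activity classifier
#'
#' @param config a [model_config()].
#' @param X training descriptor matrix.
#' @param y activity labels (both classes present).
#' @return object of class `qsar_model` exposing [predict_proba()] over the
#'   training descriptor names.
#' @export
train_model <- function(config, X, y) {
  stopifnot(inherits(config, "model_config"))
  X <- descriptor_matrix(X)
  y <- check_both_classes(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  hp <- config$hyperparameters

  center <- scale_sd <- NULL
  if (config$algorithm %in% c("svm", "knn")) {
    center <- colMeans(X)
    scale_sd <- apply(X, 2, sd)
    scale_sd[scale_sd == 0] <- 1  # constant columns pass through unscaled
  }
  standardize <- function(M) sweep(sweep(M, 2, center), 2, scale_sd, "/")

  fit <- with_seed(config$seed, switch(config$algorithm,
    svm = e1071::svm(
      x = standardize(X), y = y, probability = TRUE,
      kernel = hp$kernel, cost = hp$cost
    ),
    random_forest = randomForest::randomForest(
      x = X, y = y, ntree = hp$ntree
    ),
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                    eta = hp$eta, nthread = 1, seed = config$seed),
      data = xgboost::xgb.DMatrix(X, label = as.numeric(y == "active"),
                                  nthread = 1),
      nrounds = hp$nrounds
    ),
    knn = list(X = standardize(X), y = y, k = hp$k)
  ))

  structure(list(
    algorithm = config$algorithm, fit = fit, config = config,
    descriptor_names = colnames(X), center = center, scale_sd = scale_sd
  ), class = "qsar_model")
}

#' Probability of the active class for new compounds
#'
#' Returns the calibrated probability of activity for each row of `X`. The
#' hard-label rule throughout the package is: active iff probability >= 0.5
#' (boundary inclusive); see [hard_label()].
#'
#' @param model a trained [train_model()] object.
#' @param X descriptor matrix whose columns cover the training descriptors
#'   (extra columns ignored, order-free).
#' @return named numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "qsar_model"))
  X <- as.matrix(X)
  missing <- setdiff(model$descriptor_names, colnames(X))
  if (length(missing) > 0) {
    stop("descriptor mismatch; missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- X[, model$descriptor_names, drop = FALSE]
  if (any(!is.finite(X))) {
    bad <- rownames(X)[unique(which(!is.finite(X), arr.ind = TRUE)[, 1])]
    if (is.null(bad)) bad <- unique(which(!is.finite(X), arr.ind = TRUE)[, 1])
    stop("non-finite descriptor value(s) for row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  standardize <- function(M) sweep(sweep(M, 2, model$center), 2, model$scale_sd, "/")

  p <- switch(model$algorithm,
    svm = {
      pr <- predict(model$fit, standardize(X), probability = TRUE)
      attr(pr, "probabilities")[, "active"]
    },
    random_forest = predict(model$fit, X, type = "prob")[, "active"],
    xgboost = predict(model$fit, xgboost::xgb.DMatrix(X, nthread = 1)),
    knn = knn_proba(model$fit, standardize(X))
  )
  p <- pmin(1, pmax(0, as.numeric(p)))
  names(p) <- rownames(X)
  p
}

# kNN probability: inverse-distance-weighted active-vote fraction over the
# k nearest training compounds. Zero-distance neighbours carry infinite
# weight, so an exact match returns the active fraction among its matches
# (k = 1 on a training point reproduces its own label).
knn_proba <- function(fit, Xq) {
  k <- fit$k
  act <- fit$y == "active"
  apply(Xq, 1, function(q) {
    d <- sqrt(colSums((t(fit$X) - q)^2))
    nn <- order(d)[seq_len(min(k, length(d)))]
    dn <- d[nn]
    if (any(dn == 0)) {
      mean(act[nn][dn == 0])
    } else {
      w <- 1 / dn
      sum(w * act[nn]) / sum(w)
    }
  })
}

#' Hard activity label from a probability score
#'
#' A compound with probability score >= 0.5 is classified active; below 0.5,
#' inactive (a score of exactly 0.5 is active).
#'
#' @param p probabilities in `[0, 1]`.
#' @return factor with levels active/inactive.
#' @export
hard_label <- function(p) {
  factor(ifelse(p >= 0.5, "active", "inactive"), levels = activity_levels)
}

#' Train the four-classifier consensus ensemble
#'
#' Fits all four algorithms on the same descriptor matrix and label vector
#' and bundles them with training metadata. The consensus rule is
#' unanimity: a compound is consensus-active iff all four models call it
#' active (probability >= 0.5).
#'
#' @param X training descriptor matrix.
#' @param y activity labels.
#' @param configs list of exactly one [model_config()] per algorithm;
#'   defaults to [default_ensemble_configs()].
#' @param seed master seed used when `configs` is not supplied.
#' @return object of class `ensemble_bundle`: `models` (named list),
#'   `descriptor_names`, `data_hash`, `n_train`, `configs`.
#' @export
train_ensemble <- function(X, y, configs = default_ensemble_configs(seed),
                           seed = 1L) {
  X <- descriptor_matrix(X)
  y <- check_both_classes(y)
  algos <- vapply(configs, function(cf) cf$algorithm, character(1))
  if (anyDuplicated(algos)) {
    stop("duplicate algorithm in configs: ",
         paste(unique(algos[duplicated(algos)]), collapse = ", "), call. = FALSE)
  }
  required <- c("svm", "random_forest", "xgboost", "knn")
  if (!setequal(algos, required)) {
    stop("configs must contain exactly one of each: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  models <- lapply(configs, function(cf) train_model(cf, X, y))
  names(models) <- algos
  structure(list(
    models = models[required],
    descriptor_names = colnames(X),
    data_hash = rlang::hash(list(unname(X), as.character(y))),
    n_train = nrow(X),
    configs = configs
  ), class = "ensemble_bundle")
}

#' Per-model probabilities and consensus call for new compounds
#'
#' @param bundle an [train_ensemble()] bundle.
#' @param X descriptor matrix.
#' @return data.frame: compound_id, p_svm, p_rf, p_xgb, p_knn, mean_p,
#'   consensus_active (TRUE iff all four probabilities >= 0.5).
#' @export
predict_ensemble <- function(bundle, X) {
  stopifnot(inherits(bundle, "ensemble_bundle"))
  X <- as.matrix(X)
  P <- vapply(bundle$models, function(m) predict_proba(m, X), numeric(nrow(X)))
  if (nrow(X) == 1) P <- matrix(P, nrow = 1, dimnames = list(NULL, names(bundle$models)))
  ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  data.frame(
    compound_id = ids,
    p_svm = P[, "svm"], p_rf = P[, "random_forest"],
    p_xgb = P[, "xgboost"], p_knn = P[, "knn"],
    mean_p = rowMeans(P),
    consensus_active = rowSums(P >= 0.5) == 4L,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @export
print.qsar_model <- function(x, ...) {
  cat(sprintf("QSAR classifier: %s (%d descriptors, seed %d)\n",
              x$algorithm, length(x$descriptor_names), x$config$seed))
  invisible(x)
}

#' @export
print.ensemble_bundle <- function(x, ...) {
  cat(sprintf("Four-model consensus ensemble (%d descriptors, %d training compounds)\n",
              length(x$descriptor_names), x$n_train))
  cat("  models:", paste(names(x$models), collapse = ", "), "\n")
  cat("  data hash:", x$data_hash, "\n")
  invisible(x)
}
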