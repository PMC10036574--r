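#' Prune highly correlated descriptor pairs
#'
#' First tier of descriptor reduction: whenever two surviving descriptors
#' show absolute Pearson correlation above `threshold`, one member of the
#' pair is chosen at random (seeded) and dropped. Redundancy is
#' sign-agnostic, so anticorrelated pairs count as redundant. Pairs are
#' resolved greedily scanning the upper triangle in descriptor-name order,
#' which makes the decision sequence deterministic given the seed and
#' invariant to the input column order. Zero-variance descriptors, for which
#' correlation is undefined, are dropped with a warning beforehand.
#'
#' @param X descriptor matrix (see [descriptor_matrix()]), >= 2 compounds.
#' @param threshold absolute-correlation cutoff in `[0, 1]`; pairs with
#'   `|r| > threshold` are reduced (default 0.85).
#' @param seed integer seed driving the random pick within each pair.
#' @return list with `X` (surviving columns, original column order),
#'   `drop_log` (data.frame: kept, dropped, r — one row per resolved pair)
#'   and `dropped_constant` (names of zero-variance descriptors).
#' @export
correlation_filter <- function(X, threshold = 0.85, seed = 1L) {
  X <- descriptor_matrix(X)
  if (nrow(X) < 2) stop("need at least 2 compounds", call. = FALSE)
  if (threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  sds <- apply(X, 2, sd)
  dropped_constant <- colnames(X)[sds == 0]
  if (length(dropped_constant) > 0) {
    warning("dropping zero-variance descriptor(s): ",
            paste(dropped_constant, collapse = ", "), call. = FALSE)
    X <- X[, sds > 0, drop = FALSE]
  }
  nm <- sort(colnames(X))
  cm <- cor(X[, nm, drop = FALSE])
  alive <- setNames(rep(TRUE, length(nm)), nm)
  log_rows <- list()
  with_seed(seed, {
    for (i in seq_along(nm)) {
      if (!alive[i]) next
      for (j in seq_along(nm)) {
        if (j <= i || !alive[i] || !alive[j]) next
        r <- cm[i, j]
        if (abs(r) > threshold) {
          drop_j <- sample(c(TRUE, FALSE), 1)
          drop_idx <- if (drop_j) j else i
          keep_idx <- if (drop_j) i else j
          alive[drop_idx] <- FALSE
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            kept = nm[keep_idx], dropped = nm[drop_idx], r = r,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  })
  drop_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(kept = character(), dropped = character(), r = numeric(),
               stringsAsFactors = FALSE)
  keep_names <- colnames(X)[colnames(X) %in% nm[alive]]
  list(X = X[, keep_names, drop = FALSE], drop_log = drop_log,
       dropped_constant = dropped_constant)
}

#' Boruta shadow-feature descriptor selection
#'
#' Second tier of descriptor reduction: the all-relevant Boruta procedure.
#' Each iteration appends a *shadow* copy of every candidate descriptor
#' (its values permuted across compounds, destroying any association with
#' the labels), fits a random-forest importance estimator on the augmented
#' matrix, and scores a *hit* for every real descriptor whose importance
#' exceeds the maximum shadow importance of that iteration. Under the null
#' a descriptor's hit count is Binomial(`n_iterations`, 0.5) against the
#' max-shadow benchmark only if it is competitive with noise; descriptors
#' whose hit counts are significantly above (below) the binomial expectation
#' in a two-sided test at level `alpha`, Bonferroni-corrected across
#' candidates, are *confirmed* (*rejected*); the remainder stay *tentative*.
#'
#' This is the flat variant: all candidates stay in play for all
#' iterations and a single test is applied at the end, which keeps the hit
#' counts exchangeable and the run reproducible from one seed.
#'
#' @param X descriptor matrix after correlation pruning.
#' @param y activity labels (both classes present, >= 2 compounds each).
#' @param n_iterations number of shadow/fit rounds (>= 20; default 100).
#' @param alpha two-sided significance level before Bonferroni correction.
#' @param seed master seed; iteration `t` uses `seed + t`.
#' @param importance `"impurity"` (Gini, default) or `"permutation"`.
#' @param num_trees trees per forest fit (default 100).
#' @param include_tentative include tentative descriptors in `kept`.
#' @param rough_fix when tentatives are included, keep only those whose
#'   median importance beats the median of the per-iteration max-shadow
#'   importances.
#' @return object of class `boruta_result`: `confirmed`, `tentative`,
#'   `rejected` (name vectors partitioning `colnames(X)`), `kept`, `hits`
#'   (named hit counts), `n_iterations`, `importance_history` (iterations x
#'   candidates matrix of importances with attached `max_shadow` vector),
#'   and the decision threshold metadata.
#' @export
boruta_select <- function(X, y, n_iterations = 100L, alpha = 0.05, seed = 1L,
                          importance = c("impurity", "permutation"),
                          num_trees = 100L,
                          include_tentative = FALSE, rough_fix = FALSE) {
  X <- descriptor_matrix(X)
  y <- check_both_classes(y)
  importance <- match.arg(importance)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (any(table(y) < 2)) stop("need at least 2 compounds per class", call. = FALSE)
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 20L) stop("n_iterations must be >= 20", call. = FALSE)

  p <- ncol(X)
  cand <- colnames(X)
  hits <- setNames(integer(p), cand)
  imp_hist <- matrix(NA_real_, n_iterations, p, dimnames = list(NULL, cand))
  max_shadow <- numeric(n_iterations)

  for (t in seq_len(n_iterations)) {
    with_seed(seed + t, {
      shadow <- apply(X, 2, sample)
      aug <- cbind(X, shadow)
      colnames(aug) <- c(cand, paste0(".shadow.", cand))
      fit <- ranger::ranger(
        x = aug, y = y, num.trees = num_trees,
        importance = importance, num.threads = 1,
        seed = seed + t
      )
      imp <- fit$variable.importance
      real_imp <- imp[cand]
      sh <- max(imp[paste0(".shadow.", cand)])
      hits <- hits + (real_imp > sh)
      imp_hist[t, ] <- real_imp
      max_shadow[t] <- sh
    })
  }

  # two-sided binomial test on hit counts, Bonferroni across candidates
  p_two <- pmin(1, 2 * pmin(pbinom(hits, n_iterations, 0.5),
                            pbinom(hits - 1L, n_iterations, 0.5,
                                   lower.tail = FALSE)))
  signif <- p_two * p < alpha
  confirmed <- cand[signif & hits > n_iterations / 2]
  rejected <- cand[signif & hits < n_iterations / 2]
  tentative <- setdiff(cand, c(confirmed, rejected))

  kept <- confirmed
  if (include_tentative && length(tentative) > 0) {
    keep_t <- tentative
    if (rough_fix) {
      med_sh <- stats::median(max_shadow)
      keep_t <- tentative[apply(imp_hist[, tentative, drop = FALSE], 2,
                                stats::median) > med_sh]
    }
    kept <- c(confirmed, keep_t)
  }
  attr(imp_hist, "max_shadow") <- max_shadow
  structure(list(
    confirmed = confirmed, tentative = tentative, rejected = rejected,
    kept = kept[order(match(kept, cand))],
    hits = hits, p_adjusted = pmin(1, p_two * p),
    n_iterations = n_iterations, alpha = alpha,
    importance_history = imp_hist
  ), class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  cat(sprintf("Boruta selection over %d candidates (%d iterations, alpha %.3g):\n",
              length(x$hits), x$n_iterations, x$alpha))
  cat(sprintf("  confirmed: %d  tentative: %d  rejected: %d\n",
              length(x$confirmed), length(x$tentative), length(x$rejected)))
  if (length(x$confirmed)) {
    cat("  confirmed:", paste(x$confirmed, collapse = ", "), "\n")
  }
  invisible(x)
}
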