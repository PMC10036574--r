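#' Screen a compound library through the three-filter consensus funnel
#'
#' Applies the validated ensemble to a library and keeps compounds that
#' clear all three filters:
#'
#' * **Filter 1 (consensus)** — predicted active (probability >= 0.5) by
#'   all four models;
#' * **Filter 2 (probability)** — ensemble probability at or above
#'   `probability_threshold` (`"mean"` mode uses the mean of the four
#'   probabilities; `"min"` mode requires every model individually);
#' * **Filter 3 (applicability domain)** — inside the training-set chemical
#'   space as defined by the PCA AD.
#'
#' Passing compounds are ranked by mean ensemble probability (descending,
#' ties broken by compound id). When fingerprints are supplied, each
#' compound is annotated with its maximum Tanimoto similarity to the
#' training actives and flagged *novel* when that similarity is at or below
#' `novelty_threshold`.
#'
#' @param bundle [train_ensemble()] bundle.
#' @param ad [fit_ad()] applicability domain.
#' @param X_lib library descriptor matrix (non-empty).
#' @param fps_lib,fps_train_active optional fingerprint sets for the
#'   novelty annotation; compounds missing from `fps_lib` get `NA`
#'   similarity and are listed in the report's `log` attribute.
#' @param probability_threshold Filter 2 cutoff in `[0, 1]` (default 0.5).
#' @param novelty_threshold similarity at or below which a hit counts as
#'   novel (default 0.5).
#' @param filter2 `"mean"` (default) or `"min"` (per-model minimum).
#' @return data.frame of class `screening_report`: compound_id, the four
#'   probabilities, mean_p, consensus_active, probability_pass, in_ad,
#'   final_pass, max_similarity_to_actives, novel, rank (1..n over passing
#'   compounds, `NA` otherwise).
#' @export
screen_library <- function(bundle, ad, X_lib,
                           fps_lib = NULL, fps_train_active = NULL,
                           probability_threshold = 0.5,
                           novelty_threshold = 0.5,
                           filter2 = c("mean", "min")) {
  stopifnot(inherits(bundle, "ensemble_bundle"), inherits(ad, "ad_model"))
  filter2 <- match.arg(filter2)
  X_lib <- as.matrix(X_lib)
  if (nrow(X_lib) == 0) stop("screening library is empty", call. = FALSE)
  if (probability_threshold < 0 || probability_threshold > 1 ||
      novelty_threshold < 0 || novelty_threshold > 1) {
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  }

  preds <- predict_ensemble(bundle, X_lib)
  ad_res <- in_ad(ad, X_lib)
  prob_stat <- if (filter2 == "mean") {
    preds$mean_p
  } else {
    pmin(preds$p_svm, preds$p_rf, preds$p_xgb, preds$p_knn)
  }
  report <- data.frame(
    compound_id = preds$compound_id,
    p_svm = preds$p_svm, p_rf = preds$p_rf,
    p_xgb = preds$p_xgb, p_knn = preds$p_knn,
    mean_p = preds$mean_p,
    consensus_active = preds$consensus_active,
    probability_pass = prob_stat >= probability_threshold,
    in_ad = ad_res$inside,
    stringsAsFactors = FALSE
  )
  report$final_pass <- report$consensus_active & report$probability_pass & report$in_ad

  log <- character()
  report$max_similarity_to_actives <- NA_real_
  report$novel <- NA
  if (!is.null(fps_lib) && !is.null(fps_train_active)) {
    fps_lib <- fingerprint_set(fps_lib)
    have <- report$compound_id %in% rownames(fps_lib)
    if (any(!have)) {
      log <- c(log, paste0("no fingerprint for: ",
                           paste(report$compound_id[!have], collapse = ", ")))
    }
    if (any(have)) {
      ann <- novelty_annotation(fps_lib[report$compound_id[have], , drop = FALSE],
                                fps_train_active, threshold = novelty_threshold)
      report$max_similarity_to_actives[have] <- ann$max_similarity
      report$novel[have] <- ann$novel
    }
  }

  report$rank <- NA_integer_
  pass <- which(report$final_pass)
  if (length(pass) > 0) {
    ord <- pass[order(-report$mean_p[pass], report$compound_id[pass])]
    report$rank[ord] <- seq_along(ord)
  }
  attr(report, "log") <- log
  attr(report, "probability_threshold") <- probability_threshold
  attr(report, "filter2") <- filter2
  class(report) <- c("screening_report", "data.frame")
  report
}

#' Structural novelty of screening hits
#'
#' For each hit, the maximum Tanimoto similarity over all training actives;
#' a hit is *novel* when that maximum is at or below `threshold` (default
#' 0.5), i.e. it shares at most half of its distinct structural keys with
#' every known active.
#'
#' @param fps_hits,fps_train_active non-empty fingerprint sets.
#' @param threshold novelty cutoff in `[0, 1]`.
#' @return data.frame: compound_id, max_similarity, nearest_active, novel.
#' @export
novelty_annotation <- function(fps_hits, fps_train_active, threshold = 0.5) {
  sim <- pairwise_similarity(fps_hits, fps_train_active)
  max_sim <- apply(sim, 1, max)
  nearest <- colnames(sim)[apply(sim, 1, which.max)]
  data.frame(
    compound_id = rownames(sim),
    max_similarity = unname(max_sim),
    nearest_active = nearest,
    novel = unname(max_sim <= threshold),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("Screening report: %d compounds\n", nrow(x)))
  cat(sprintf("  Filter 1 (consensus):   %d pass\n", sum(x$consensus_active)))
  cat(sprintf("  Filter 2 (probability): %d pass\n", sum(x$probability_pass)))
  cat(sprintf("  Filter 3 (AD):          %d pass\n", sum(x$in_ad)))
  cat(sprintf("  final:                  %d pass\n", sum(x$final_pass)))
  if (any(x$final_pass)) {
    top <- x[order(x$rank), ][seq_len(min(5, sum(x$final_pass))), ]
    cat("  top hits:", paste(sprintf("%s (p=%.2f)", top$compound_id, top$mean_p),
                             collapse = ", "), "\n")
  }
  invisible(x)
}
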