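#' Stratified train/test split
#'
#' Splits compounds into train and test partitions preserving the class
#' balance (per-class rounding of `test_fraction`).
#'
#' @param y activity labels.
#' @param test_fraction fraction held out (default 0.2).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_stratified <- function(y, test_fraction = 0.2, seed = 1L) {
  y <- check_both_classes(y)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie in (0, 1)", call. = FALSE)
  }
  with_seed(seed, {
    test <- integer()
    for (cl in levels(y)) {
      idx <- which(y == cl)
      n_test <- max(1L, round(test_fraction * length(idx)))
      test <- c(test, sample(idx, n_test))
    }
    test <- sort(test)
    list(train = setdiff(seq_along(y), test), test = test)
  })
}

#' Configuration for an end-to-end pipeline run
#'
#' Bundles every stage parameter with the master seed. Either provide input
#' CSV paths (`compounds_csv`, `descriptors_csv`, `fingerprints_csv`,
#' `library_descriptors_csv`, `library_fingerprints_csv`) or leave them
#' `NULL` to run on synthetic data drawn from `synthetic` (a
#' [synthetic_spec()]). The configuration round-trips through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param out_dir run directory (created by [run_pipeline()]).
#' @param boundary_um IC50 activity boundary, micromolar.
#' @param exclude_range optional `c(lo, hi)` IC50 band to exclude.
#' @param correlation_threshold absolute-correlation pruning cutoff.
#' @param boruta list: n_iterations, alpha, num_trees.
#' @param test_fraction held-out fraction for the stratified split.
#' @param ad list: n_components, margin.
#' @param yrand list: n_runs, resample_fraction.
#' @param screening list: probability_threshold, novelty_threshold, filter2,
#'   plus library_n, library_frac_shifted, library_shift for the synthetic
#'   library when no library CSVs are given.
#' @param seed master seed; every stage derives its seed from it.
#' @param synthetic [synthetic_spec()] used when no input paths are given.
#' @param compounds_csv,descriptors_csv,fingerprints_csv optional input paths.
#' @param library_descriptors_csv,library_fingerprints_csv optional library
#'   input paths.
#' @return validated object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            boundary_um = 1.0,
                            exclude_range = NULL,
                            correlation_threshold = 0.85,
                            boruta = list(),
                            test_fraction = 0.2,
                            ad = list(),
                            yrand = list(),
                            screening = list(),
                            seed = 1L,
                            synthetic = synthetic_spec(),
                            compounds_csv = NULL, descriptors_csv = NULL,
                            fingerprints_csv = NULL,
                            library_descriptors_csv = NULL,
                            library_fingerprints_csv = NULL) {
  cfg <- list(
    out_dir = out_dir,
    boundary_um = boundary_um,
    exclude_range = exclude_range,
    correlation_threshold = correlation_threshold,
    boruta = utils::modifyList(
      list(n_iterations = 100L, alpha = 0.05, num_trees = 100L), boruta),
    test_fraction = test_fraction,
    ad = utils::modifyList(list(n_components = 2L, margin = 0), ad),
    yrand = utils::modifyList(
      list(n_runs = 500L, resample_fraction = 0.5), yrand),
    screening = utils::modifyList(
      list(probability_threshold = 0.5, novelty_threshold = 0.5,
           filter2 = "mean", library_n = 500L,
           library_frac_shifted = 0.3, library_shift = 10), screening),
    seed = as.integer(seed),
    synthetic = synthetic,
    compounds_csv = compounds_csv, descriptors_csv = descriptors_csv,
    fingerprints_csv = fingerprints_csv,
    library_descriptors_csv = library_descriptors_csv,
    library_fingerprints_csv = library_fingerprints_csv
  )
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  check_range <- function(v, lo, hi, what, lo_open = FALSE, hi_open = FALSE) {
    ok <- is.numeric(v) && length(v) == 1 && is.finite(v) &&
      (if (lo_open) v > lo else v >= lo) &&
      (if (hi_open) v < hi else v <= hi)
    if (!ok) {
      stop("invalid config: ", what, " must lie in ",
           if (lo_open) "(" else "[", lo, ", ", hi,
           if (hi_open) ")" else "]", call. = FALSE)
    }
  }
  check_range(cfg$boundary_um, 0, Inf, "boundary_um", lo_open = TRUE)
  check_range(cfg$correlation_threshold, 0, 1, "correlation_threshold")
  check_range(cfg$test_fraction, 0, 1, "test_fraction", TRUE, TRUE)
  check_range(cfg$boruta$alpha, 0, 1, "boruta$alpha", TRUE, TRUE)
  check_range(cfg$yrand$resample_fraction, 0, 1, "yrand$resample_fraction",
              lo_open = TRUE)
  check_range(cfg$screening$probability_threshold, 0, 1,
              "screening$probability_threshold")
  check_range(cfg$screening$novelty_threshold, 0, 1,
              "screening$novelty_threshold")
  check_range(cfg$ad$margin, 0, Inf, "ad$margin")
  invisible(cfg)
}

#' Serialise / restore a pipeline configuration as YAML
#'
#' @param cfg a [pipeline_config()].
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  x <- unclass(cfg)
  x$synthetic <- unclass(x$synthetic)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  syn <- x$synthetic
  syn$n_descriptors <- NULL
  do.call(pipeline_config, c(
    x[setdiff(names(x), c("synthetic", "boruta", "ad", "yrand", "screening"))],
    list(synthetic = do.call(synthetic_spec, syn),
         boruta = x$boruta, ad = x$ad, yrand = x$yrand,
         screening = x$screening)
  ))
}

#' Run the full virtual-screening pipeline
#'
#' Executes the six stages in order — curate, select, train, evaluate,
#' validate, screen — writing each stage's outputs under `cfg$out_dir` and
#' a `manifest.json` recording seeds, input hashes, per-stage record counts,
#' collected warnings and timings. Rerunning with the same configuration
#' reproduces all numeric outputs.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress per-stage messages.
#' @return (invisibly) list with the in-memory stage results: `curated`,
#'   `selection`, `bundle`, `metrics`, `ad`, `yrand`, `screening_report`,
#'   `manifest`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("qsarscreen")),
    seed = cfg$seed, stages = list(), warnings = character()
  )
  note <- function(...) if (!quiet) message(sprintf(...))
  warns <- character()
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e) {
      err <- list(stage = name, error = conditionMessage(e))
      write_json_report(err, file.path(cfg$out_dir, "error.json"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      elapsed_s = round(proc.time()[3] - t0, 3),
      records = if (!is.null(res$n_records)) res$n_records else NA
    )
    note("stage %-9s done (%.1fs)", name, proc.time()[3] - t0)
    res
  }

  # -- inputs ---------------------------------------------------------------
  if (is.null(cfg$compounds_csv)) {
    data <- generate_dataset(cfg$synthetic)
    manifest$input <- list(source = "synthetic",
                           spec_seed = cfg$synthetic$seed)
  } else {
    data <- list(
      compounds = read_compounds_csv(cfg$compounds_csv),
      descriptors = read_descriptors_csv(cfg$descriptors_csv),
      fingerprints = read_fingerprints_csv(cfg$fingerprints_csv)
    )
    manifest$input <- list(source = "files", compounds = cfg$compounds_csv)
  }
  manifest$input$data_hash <- rlang::hash(data["compounds"])

  # -- stage 1: curate ------------------------------------------------------
  curated <- stage("curate", {
    dd <- deduplicate_compounds(data$compounds[, c("compound_id", "structure", "ic50_um")])
    rec <- assign_labels(dd$records, boundary_um = cfg$boundary_um,
                         exclude_range = cfg$exclude_range)
    write_compounds_csv(rec, file.path(cfg$out_dir, "curated_compounds.csv"))
    list(records = rec, removal_log = dd$removal_log, n_records = nrow(rec))
  })
  ids <- curated$records$compound_id
  y <- curated$records$label
  X <- data$descriptors[ids, , drop = FALSE]
  fps <- data$fingerprints[ids, , drop = FALSE]

  # -- stage 2: select ------------------------------------------------------
  selection <- stage("select", collect({
    cf <- correlation_filter(X, threshold = cfg$correlation_threshold,
                             seed = cfg$seed + 100L)
    bo <- boruta_select(cf$X, y,
                        n_iterations = cfg$boruta$n_iterations,
                        alpha = cfg$boruta$alpha,
                        num_trees = cfg$boruta$num_trees,
                        seed = cfg$seed + 200L)
    kept <- bo$kept
    write_json_report(list(
      dropped_by_correlation = cf$drop_log,
      dropped_constant = cf$dropped_constant,
      boruta_confirmed = bo$confirmed, boruta_tentative = bo$tentative,
      boruta_rejected = bo$rejected, kept = kept,
      hits = as.list(bo$hits)
    ), file.path(cfg$out_dir, "selection.json"))
    write_descriptors_csv(X[, kept, drop = FALSE],
                          file.path(cfg$out_dir, "descriptors_selected.csv"))
    list(correlation = cf, boruta = bo, kept = kept, n_records = length(kept))
  }))
  if (length(selection$kept) == 0) {
    stop("pipeline stage 'select' retained no descriptors", call. = FALSE)
  }
  Xsel <- X[, selection$kept, drop = FALSE]

  # -- stage 3: train -------------------------------------------------------
  split <- split_stratified(y, cfg$test_fraction, seed = cfg$seed + 300L)
  trained <- stage("train", {
    bundle <- train_ensemble(Xsel[split$train, , drop = FALSE], y[split$train],
                             seed = cfg$seed + 400L)
    preds <- predict_ensemble(bundle, Xsel[split$test, , drop = FALSE])
    write.csv(preds, file.path(cfg$out_dir, "test_predictions.csv"),
              row.names = FALSE)
    list(bundle = bundle, test_predictions = preds, n_records = bundle$n_train)
  })

  # -- stage 4: evaluate ----------------------------------------------------
  evaluation <- stage("evaluate", {
    y_test <- y[split$test]
    per_model <- lapply(c(svm = "p_svm", random_forest = "p_rf",
                          xgboost = "p_xgb", knn = "p_knn"), function(col) {
      p <- trained$test_predictions[[col]]
      m <- classification_metrics(confusion_counts(y_test, hard_label(p)))
      m$auc <- roc_auc(y_test, p)$auc
      m
    })
    gain <- cumulative_gain(y_test, trained$test_predictions$mean_p)
    roc <- roc_auc(y_test, trained$test_predictions$mean_p)
    write_json_report(lapply(per_model, function(m) {
      list(precision = m$precision, recall = m$recall, accuracy = m$accuracy,
           f1 = m$f1, auc = m$auc, counts = m$counts)
    }), file.path(cfg$out_dir, "metrics.json"))
    write.csv(roc$curve, file.path(cfg$out_dir, "roc_curve.csv"), row.names = FALSE)
    write.csv(gain, file.path(cfg$out_dir, "gain_curve.csv"), row.names = FALSE)
    list(per_model = per_model, gain = gain, roc = roc,
         n_records = length(split$test))
  })

  # -- stage 5: validate ----------------------------------------------------
  validation <- stage("validate", collect({
    ad <- fit_ad(Xsel[split$train, , drop = FALSE],
                 n_components = cfg$ad$n_components, margin = cfg$ad$margin)
    ad_test <- in_ad(ad, Xsel[split$test, , drop = FALSE])
    yr <- y_randomization(
      Xsel[split$train, , drop = FALSE], y[split$train],
      model_config("random_forest", seed = cfg$seed + 400L),
      Xsel[split$test, , drop = FALSE], y[split$test],
      n_runs = cfg$yrand$n_runs,
      resample_fraction = cfg$yrand$resample_fraction,
      seed = cfg$seed + 500L
    )
    write_json_report(list(
      center = as.list(ad$center), scale = as.list(ad$scale_sd),
      loadings = ad$loadings, bounds = ad$bounds, margin = ad$margin
    ), file.path(cfg$out_dir, "ad_model.json"))
    write.csv(yr$runs, file.path(cfg$out_dir, "y_randomization.csv"),
              row.names = FALSE)
    list(ad = ad, ad_test = ad_test, yrand = yr, n_records = cfg$yrand$n_runs)
  }))

  # -- stage 6: screen ------------------------------------------------------
  screening <- stage("screen", {
    if (is.null(cfg$library_descriptors_csv)) {
      lib <- generate_screening_library(
        n = cfg$screening$library_n,
        frac_shifted = cfg$screening$library_frac_shifted,
        shift = cfg$screening$library_shift,
        seed = cfg$seed + 600L, spec = cfg$synthetic
      )
    } else {
      lib <- list(descriptors = read_descriptors_csv(cfg$library_descriptors_csv),
                  fingerprints = read_fingerprints_csv(cfg$library_fingerprints_csv))
    }
    fps_active <- fps[y == "active", , drop = FALSE]
    report <- screen_library(
      trained$bundle, validation$ad, lib$descriptors,
      fps_lib = lib$fingerprints, fps_train_active = fps_active,
      probability_threshold = cfg$screening$probability_threshold,
      novelty_threshold = cfg$screening$novelty_threshold,
      filter2 = cfg$screening$filter2
    )
    write.csv(as.data.frame(report), file.path(cfg$out_dir, "screening_report.csv"),
              row.names = FALSE)
    list(report = report, n_records = nrow(report))
  })

  manifest$warnings <- warns
  manifest$n_stages <- length(manifest$stages)
  manifest$split <- list(n_train = length(split$train), n_test = length(split$test))
  write_json_report(manifest, file.path(cfg$out_dir, "manifest.json"))

  invisible(list(
    curated = curated, selection = selection, bundle = trained$bundle,
    metrics = evaluation$per_model, ad = validation$ad,
    yrand = validation$yrand, screening_report = screening$report,
    manifest = manifest
  ))
}
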