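#' Label compounds by an IC50 activity decision boundary
#'
#' Assigns the binary activity label used throughout the pipeline:
#' a compound is *active* iff its IC50 is at or below the boundary
#' (default 1 micromolar, i.e. `ic50_um <= 1` is active, boundary
#' inclusive), otherwise *inactive*. Optionally an intermediate-activity
#' band can be excluded entirely (e.g. `exclude_range = c(1, 10)` drops
#' compounds with 1 < IC50 <= 10 before labeling); by default nothing is
#' excluded and everything above the boundary is kept as inactive.
#'
#' @param records data.frame with at least `compound_id` and `ic50_um`
#'   columns (micromolar, strictly positive).
#' @param boundary_um positive activity boundary in micromolar.
#' @param exclude_range optional numeric `c(lo, hi)`: records with
#'   `lo < ic50_um <= hi` are dropped and reported.
#' @return the records with a `label` factor column (levels active,
#'   inactive). Class counts are attached as `attr(, "class_counts")`;
#'   excluded rows, if any, as `attr(, "excluded")`.
#' @examples
#' df <- data.frame(compound_id = c("a", "b", "c"),
#'                  ic50_um = c(0.5, 1.0, 10.0))
#' labelled <- assign_labels(df)
#' table(labelled$label)  # a, b active; c inactive
#' @export
assign_labels <- function(records, boundary_um = 1.0, exclude_range = NULL) {
  stopifnot(is.data.frame(records))
  if (!all(c("compound_id", "ic50_um") %in% names(records))) {
    stop("records must have 'compound_id' and 'ic50_um' columns", call. = FALSE)
  }
  if (!is.numeric(boundary_um) || length(boundary_um) != 1 || boundary_um <= 0) {
    stop("boundary_um must be a single positive number", call. = FALSE)
  }
  bad <- is.na(records$ic50_um) | !is.finite(records$ic50_um) | records$ic50_um <= 0
  if (any(bad)) {
    stop("missing or non-positive ic50_um for compound(s): ",
         paste(records$compound_id[bad], collapse = ", "), call. = FALSE)
  }
  excluded <- NULL
  if (!is.null(exclude_range)) {
    stopifnot(length(exclude_range) == 2, exclude_range[1] < exclude_range[2])
    drop <- records$ic50_um > exclude_range[1] & records$ic50_um <= exclude_range[2]
    excluded <- records[drop, , drop = FALSE]
    records <- records[!drop, , drop = FALSE]
  }
  records$label <- factor(
    ifelse(records$ic50_um <= boundary_um, "active", "inactive"),
    levels = activity_levels
  )
  attr(records, "class_counts") <- table(records$label)
  if (!is.null(excluded)) attr(records, "excluded") <- excluded
  records
}

#' Collapse duplicate compound records
#'
#' Groups records sharing a canonical structure key and keeps one record per
#' group, aggregating IC50 by the group median (robust to discordant assay
#' replicates) or, optionally, keeping the first record's value. Records
#' whose structure fails canonicalisation (the hook through which an
#' organic/validity filter can be plugged) are dropped and logged.
#'
#' @param records data.frame with `compound_id`, `structure`, `ic50_um`.
#' @param aggregate `"median"` (default) or `"first"`.
#' @param canonicalize optional function mapping a structure string to a
#'   canonical key, returning `NA` for structures to reject. Defaults to the
#'   identity (exact string match).
#' @return list with `records` (deduplicated; every surviving group carries
#'   the first member's id and structure) and `removal_log` (data.frame:
#'   compound_id, reason, kept_as). Every input id appears either in the
#'   output or in the log.
#' @examples
#' df <- data.frame(compound_id = c("a", "b"),
#'                  structure = c("X", "X"), ic50_um = c(0.2, 0.4))
#' deduplicate_compounds(df)$records$ic50_um  # 0.3
#' @export
deduplicate_compounds <- function(records,
                                  aggregate = c("median", "first"),
                                  canonicalize = NULL) {
  stopifnot(is.data.frame(records))
  aggregate <- match.arg(aggregate)
  if (!all(c("compound_id", "structure", "ic50_um") %in% names(records))) {
    stop("records must have 'compound_id', 'structure' and 'ic50_um' columns",
         call. = FALSE)
  }
  n <- nrow(records)
  keys <- if (is.null(canonicalize)) {
    as.character(records$structure)
  } else {
    vapply(as.character(records$structure),
           function(s) as.character(canonicalize(s))[1], character(1),
           USE.NAMES = FALSE)
  }

  log_rows <- list()
  invalid <- is.na(keys)
  if (any(invalid)) {
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      compound_id = records$compound_id[invalid],
      reason = "unparseable_structure", kept_as = NA_character_,
      stringsAsFactors = FALSE
    )
    records <- records[!invalid, , drop = FALSE]
    keys <- keys[!invalid]
  }

  keep <- !duplicated(keys)
  out <- records[keep, , drop = FALSE]
  key_of <- keys[keep]
  for (i in which(duplicated(keys))) {
    j <- match(keys[i], key_of)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      compound_id = records$compound_id[i], reason = "duplicate_structure",
      kept_as = out$compound_id[j], stringsAsFactors = FALSE
    )
  }
  if (aggregate == "median" && any(duplicated(keys))) {
    agg <- tapply(records$ic50_um, keys, stats::median)
    out$ic50_um <- as.numeric(agg[key_of])
  }
  removal_log <- if (length(log_rows)) {
    do.call(rbind, log_rows)
  } else {
    data.frame(compound_id = character(), reason = character(),
               kept_as = character(), stringsAsFactors = FALSE)
  }
  stopifnot(nrow(out) + nrow(removal_log) == n)
  list(records = out, removal_log = removal_log)
}
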