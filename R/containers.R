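#' Validate a descriptor matrix
#'
#' A descriptor matrix is a plain numeric matrix, compounds in rows
#' (rownames = compound ids) and named molecular descriptors in columns.
#' This constructor checks the contract every modelling function assumes:
#' finite numeric values, unique descriptor names, unique compound ids.
#'
#' @param values numeric matrix (compounds x descriptors).
#' @param compound_ids character vector of row ids; defaults to existing
#'   rownames.
#' @param descriptor_names character vector of column names; defaults to
#'   existing colnames.
#' @return the validated matrix with dimnames set.
#' @export
descriptor_matrix <- function(values,
                              compound_ids = rownames(values),
                              descriptor_names = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("descriptor values must be numeric", call. = FALSE)
  if (is.null(compound_ids)) {
    compound_ids <- sprintf("CPD%05d", seq_len(nrow(values)))
  }
  if (is.null(descriptor_names)) {
    stop("descriptor columns must be named", call. = FALSE)
  }
  if (anyDuplicated(descriptor_names)) {
    stop("descriptor names must be unique", call. = FALSE)
  }
  if (anyDuplicated(compound_ids)) {
    stop("compound ids must be unique", call. = FALSE)
  }
  if (length(compound_ids) != nrow(values) ||
      length(descriptor_names) != ncol(values)) {
    stop("dimnames do not match matrix dimensions", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    bad <- compound_ids[unique(which(!is.finite(values), arr.ind = TRUE)[, 1])]
    stop("non-finite descriptor values for compound(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  dimnames(values) <- list(compound_ids, descriptor_names)
  values
}

#' Validate a structural-key fingerprint set
#'
#' Fingerprints are stored as a plain binary matrix: compounds in rows
#' (rownames = compound ids), exactly `n_bits` 0/1 columns named
#' `bit_1 ... bit_n`. The 166-bit MACCS-style structural-key length is the
#' default and the only length used by the rest of the package.
#'
#' @param bits matrix (or data frame) of 0/1 values.
#' @param compound_ids row ids; defaults to existing rownames.
#' @param n_bits required number of bit positions (default 166).
#' @return validated integer matrix of 0/1 values.
#' @export
fingerprint_set <- function(bits, compound_ids = rownames(bits), n_bits = 166L) {
  bits <- as.matrix(bits)
  if (ncol(bits) != n_bits) {
    stop("fingerprints must have exactly ", n_bits, " bit positions, got ",
         ncol(bits), call. = FALSE)
  }
  if (!all(bits %in% c(0L, 1L))) {
    stop("fingerprint entries must be 0 or 1", call. = FALSE)
  }
  if (is.null(compound_ids)) {
    compound_ids <- sprintf("CPD%05d", seq_len(nrow(bits)))
  }
  if (anyDuplicated(compound_ids)) stop("compound ids must be unique", call. = FALSE)
  storage.mode(bits) <- "integer"
  dimnames(bits) <- list(compound_ids, paste0("bit_", seq_len(n_bits)))
  bits
}
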