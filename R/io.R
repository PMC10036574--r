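# Readers/writers for the strict CSV interchange dialect: UTF-8, header
# row, first column `compound_id`. JSON via jsonlite for reports.

#' Read / write a compound table
#'
#' Columns: compound_id, structure, ic50_um and (after labeling) label.
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_compounds_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (names(df)[1] != "compound_id") {
    stop("first column must be 'compound_id'", call. = FALSE)
  }
  if ("label" %in% names(df)) df$label <- as_activity_factor(df$label)
  df
}

#' @rdname read_compounds_csv
#' @param compounds data.frame to write.
#' @export
write_compounds_csv <- function(compounds, path) {
  write.csv(compounds, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read / write a descriptor matrix as CSV
#'
#' First column `compound_id`, remaining columns named numeric descriptors.
#' @param path CSV file path.
#' @return validated descriptor matrix.
#' @export
read_descriptors_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "compound_id") {
    stop("first column must be 'compound_id'", call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  descriptor_matrix(m, compound_ids = df$compound_id)
}

#' @rdname read_descriptors_csv
#' @param X descriptor matrix to write.
#' @export
write_descriptors_csv <- function(X, path) {
  X <- descriptor_matrix(X)
  df <- data.frame(compound_id = rownames(X), X,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read / write a fingerprint set as CSV of 166 0/1 columns
#'
#' @param path CSV file path.
#' @return validated fingerprint matrix.
#' @export
read_fingerprints_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "compound_id") {
    stop("first column must be 'compound_id'", call. = FALSE)
  }
  fingerprint_set(as.matrix(df[, -1, drop = FALSE]), compound_ids = df$compound_id)
}

#' @rdname read_fingerprints_csv
#' @param fps fingerprint set to write.
#' @export
write_fingerprints_csv <- function(fps, path) {
  fps <- fingerprint_set(fps)
  df <- data.frame(compound_id = rownames(fps), fps,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Hex-string encoding of 166-bit fingerprints
#'
#' Bits are packed most-significant-first into 42 hex characters (168 bits;
#' the trailing 2 bits are zero padding). The encoding round-trips exactly.
#'
#' @param fps fingerprint set.
#' @return named character vector of 42-character hex strings.
#' @export
fingerprints_to_hex <- function(fps) {
  fps <- fingerprint_set(fps)
  apply(fps, 1, function(bits) {
    padded <- c(bits, 0L, 0L)
    nib <- matrix(padded, nrow = 4)
    vals <- 8L * nib[1, ] + 4L * nib[2, ] + 2L * nib[3, ] + nib[4, ]
    paste(sprintf("%x", vals), collapse = "")
  })
}

#' @rdname fingerprints_to_hex
#' @param hex character vector of 42-character hex strings.
#' @param compound_ids ids for the decoded set; defaults to `names(hex)`.
#' @export
hex_to_fingerprints <- function(hex, compound_ids = names(hex)) {
  if (any(nchar(hex) != 42L)) stop("hex strings must have 42 characters", call. = FALSE)
  bits <- t(vapply(hex, function(h) {
    vals <- strtoi(strsplit(h, "")[[1]], base = 16L)
    if (any(is.na(vals))) stop("invalid hex string: ", h, call. = FALSE)
    unlist(lapply(vals, function(v) c(v %/% 8L %% 2L, v %/% 4L %% 2L,
                                      v %/% 2L %% 2L, v %% 2L)))[1:166]
  }, integer(166)))
  fingerprint_set(bits, compound_ids = compound_ids)
}

#' Write a list as pretty JSON
#'
#' @param x list to serialise.
#' @param path output path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
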